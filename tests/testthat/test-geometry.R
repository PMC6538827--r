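test_that("default infarct sheet has the canonical discretization and labels", {
  mesh <- build_idealized_infarct_sheet(infarct_spec())
  expect_equal(nrow(mesh$elements), 40000L)
  expect_equal(nrow(mesh$nodes), 201L * 201L)
  # labels partition the nodes
  expect_equal(sum(table(mesh$nodes$region)), nrow(mesh$nodes))
  expect_setequal(unique(mesh$nodes$region), c("MYO", "BZ", "SCAR"))
  # nodal areas tile the sheet exactly
  expect_equal(sum(mesh$nodes$area), 40 * 40, tolerance = 1e-10)
})

test_that("scar gap and border-zone rim match the construction within a grid step", {
  mesh <- build_idealized_infarct_sheet(infarct_spec())
  nd <- mesh$nodes
  res <- mesh$resolution
  scar <- nd[nd$region == "SCAR", ]
  # two scar components left/right of the vertical channel through x = 20
  left <- scar[scar$x < 20, ]
  right <- scar[scar$x > 20, ]
  expect_gt(nrow(left), 0)
  expect_gt(nrow(right), 0)
  gap <- min(right$x) - max(left$x)
  expect_lt(abs(gap - 4), res + 1e-9)
  # border-zone rim outside the scar radius is 0.5 mm wide
  r <- sqrt((nd$x - 20)^2 + (nd$y - 20)^2)
  rim <- nd$region == "BZ" & r > 15
  expect_true(any(rim))
  expect_lte(max(r[rim]) - 15, 0.5 + res)
  expect_gte(max(r[rim]) - 15, 0.5 - res)
})

test_that("zero isthmus width degenerates to a solid scar disc with an annular BZ", {
  mesh <- build_idealized_infarct_sheet(
    infarct_spec(isthmus_width = 0))
  nd <- mesh$nodes
  r <- sqrt((nd$x - 20)^2 + (nd$y - 20)^2)
  expect_true(all(nd$region[r <= 15] == "SCAR"))
  expect_true(all(nd$region[r > 15 & r <= 15.5] == "BZ"))
  expect_true(all(nd$region[r > 15.5] == "MYO"))
})

test_that("invalid infarct specifications are rejected", {
  expect_error(infarct_spec(resolution = 0.3), "divide")
  expect_error(infarct_spec(isthmus_width = 31), "no scar")
  expect_error(infarct_spec(bz_radius = 10), "bz_radius")
  expect_error(infarct_spec(sheet_size = 20), "contain")
})

test_that("the default infarct is mirror-symmetric about the isthmus axis", {
  mesh <- build_idealized_infarct_sheet(infarct_spec())
  nd <- mesh$nodes
  # reflect x -> 40 - x maps grid nodes onto grid nodes
  i <- round(nd$x / mesh$resolution)
  j <- round(nd$y / mesh$resolution)
  mirror <- j * mesh$nx + (mesh$nx - 1L - i) + 1L
  agree <- mean(nd$region == nd$region[mirror])
  expect_gte(agree, 0.995)
})

test_that("decapolar placement follows the spacing pattern", {
  mesh <- grid_mesh(61, 61, 1)  # 60 mm sheet: the default catheter spans 42 mm
  g <- place_decapolar(mesh, origin = c(10, 5))
  expect_equal(nrow(g), 10L)
  expect_equal(max(g$y) - min(g$y), 42)  # sum of the nine gaps
  gaps <- diff(g$y)
  expect_equal(gaps, c(2, 8, 2, 8, 2, 8, 2, 8, 2))

  g2 <- place_decapolar(mesh, origin = c(10, 5),
                        spacing_pattern = c(1.25, 5, 1.25, 5, 1.25, 5, 1.25, 5, 1.25))
  expect_equal(max(g2$y) - min(g2$y), 26.25)

  g3 <- place_decapolar(mesh, origin = c(5, 5), spacing_pattern = numeric(0))
  expect_equal(nrow(g3), 1L)
  expect_equal(c(g3$x, g3$y), c(5, 5))

  expect_error(place_decapolar(mesh, origin = c(10, 30)), "electrode")
  expect_error(place_decapolar(mesh, origin = c(10, 5),
                               spacing_pattern = c(2, -1)), "positive")
})

test_that("fan placement reduces to a decapolar for one arm and fans out otherwise", {
  mesh <- grid_mesh(61, 61, 1)
  f1 <- place_fan(mesh, origin = c(20, 5), arm_angles = 0)
  d1 <- place_decapolar(mesh, origin = c(20, 5))
  expect_equal(f1$x, d1$x, tolerance = 1e-12)
  expect_equal(f1$y, d1$y, tolerance = 1e-12)

  f3 <- place_fan(mesh, origin = c(20, 5), arm_angles = c(-20, 0, 20),
                  spacing_pattern = rep(2, 9))
  expect_equal(nrow(f3), 30L)
  # arm separation grows with distance from the origin
  a1 <- f3[f3$cluster == 1, ]
  a2 <- f3[f3$cluster == 2, ]
  sep <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2)
  expect_true(all(diff(sep) > 0))

  expect_error(place_fan(mesh, origin = c(20, 5), arm_angles = c(0, 0)),
               "distinct")
})

test_that("random multipolar grids are radius-bounded, seeded and reproducible", {
  mesh <- build_idealized_infarct_sheet(
    infarct_spec(sheet_size = 20, scar_radius = 6, bz_radius = 6.5,
                 isthmus_width = 2))
  g <- place_multipolar_random(mesh, n_clusters = 10, seed = 42)
  # every electrode lies within the cluster radius of its cluster center:
  # cluster radius bounds the within-cluster spread to a 3 mm diameter
  spread <- g %>%
    dplyr::group_by(cluster) %>%
    dplyr::summarise(d = max(sqrt((x - mean(x))^2 + (y - mean(y))^2)))
  for (cl in unique(g$cluster)) {
    sub <- g[g$cluster == cl, ]
    dd <- sqrt(outer(sub$x, sub$x, "-")^2 + outer(sub$y, sub$y, "-")^2)
    expect_lte(max(dd), 2 * 1.5 + 1e-9)
  }
  g2 <- place_multipolar_random(mesh, n_clusters = 10, seed = 42)
  expect_identical(as.data.frame(g), as.data.frame(g2))
  g3 <- place_multipolar_random(mesh, n_clusters = 10, seed = 43)
  expect_false(identical(as.data.frame(g), as.data.frame(g3)))

  # node_fraction = 1 records every node inside the ball
  g4 <- place_multipolar_random(mesh, n_clusters = 1, node_fraction = 1,
                                cluster_radius = 1.5, seed = 7)
  ctr <- c(mean(range(g4$x)), mean(range(g4$y)))
  nd <- mesh$nodes
  # the cluster center is one of the sampled nodes: recover it as the node
  # whose 1.5 mm ball equals the electrode set
  found <- FALSE
  for (cand in which(nd$x >= min(g4$x) & nd$x <= max(g4$x) &
                     nd$y >= min(g4$y) & nd$y <= max(g4$y))) {
    ball <- which((nd$x - nd$x[cand])^2 + (nd$y - nd$y[cand])^2 <= 1.5^2)
    if (setequal(ball, g4$host_node)) { found <- TRUE; break }
  }
  expect_true(found)

  expect_error(place_multipolar_random(mesh, n_clusters = 1e6), "node count")
})

test_that("host nodes are the true nearest mesh nodes (brute force)", {
  mesh <- build_idealized_infarct_sheet(
    infarct_spec(sheet_size = 10, resolution = 0.5, scar_radius = 3,
                 bz_radius = 3.5, isthmus_width = 1))
  expect_lte(nrow(mesh$nodes), 1e4)
  set.seed(11)
  px <- runif(40, 0, 10); py <- runif(40, 0, 10)
  g <- rvimap:::new_recording_grid(
    tibble::tibble(electrode = 1:40, x = px, y = py), "fixture", mesh = mesh)
  for (k in 1:40) {
    d <- sqrt((mesh$nodes$x - px[k])^2 + (mesh$nodes$y - py[k])^2)
    best <- which(d <= min(d) + 1e-12)[1]  # lowest index among ties
    expect_equal(g$host_node[k], best)
  }
})
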