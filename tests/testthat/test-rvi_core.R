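test_that("a hand-worked three-electrode line reproduces all three interpolations", {
  # electrodes at 0, 2, 4 mm; AT 0/10/40; RT 200/215/260; R = 4
  g <- make_grid(x = c(0, 2, 4), y = c(0, 0, 0))
  m <- make_markers(at = c(0, 10, 40), rt = c(200, 215, 260))
  pr <- downstream_pairs(m, g, radius = 4)
  expect_equal(nrow(pr), 3L)
  expect_setequal(paste(pr$i, pr$j), c("1 2", "1 3", "2 3"))
  expect_equal(pr$rvi[order(pr$i, pr$j)], c(190, 160, 175))

  cfg_min <- rvi_config(radius = 4, method = "minimum")
  cfg_avg <- rvi_config(radius = 4, method = "average")
  mp_min <- build_rvi_map(m, g, cfg_min)
  mp_avg <- build_rvi_map(m, g, cfg_avg)
  expect_equal(mp_min$rvi, c(160, 175, NA))
  expect_equal(mp_avg$rvi, c(175, 175, NA))

  # nearest-neighbour on a 1 mm line mesh: midpoints 1, 2, 3 mm
  mesh <- grid_mesh(nx = 5, ny = 1, res = 1)
  cfg_nn <- rvi_config(radius = 4, method = "nearest_neighbor")
  mp_nn <- build_rvi_map(m, g, cfg_nn, mesh = mesh)
  expect_equal(mp_nn$site, c(2L, 3L, 4L))
  expect_equal(mp_nn$rvi, c(190, 160, 175))
})

test_that("downstream pairing excludes AT ties, NAs and out-of-radius sites", {
  g <- make_grid(x = c(0, 1, 2, 10), y = rep(0, 4))
  m <- make_markers(at = c(5, 5, NA, 6), rt = c(100, 100, 100, 100))
  pr <- downstream_pairs(m, g, radius = 4)
  expect_equal(nrow(pr), 0L)  # ties not downstream; NA skipped; 4 too far

  # undefined RT(i) keeps the pair but gives NA rvi
  m2 <- make_markers(at = c(0, 10), rt = c(NA, 100))
  pr2 <- downstream_pairs(m2, make_grid(x = c(0, 1), y = c(0, 0)), radius = 4)
  expect_equal(nrow(pr2), 1L)
  expect_true(is.na(pr2$rvi))
})

test_that("aggregated maps agree with brute-force oracles on random fields", {
  set.seed(301)
  for (trial in 1:4) {
    n <- 150
    pos <- cbind(runif(n, 0, 30), runif(n, 0, 30))
    at <- runif(n, 0, 300); rt <- at + runif(n, 100, 250)
    at[sample(n, 10)] <- NA; rt[sample(n, 10)] <- NA
    g <- make_grid(pos[, 1], pos[, 2])
    m <- make_markers(at, rt)
    for (R in c(3, 8)) {
      expect_equal(build_rvi_map(m, g, rvi_config(R, "minimum"))$rvi,
                   brute_map(pos, at, rt, R, "minimum"))
      expect_equal(build_rvi_map(m, g, rvi_config(R, "average"))$rvi,
                   brute_map(pos, at, rt, R, "average"))
      mesh <- grid_mesh(31, 31, 1)
      nn <- build_rvi_map(m, g, rvi_config(R, "nearest_neighbor"), mesh = mesh)
      oracle <- brute_nn_map(pos, at, rt, R, 1, 31, 31)
      full <- rep(NA_real_, 31 * 31); full[nn$site] <- nn$rvi
      expect_equal(full, oracle)
    }
  }
})

test_that("3D electrode coordinates enter the pair distance", {
  g <- make_grid(x = c(0, 0), y = c(0, 0), z = c(0, 5))
  m <- make_markers(at = c(0, 10), rt = c(100, 120))
  expect_equal(nrow(downstream_pairs(m, g, radius = 4)), 0L)
  expect_equal(nrow(downstream_pairs(m, g, radius = 6)), 1L)
  mp <- build_rvi_map(m, g, rvi_config(6, "minimum"))
  expect_equal(mp$rvi, c(90, NA))
})

test_that("minimum maps bound average maps from below site-wise", {
  set.seed(302)
  n <- 200
  g <- make_grid(runif(n, 0, 40), runif(n, 0, 40))
  m <- make_markers(runif(n, 0, 400), runif(n, 400, 700))
  lo <- build_rvi_map(m, g, rvi_config(8, "minimum"))$rvi
  av <- build_rvi_map(m, g, rvi_config(8, "average"))$rvi
  ok <- !is.na(lo)
  expect_identical(is.na(lo), is.na(av))
  expect_true(all(lo[ok] <= av[ok] + 1e-12))
})

test_that("the site-wise minimum never increases as the search radius grows", {
  set.seed(303)
  n <- 200
  g <- make_grid(runif(n, 0, 40), runif(n, 0, 40))
  m <- make_markers(runif(n, 0, 400), runif(n, 400, 700))
  prev <- rep(Inf, n)
  for (R in c(2, 4, 8, 16)) {
    cur <- build_rvi_map(m, g, rvi_config(R, "minimum"))$rvi
    cur[is.na(cur)] <- Inf
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("maps are invariant to electrode row order and to rigid motion", {
  set.seed(304)
  n <- 120
  x <- runif(n, 0, 30); y <- runif(n, 0, 30)
  at <- runif(n, 0, 300); rt <- at + runif(n, 100, 250)
  g <- make_grid(x, y); m <- make_markers(at, rt)
  base <- build_rvi_map(m, g, rvi_config(6, "minimum"))

  perm <- sample(n)
  gp <- rvimap:::new_recording_grid(
    tibble::tibble(electrode = perm, x = x[perm], y = y[perm]), "fixture")
  mp <- rvimap:::new_marker_map(
    tibble::tibble(electrode = perm, beat = "SYN", at = at[perm], rt = rt[perm]))
  shuf <- build_rvi_map(mp, gp, rvi_config(6, "minimum"))
  expect_equal(shuf$rvi[match(base$site, shuf$site)], base$rvi)

  # translation + rotation leave pair distances, hence the map, unchanged
  th <- 0.7
  gr <- make_grid(5 + cos(th) * x - sin(th) * y, -3 + sin(th) * x + cos(th) * y)
  rot <- build_rvi_map(m, gr, rvi_config(6, "minimum"))
  expect_equal(rot$rvi, base$rvi, tolerance = 1e-9)
})

test_that("vulnerable-region quantification counts strict sub-threshold sites and areas", {
  g <- make_grid(x = c(0, 1, 2, 3), y = rep(0, 4))
  df <- tibble::tibble(site = 1:4, x = g$x, y = g$y,
                       rvi = c(49.999, 50, NA, -10), n_pairs = c(1L, 1L, 0L, 1L),
                       area = c(2, 2, 2, 2))
  mp <- rvimap:::new_rvi_map(df, rvi_config(4, "minimum"), "electrode")
  q <- quantify_vulnerable_region(mp)
  expect_equal(q$n_sites, 4L)
  expect_equal(q$n_defined, 3L)
  expect_equal(q$n_below, 2L)
  expect_equal(q$size_mm2, 4)
  expect_equal(q$lowest_rvi, -10)
  # threshold override
  expect_equal(quantify_vulnerable_region(mp, threshold = 0)$n_below, 1L)
  # empty map
  mp0 <- rvimap:::new_rvi_map(df[0, ], rvi_config(4, "minimum"), "electrode")
  q0 <- quantify_vulnerable_region(mp0)
  expect_equal(q0$n_below, 0L)
  expect_true(is.na(q0$lowest_rvi))
})

test_that("the sweep table matches maps built one at a time", {
  set.seed(305)
  mesh <- grid_mesh(21, 21, 1)
  g <- make_grid(runif(60, 0, 20), runif(60, 0, 20))
  m <- make_markers(runif(60, 0, 300), runif(60, 250, 500))
  sw <- rvi_sweep(m, g, methods = c("average", "minimum"), radii = c(3, 6),
                  mesh = mesh)
  expect_equal(nrow(sw), 4L)
  for (k in seq_len(nrow(sw))) {
    cfg <- rvi_config(sw$radius[k], sw$method[k])
    q <- quantify_vulnerable_region(
      build_rvi_map(m, g, cfg, mesh = mesh), mesh = mesh)
    expect_equal(sw$n_below[k], q$n_below)
    expect_equal(sw$lowest_rvi[k], q$lowest_rvi)
  }
})

test_that("the consistency report reproduces the published fold changes", {
  rep <- consistency_report()
  get <- function(model, method)
    rep$fold_change[rep$model == model & rep$method == method]
  expect_equal(round(get("sheet_2d", "minimum"), 1), 8.6)
  expect_equal(round(get("biv", "minimum"), 1), 6.7)
  # minimum interpolation over-extends more than the others in both models
  expect_gt(get("sheet_2d", "minimum"), get("sheet_2d", "nearest_neighbor"))
  expect_gt(get("biv", "minimum"), get("biv", "nearest_neighbor"))
})

test_that("mismatched electrode sets and multi-beat maps are rejected", {
  g <- make_grid(x = c(0, 1), y = c(0, 0))
  m <- make_markers(at = c(0, 10, 20), rt = c(100, 120, 140))
  expect_error(build_rvi_map(m, g, rvi_config()), "electrode set")
  m2 <- rvimap:::new_marker_map(
    tibble::tibble(electrode = c(1, 2, 1, 2), beat = c("a", "a", "b", "b"),
                   at = 1:4, rt = 5:8))
  expect_error(build_rvi_map(m2, g, rvi_config()), "several beats")
  expect_equal(nrow(build_rvi_map(m2, g, rvi_config(), beat = "a")), 2L)
})
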