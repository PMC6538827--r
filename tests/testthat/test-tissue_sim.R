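test_that("an unstimulated sheet stays quiescent", {
  mesh <- grid_mesh(26, 26, 0.4)
  prot <- pacing_protocol(n_s1 = 1, s2_coupling = NULL, stim_amplitude = 0,
                          tail = 100)
  grid <- rvimap:::new_recording_grid(
    tibble::tibble(electrode = 1, x = 5, y = 5), "fixture", mesh = mesh)
  sim <- run_monodomain(mesh, tissue_params(), prot, grid = grid)
  expect_lt(max(abs(sim$traces$e1 - (-80))), 0.1)
  expect_equal(nrow(sim$crossings), 0L)
})

test_that("the explicit stability bound is enforced before running", {
  mesh <- grid_mesh(11, 11, 0.2)
  expect_error(
    run_monodomain(mesh, tissue_params(dt = 0.5), pacing_protocol()),
    "stability bound")
})

test_that("plane-wave conduction velocity is within 10% of a fine 1D cable oracle", {
  # fine 1D cable (dx/4, dt/8) of the same model as the reference
  cable_cv <- function(res, dt) {
    nx <- as.integer(round(30 / res)) + 1L
    ip <- ionic_params()
    tp <- tissue_params(dt = dt)
    D <- rep(rvimap:::diffusivity(tp), nx)
    xs <- (seq_len(nx) - 1) * res
    raw <- rvimap:::.cpp_monodomain(
      nx, 1L, res, dt, as.integer(200 / dt), D, integer(nx),
      rep(ip$tau_in, nx), rep(ip$tau_out, nx), rep(ip$tau_open, nx),
      rep(ip$tau_close_myo, nx), rep(ip$v_gate, nx),
      which(xs <= 2) - 1L, 0, 2, 0.3,
      integer(0), 0L, integer(0),
      rvimap:::vm_to_v(-20), rvimap:::vm_to_v(-70), numeric(0), TRUE)
    at <- function(xmm) raw$up_time[raw$up_node + 1L == which.min(abs(xs - xmm))]
    (25 - 10) / (at(25) - at(10))
  }
  cv_ref <- cable_cv(0.05, 0.0025)
  cv_def <- cable_cv(0.2, 0.02)
  expect_lt(abs(cv_def - cv_ref) / cv_ref, 0.10)
})

test_that("halving the time step changes activation times by less than 1 ms", {
  mesh <- grid_mesh(26, 26, 0.4)  # 10 x 10 mm test sheet
  prot <- pacing_protocol(n_s1 = 1, s2_coupling = NULL, tail = 300)
  at_of <- function(dt) {
    sim <- run_monodomain(mesh, tissue_params(dt = dt), prot)
    m <- marker_beat(markers_from_crossings(sim), "S1_1")
    m$at[match(seq_len(nrow(mesh$nodes)), m$electrode)]
  }
  a1 <- at_of(0.02)
  a2 <- at_of(0.01)
  expect_true(all(abs(a1 - a2) < 1, na.rm = TRUE))
  expect_identical(is.na(a1), is.na(a2))
})

test_that("pure diffusion conserves the spatial mean of the voltage", {
  nx <- 21L; ny <- 21L; N <- nx * ny
  set.seed(5)
  v0 <- runif(N)
  ip <- ionic_params()
  raw <- rvimap:::.cpp_monodomain(
    nx, ny, 0.2, 0.02, 2000L, rep(0.05, N), integer(N),
    rep(ip$tau_in, N), rep(ip$tau_out, N), rep(ip$tau_open, N),
    rep(ip$tau_close_myo, N), rep(ip$v_gate, N),
    0L, numeric(0), 2, 0,
    integer(0), 0L, integer(0), 0.6, 0.1, v0, FALSE)
  expect_equal(mean(raw$v_final), mean(v0), tolerance = 1e-10)
  # and the field relaxes toward uniformity
  expect_lt(sd(raw$v_final), sd(v0))
})

test_that("a mirror-symmetric infarct gives a mirror-symmetric activation map", {
  spec <- infarct_spec(sheet_size = 20, resolution = 0.2, scar_radius = 6,
                       bz_radius = 6.5, isthmus_width = 2)
  mesh <- build_idealized_infarct_sheet(spec)
  prot <- pacing_protocol(n_s1 = 1, s2_coupling = NULL, tail = 400)
  sim <- run_monodomain(mesh, tissue_params(), prot)
  m <- marker_beat(markers_from_crossings(sim), "S1_1")
  at <- m$at[match(seq_len(nrow(mesh$nodes)), m$electrode)]
  i <- round(mesh$nodes$x / mesh$resolution)
  j <- round(mesh$nodes$y / mesh$resolution)
  mirror <- j * mesh$nx + (mesh$nx - 1L - i) + 1L
  d <- abs(at - at[mirror])
  # max asymmetry below the activation-time span of 2 grid cells
  cv_ref <- 0.23
  expect_lt(max(d, na.rm = TRUE), 2 * mesh$resolution / cv_ref)
  # the discrete scar boundary itself is symmetric only up to the node
  # rounding rule; allow a thin rim of region-label mismatches
  expect_lt(mean(is.na(at) != is.na(at[mirror])), 0.005)
})

test_that("scar nodes never activate and act as no-flux obstacles", {
  spec <- infarct_spec(sheet_size = 20, resolution = 0.2, scar_radius = 6,
                       bz_radius = 6.5, isthmus_width = 2)
  mesh <- build_idealized_infarct_sheet(spec)
  prot <- pacing_protocol(n_s1 = 1, s2_coupling = NULL, tail = 400)
  sim <- run_monodomain(mesh, tissue_params(), prot)
  m <- marker_beat(markers_from_crossings(sim), "S1_1")
  scar <- which(mesh$nodes$region == "SCAR")
  expect_equal(sum(m$electrode %in% scar), 0L)
  # every non-scar node activates (the wave goes around the obstacle)
  nonscar <- which(mesh$nodes$region != "SCAR")
  expect_true(all(nonscar %in% m$electrode[!is.na(m$at)]))
})

test_that("closed-form restitution is monotone and matches the paced model family", {
  ip <- ionic_params()
  di <- seq(20, 600, by = 10)
  apd <- apd_restitution(di, ip)
  expect_true(all(diff(apd) > 0))
  # prolonged plateau scales APD up; slower recovery depresses it at fixed DI
  expect_true(all(apd_restitution(di, ip, tau_close = 2 * ip$tau_close_myo) >
                  apd, na.rm = TRUE))
  expect_true(all(apd_restitution(di, ip, tau_open = 400) < apd))
})

test_that("calibration hits the APD targets and is a fixed point at the defaults", {
  cal <- calibrate_ionic_params()
  expect_equal(cal$tau_close_myo, ionic_params()$tau_close_myo)
  expect_equal(cal$bz_apd_prolongation, ionic_params()$bz_apd_prolongation)
  ip <- ionic_params()
  tp <- tissue_params()
  apd_myo <- rvimap:::strip_apd(cal$tau_close_myo, ip, tp)
  apd_bz <- rvimap:::strip_apd(cal$tau_close_myo * cal$bz_apd_prolongation,
                               ip, tp,
                               tau_open = ip$tau_open * ip$bz_tau_open_scaling)
  expect_lt(abs(apd_myo - 176), 4)
  expect_lt(abs(apd_bz - 229), 9)
  expect_error(calibrate_ionic_params(c(apd_myo = 5, apd_bz = 229)),
               "attainable range")
})

test_that("border-zone variants set the intended parameter fields", {
  tp <- tissue_params()
  hom <- make_bz_variant(tp, "homogeneous")
  expect_equal(hom$ionic$bz_apd_prolongation, 1)
  expect_equal(hom$ionic$bz_tau_open_scaling, 1)
  expect_equal(hom$ionic$bz_sigma_scaling, 1)
  slow <- make_bz_variant(tp, "slow_cv")
  expect_equal(slow$ionic$bz_sigma_scaling, 0.1)
  expect_equal(slow$ionic$bz_apd_prolongation, 1)
  long <- make_bz_variant(tp, "long_apd")
  expect_gt(long$ionic$bz_apd_prolongation, 1)
  expect_error(make_bz_variant(tp, "nonsense"))
  # slow_cv: 0.068 S/m base becomes 0.0068 S/m in the BZ
  expect_equal(slow$sigma * slow$ionic$bz_sigma_scaling, 0.0068)
})

test_that("diffusivity converts conductivity to mm^2/ms", {
  expect_equal(rvimap:::diffusivity(tissue_params()), 0.068 / 1.4,
               tolerance = 1e-12)
})

test_that("traces stay within physiological voltage bounds", {
  mesh <- grid_mesh(26, 26, 0.4)
  grid <- rvimap:::new_recording_grid(
    tibble::tibble(electrode = 1:2, x = c(2, 8), y = c(2, 8)),
    "fixture", mesh = mesh)
  prot <- pacing_protocol(n_s1 = 2, bcl = 400, s2_coupling = NULL, tail = 300)
  sim <- run_monodomain(mesh, tissue_params(), prot, grid = grid)
  vm <- unlist(sim$traces[-1])
  expect_true(all(vm > -100 & vm < 60))
  # both electrodes see both beats
  m <- extract_markers(sim)
  expect_true(all(!is.na(m$at)))
})
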