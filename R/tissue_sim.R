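# Monodomain tissue simulation on the labeled sheet.
#
# The ionic model is a two-variable phenomenological description (fast inward
# current gated by a single recovery variable, slow ungated outward current)
# with an explicit, monotone APD restitution relation. Its parameters are
# calibrated so that steady-state pacing at a basic cycle length of 500 ms
# yields an action potential duration (APD) of ~176 ms in healthy myocardium
# and ~229 ms in the border zone; the border-zone potassium-current
# down-regulation of ionically remodelled tissue is emulated by an APD
# prolongation factor acting on the repolarization time constant together
# with a slowed border-zone recovery of excitability (scaled tau_open), which
# supplies the post-repolarization refractoriness that lets a premature beat
# block at the isthmus mouth instead of merely conducting decrementally.

# Transmembrane-voltage mapping for the dimensionless state variable
VM_REST <- -80   # mV at v = 0
VM_PEAK <- 20    # mV at v = 1
v_to_vm <- function(v) VM_REST + v * (VM_PEAK - VM_REST)
vm_to_v <- function(vm) (vm - VM_REST) / (VM_PEAK - VM_REST)

#' Ionic-model parameters
#'
#' Parameters of the two-variable phenomenological ionic model used by the
#' tissue simulator. `tau_in` and `tau_out` set the upstroke and early
#' repolarization time scales, `tau_open` the post-repolarization recovery of
#' excitability (and hence restitution steepness), and `tau_close` the plateau
#' duration that controls APD. The defaults are calibrated (see
#' [calibrate_ionic_params()]) so that a paced 1D strip at a basic cycle
#' length of 500 ms gives a myocardial APD of 176 ms; `bz_apd_prolongation`
#' scales the border-zone `tau_close` to reach the 229 ms border-zone target,
#' standing in for the down-regulated repolarizing potassium currents of
#' ionically remodelled border-zone myocytes.
#'
#' `bz_tau_open_scaling` slows the border zone's recovery of excitability,
#' the second facet of ionic remodelling: without it, this model family has
#' almost no refractoriness beyond the action potential itself, so a
#' premature wavefront merely slows down inside the long-APD border zone
#' instead of blocking. The default scaling gives the border zone an
#' effective `tau_open` of 400 ms, placing the isthmus block window between
#' coupling intervals of about 240 and 250 ms on a paced myocardium-to-border
#' -zone cable.
#'
#' @param tau_in,tau_out,tau_open,tau_close_myo,v_gate Model time constants
#'   (ms) and gate threshold (dimensionless voltage).
#' @param bz_apd_prolongation Factor applied to `tau_close` in the border
#'   zone (> 1 lengthens the border-zone APD).
#' @param bz_tau_open_scaling Factor applied to `tau_open` in the border zone
#'   (> 1 slows post-repolarization recovery of excitability).
#' @param bz_sigma_scaling Factor applied to the border-zone bulk conductivity
#'   (used by the slow-conduction border-zone variant).
#' @return An object of class `ionic_params`.
#' @export
ionic_params <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                         tau_close_myo = 90.04, v_gate = 0.13,
                         bz_apd_prolongation = 1.448467,
                         bz_tau_open_scaling = 160 / 120,
                         bz_sigma_scaling = 1) {
  stopifnot(tau_in > 0, tau_out > 0, tau_open > 0, tau_close_myo > 0,
            bz_apd_prolongation > 0, bz_tau_open_scaling > 0,
            bz_sigma_scaling > 0)
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close_myo = tau_close_myo, v_gate = v_gate,
                 bz_apd_prolongation = bz_apd_prolongation,
                 bz_tau_open_scaling = bz_tau_open_scaling,
                 bz_sigma_scaling = bz_sigma_scaling),
            class = "ionic_params")
}

#' Tissue-level simulation parameters
#'
#' @param sigma Bulk conductivity, S/m (isotropic; default 0.068).
#' @param beta Surface-to-volume ratio, 1/um (default 0.14).
#' @param cm Membrane capacitance per unit area, uF/cm^2 (default 1).
#' @param ionic An [ionic_params()] object.
#' @param dt Time step in ms (default 0.02); checked against the explicit
#'   stability bound for the mesh resolution before a run starts.
#' @return An object of class `tissue_params`.
#' @details The diffusion coefficient entering the monodomain equation is
#'   `D = sigma / (beta * cm)`; in the units above `D = sigma/(10 * beta * cm)`
#'   mm^2/ms, i.e. 0.0486 mm^2/ms for the defaults.
#' @export
tissue_params <- function(sigma = 0.068, beta = 0.14, cm = 1,
                          ionic = ionic_params(), dt = 0.02) {
  stopifnot(sigma >= 0, beta > 0, cm > 0, dt > 0,
            inherits(ionic, "ionic_params"))
  structure(list(sigma = sigma, beta = beta, cm = cm, ionic = ionic, dt = dt),
            class = "tissue_params")
}

# mm^2/ms
diffusivity <- function(params) params$sigma / (10 * params$beta * params$cm)

#' Derive a border-zone electrophysiology variant
#'
#' The border zone can be remodelled ionically (prolonged APD, the default
#' configuration), structurally (slow conduction: border-zone conductivity
#' reduced by 90%, APD equal to myocardium), or not at all (homogeneous
#' tissue, border zone identical to healthy myocardium).
#'
#' @param params A [tissue_params()] object to derive from.
#' @param variant One of `"long_apd"`, `"slow_cv"`, `"homogeneous"`.
#' @return Modified `tissue_params`.
#' @export
make_bz_variant <- function(params, variant = c("long_apd", "slow_cv",
                                                "homogeneous")) {
  variant <- match.arg(variant)
  ion <- params$ionic
  switch(variant,
    long_apd = { ion$bz_sigma_scaling <- 1 },
    slow_cv = { ion$bz_apd_prolongation <- 1; ion$bz_tau_open_scaling <- 1
                ion$bz_sigma_scaling <- 0.1 },
    homogeneous = { ion$bz_apd_prolongation <- 1; ion$bz_tau_open_scaling <- 1
                    ion$bz_sigma_scaling <- 1 })
  params$ionic <- ion
  params
}

#' S1-S2 pacing protocol
#'
#' A train of `n_s1` baseline stimuli at basic cycle length `bcl`, optionally
#' followed by one premature S2 beat `s2_coupling` ms after the last S1.
#' Stimulation is applied as a transmembrane current to a strip of nodes
#' along the lowermost edge of the sheet.
#'
#' @param n_s1 Number of S1 beats (default 3).
#' @param bcl Basic cycle length, ms (default 500).
#' @param s2_coupling Coupling interval of the premature beat, ms (default
#'   220); `NULL` for steady-state S1 pacing without an S2.
#' @param stim_depth Depth of the stimulated bottom strip, mm (default 2).
#' @param stim_duration Stimulus duration, ms (default 2).
#' @param stim_amplitude Stimulus strength in units of the dimensionless
#'   membrane-state rate (1/ms). The default 0.3 is about 1.5x the diastolic
#'   threshold of the default model.
#' @param tail Time simulated after the final stimulus, ms (default 800,
#'   long enough to capture a full re-entrant cycle).
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(n_s1 = 3, bcl = 500, s2_coupling = 220,
                            stim_depth = 2, stim_duration = 2,
                            stim_amplitude = 0.3, tail = 800) {
  stopifnot(n_s1 >= 1, bcl > 0)
  if (!is.null(s2_coupling) && s2_coupling >= bcl)
    abort("s2_coupling must be shorter than the basic cycle length")
  onsets <- (seq_len(n_s1) - 1) * bcl
  if (!is.null(s2_coupling)) onsets <- c(onsets, onsets[n_s1] + s2_coupling)
  structure(list(n_s1 = n_s1, bcl = bcl, s2_coupling = s2_coupling,
                 stim_onsets = onsets, stim_depth = stim_depth,
                 stim_duration = stim_duration,
                 stim_amplitude = stim_amplitude, tail = tail),
            class = "pacing_protocol")
}

beat_labels <- function(protocol) {
  lb <- paste0("S1_", seq_len(protocol$n_s1))
  if (!is.null(protocol$s2_coupling)) lb <- c(lb, "S2")
  lb
}

#' Run a monodomain simulation on a labeled mesh
#'
#' Explicit finite-difference integration of the monodomain reaction-diffusion
#' equation on the regular grid of a `labeled_mesh`, with harmonic-mean face
#' conductivities and a no-flux condition at the scar interface (scar faces
#' carry zero conductivity). The recovery variable is advanced with its exact
#' per-branch exponential update; voltage uses forward Euler.
#'
#' Threshold crossings of the transmembrane voltage (upward through the
#' activation threshold, downward through the repolarization threshold) are
#' recorded for every node with sub-step linear interpolation, so full-field
#' activation/repolarization maps are available without storing voltage
#' traces. Voltage traces are additionally sampled at the electrodes of
#' `grid`, if given.
#'
#' @param mesh A `labeled_mesh`.
#' @param params [tissue_params()]; the time step is rejected before the run
#'   if it violates the explicit stability bound for the mesh resolution.
#' @param protocol [pacing_protocol()].
#' @param grid Optional `recording_grid`; its host nodes are sampled at
#'   `record_dt` (1 kHz by default).
#' @param record_dt Trace sampling interval, ms.
#' @param snapshot_dt Interval between full-field voltage snapshots, ms;
#'   `NULL` disables snapshots.
#' @param t_total Total simulated time, ms; defaults to the last stimulus
#'   onset plus `protocol$tail`.
#' @param at_threshold,rt_threshold Crossing thresholds, mV.
#' @return An object of class `sim_result` with trace tibble, crossing
#'   records, snapshots, stimulus timeline and a parameter echo.
#' @export
run_monodomain <- function(mesh, params = tissue_params(),
                           protocol = pacing_protocol(), grid = NULL,
                           record_dt = 1, snapshot_dt = NULL, t_total = NULL,
                           at_threshold = -20, rt_threshold = -70) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(params, "tissue_params"),
            inherits(protocol, "pacing_protocol"))
  nd <- mesh$nodes
  N <- nrow(nd)
  ion <- params$ionic
  is_bz <- nd$region == "BZ"
  is_scar <- nd$region == "SCAR"

  D <- rep(diffusivity(params), N)
  D[is_bz] <- D[is_bz] * ion$bz_sigma_scaling
  D[is_scar] <- 0

  tau_close <- rep(ion$tau_close_myo, N)
  tau_close[is_bz] <- ion$tau_close_myo * ion$bz_apd_prolongation
  tau_open <- rep(ion$tau_open, N)
  tau_open[is_bz] <- ion$tau_open * ion$bz_tau_open_scaling

  dt <- params$dt
  dx <- mesh$resolution
  dt_max <- min(dx^2 / (4 * max(D)), ion$tau_in / 10)
  if (dt > dt_max + 1e-12)
    abort(sprintf(
      "time step %.4g ms violates the stability bound %.4g ms for dx = %.3g mm",
      dt, dt_max, dx))

  stim_nodes <- which(nd$y <= protocol$stim_depth + 1e-9 & !is_scar)
  if (!length(stim_nodes)) abort("stimulus region is empty")

  t_total <- t_total %||% (max(protocol$stim_onsets) + protocol$tail)
  n_steps <- as.integer(ceiling(t_total / dt))

  record_nodes <- integer(0)
  record_every <- 0L
  if (!is.null(grid)) {
    record_nodes <- grid$host_node - 1L
    record_every <- max(1L, as.integer(round(record_dt / dt)))
  }
  snapshot_steps <- integer(0)
  if (!is.null(snapshot_dt)) {
    st <- seq(snapshot_dt, t_total, by = snapshot_dt)
    snapshot_steps <- as.integer(round(st / dt)) - 1L
  }

  raw <- .cpp_monodomain(
    mesh$nx, mesh$ny, dx, dt, n_steps,
    D, as.integer(is_scar),
    rep(ion$tau_in, N), rep(ion$tau_out, N), tau_open,
    tau_close, rep(ion$v_gate, N),
    stim_nodes - 1L, protocol$stim_onsets,
    protocol$stim_duration, protocol$stim_amplitude,
    record_nodes, record_every, snapshot_steps,
    vm_to_v(at_threshold), vm_to_v(rt_threshold),
    numeric(0), TRUE)

  traces <- NULL
  if (!is.null(grid)) {
    tm <- v_to_vm(raw$traces)
    colnames(tm) <- paste0("e", grid$electrode)
    traces <- dplyr::bind_cols(tibble(time = raw$trace_times), as_tibble(tm))
  }

  crossings <- tibble(
    node = c(raw$up_node, raw$down_node) + 1L,
    time = c(raw$up_time, raw$down_time),
    type = rep(c("up", "down"), c(length(raw$up_node), length(raw$down_node))))

  snapshots <- NULL
  if (length(snapshot_steps))
    snapshots <- list(times = raw$snapshot_times,
                      vm = v_to_vm(raw$snapshots))

  structure(list(traces = traces, crossings = crossings,
                 snapshots = snapshots,
                 stim_times = protocol$stim_onsets,
                 t_total = n_steps * dt,
                 at_threshold = at_threshold, rt_threshold = rt_threshold,
                 mesh = mesh, grid = grid, params = params,
                 protocol = protocol,
                 v_final = raw$v_final, w_final = raw$w_final),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d nodes, %.0f ms simulated, stimuli at %s ms\n",
              nrow(x$mesh$nodes), x$t_total,
              paste(x$stim_times, collapse = ", ")))
  invisible(x)
}

# internal: paced 1D strip APD of the last beat, used for calibration.
# length_mm strip at the mesh-default resolution; APD measured at the middle
# node from the threshold-crossing records.
strip_apd <- function(tau_close, ion, params, bcl = 500, n_beats = 3,
                      length_mm = 20, resolution = 0.2,
                      tau_open = ion$tau_open) {
  nx <- as.integer(round(length_mm / resolution)) + 1L
  N <- nx
  D <- rep(diffusivity(params), N)
  onsets <- (seq_len(n_beats) - 1) * bcl
  t_total <- max(onsets) + 450
  n_steps <- as.integer(ceiling(t_total / params$dt))
  stim_nodes <- which((seq_len(nx) - 1) * resolution <= 2) - 1L
  raw <- .cpp_monodomain(
    nx, 1L, resolution, params$dt, n_steps,
    D, integer(N),
    rep(ion$tau_in, N), rep(ion$tau_out, N), rep(tau_open, N),
    rep(tau_close, N), rep(ion$v_gate, N),
    stim_nodes, onsets, 2, 0.3,
    integer(0), 0L, integer(0),
    vm_to_v(-20), vm_to_v(-70), numeric(0), TRUE)
  mid <- as.integer(nx / 2) + 1L
  ups <- sort(raw$up_time[raw$up_node + 1L == mid])
  dns <- sort(raw$down_time[raw$down_node + 1L == mid])
  last_on <- max(onsets)
  at <- ups[ups >= last_on][1]
  if (is.na(at)) return(NA_real_)
  rt <- dns[dns > at][1]
  rt - at
}

#' Calibrate the ionic model to APD targets
#'
#' Finds the repolarization time constants that reproduce target action
#' potential durations in a paced 1D tissue strip (3 beats at the given basic
#' cycle length; APD measured on the last beat at the strip midpoint from the
#' -20 mV / -70 mV crossing markers). The APD of the model is monotone in
#' `tau_close`, so a bracketed root search is used; the procedure is fully
#' deterministic. If the current parameters already meet a target to within
#' 0.5 ms they are returned unchanged.
#'
#' @param targets Named numeric: `apd_myo` and `apd_bz`, ms. Defaults to the
#'   study targets 176 and 229 ms.
#' @param bcl Basic cycle length of the calibration pacing, ms.
#' @param base `ionic_params` to start from.
#' @param params `tissue_params` supplying conductivity and time step.
#' @param resolution Strip resolution, mm.
#' @return Calibrated [ionic_params()] (with `bz_apd_prolongation` set to the
#'   ratio of the calibrated border-zone and myocardial `tau_close`).
#' @export
calibrate_ionic_params <- function(targets = c(apd_myo = 176, apd_bz = 229),
                                   bcl = 500, base = ionic_params(),
                                   params = tissue_params(ionic = base),
                                   resolution = 0.2) {
  stopifnot(all(c("apd_myo", "apd_bz") %in% names(targets)),
            all(targets > 0))
  # APD is monotone increasing in tau_close; a strip that loses 1:1 capture
  # at the pacing rate (NA APD) means the APD outgrew the cycle length, so
  # NA at the upper bracket counts as "too long".
  f <- function(tc) {
    a <- strip_apd(tc, base, params, bcl, resolution = resolution,
                   tau_open = tau_open_cur)
    if (is.na(a)) bcl else a - target_cur
  }
  target_cur <- NA_real_
  tau_open_cur <- base$tau_open
  solve_tau <- function(target, tau0, tau_open = base$tau_open) {
    target_cur <<- target
    tau_open_cur <<- tau_open
    f0 <- f(tau0)
    if (is.finite(f0) && abs(f0) < 0.5) return(tau0)
    lo <- 20; hi <- 400
    flo <- f(lo)
    fhi <- f(hi)
    if (!(flo <= 0) || !(fhi >= 0))
      abort(sprintf(
        "APD target %.0f ms is outside the attainable range [%.0f, %.0f] ms at BCL %.0f ms",
        target, flo + target, if (is.finite(fhi)) fhi + target else bcl, bcl))
    uniroot(f, c(lo, hi), tol = 0.05)$root
  }
  tc_myo <- solve_tau(targets[["apd_myo"]], base$tau_close_myo)
  tc_bz <- solve_tau(targets[["apd_bz"]],
                     base$tau_close_myo * base$bz_apd_prolongation,
                     tau_open = base$tau_open * base$bz_tau_open_scaling)
  out <- base
  out$tau_close_myo <- tc_myo
  out$bz_apd_prolongation <- tc_bz / tc_myo
  out
}

#' Closed-form APD restitution of the ionic model
#'
#' For the two-variable model the APD after a diastolic interval `di` has the
#' closed form `tau_close * log((1 - (1 - h_min) * exp(-di / tau_open)) /
#' h_min)` with `h_min = 4 * tau_in / tau_out`, monotonically increasing in
#' `di`. Useful as an analytic cross-check of simulated restitution.
#'
#' @param di Diastolic interval(s), ms.
#' @param ion [ionic_params()].
#' @param tau_close Plateau time constant; defaults to the myocardial value.
#' @param tau_open Recovery time constant; pass the scaled border-zone value
#'   for border-zone restitution.
#' @return APD in ms (NaN where the model cannot sustain an action potential).
#' @export
apd_restitution <- function(di, ion = ionic_params(),
                            tau_close = ion$tau_close_myo,
                            tau_open = ion$tau_open) {
  h_min <- 4 * ion$tau_in / ion$tau_out
  w <- 1 - (1 - h_min) * exp(-di / tau_open)
  ifelse(w > h_min, tau_close * log(w / h_min), NaN)
}
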