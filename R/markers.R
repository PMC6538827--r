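# Activation/repolarization marker extraction and marker-map manipulation.
#
# Activation time (AT): first upward crossing of the activation threshold
# (-20 mV) within a beat window, with linear interpolation between samples.
# Repolarization time (RT): first downward crossing of the repolarization
# threshold (-70 mV) after that AT. Times are beat-relative (ms from the
# beat's own stimulus onset); absolute window onsets travel in an attribute.
# The RT search is not truncated at the window end: a premature S2 can cut
# the last S1 window short of the border-zone repolarization.

new_marker_map <- function(df, at_threshold = -20, rt_threshold = -70,
                           onsets = NULL) {
  out <- as_tibble(df)
  class(out) <- c("marker_map", class(out))
  attr(out, "at_threshold") <- at_threshold
  attr(out, "rt_threshold") <- rt_threshold
  attr(out, "onsets") <- onsets
  out
}

# first crossing of `thr` in direction `dir` ("up"/"down") at times >= from,
# linearly interpolated; NA if none
first_crossing <- function(t, v, thr, dir, from = -Inf, to = Inf) {
  a <- head(v, -1); b <- tail(v, -1)
  hit <- if (dir == "up") a < thr & b >= thr else a > thr & b <= thr
  tc <- head(t, -1) + diff(t) * (thr - a) / (b - a)
  tc <- tc[hit]
  tc <- tc[tc >= from & tc < to]
  if (length(tc)) tc[1] else NA_real_
}

#' Extract activation and repolarization markers from voltage traces
#'
#' Derives per-beat AT and RT for every electrode of a simulation's trace
#' table (or any tibble with a `time` column and one column per electrode).
#' Beat windows run from each stimulus onset to the next; the final window
#' extends to the end of the trace. If re-entry produces multiple activations
#' within a window, the first crossing is taken. Sites without a crossing
#' (scar, no capture) get `NA`.
#'
#' @param traces A `sim_result` or a tibble with columns `time`, `e1`, ...
#'   (mV vs ms, uniformly sampled).
#' @param stim_times Stimulus onsets, ms (taken from the `sim_result` if one
#'   is supplied).
#' @param beats Beat labels, one per window; defaults to `S1_1 ... S1_k, S2`
#'   when the number of windows matches an S1-S2 protocol, else `beat_i`.
#' @param at_threshold,rt_threshold Crossing thresholds, mV.
#' @return A `marker_map` tibble with columns `electrode`, `beat`, `at`, `rt`
#'   (beat-relative ms, `NA` where undefined).
#' @export
extract_markers <- function(traces, stim_times = NULL, beats = NULL,
                            at_threshold = -20, rt_threshold = -70) {
  if (inherits(traces, "sim_result")) {
    stim_times <- stim_times %||% traces$stim_times
    beats <- beats %||% beat_labels(traces$protocol)
    if (is.null(traces$traces))
      abort("this sim_result carries no traces; supply a recording grid to run_monodomain()")
    traces <- traces$traces
  }
  if (is.null(stim_times)) abort("stim_times is required")
  stopifnot(is.data.frame(traces), "time" %in% names(traces))
  tv <- traces$time
  if (any(!is.finite(tv))) abort("non-finite sample times")
  cols <- setdiff(names(traces), "time")
  onsets <- sort(stim_times)
  ends <- c(onsets[-1], Inf)
  if (is.null(beats)) {
    nb <- length(onsets)
    beats <- if (nb == 1) "S1_1" else c(paste0("S1_", seq_len(nb - 1)), "S2")
  }
  stopifnot(length(beats) == length(onsets))

  rows <- purrr::imap(cols, function(cl, k) {
    v <- traces[[cl]]
    if (any(!is.finite(v))) abort(sprintf("non-finite samples in trace %s", cl))
    el <- as.integer(sub("^e", "", cl))
    if (is.na(el)) el <- k
    purrr::map2_dfr(onsets, seq_along(onsets), function(on, b) {
      at_abs <- first_crossing(tv, v, at_threshold, "up", on, ends[b])
      rt_abs <- if (is.na(at_abs)) NA_real_ else
        first_crossing(tv, v, rt_threshold, "down", at_abs)
      tibble(electrode = el, beat = beats[b],
             at = at_abs - on, rt = rt_abs - on)
    })
  })
  new_marker_map(bind_rows(rows), at_threshold, rt_threshold,
                 onsets = setNames(onsets, beats))
}

#' Full-field markers from a simulation's crossing records
#'
#' Builds a per-node marker map for every beat window from the threshold
#' crossings the solver records at native time-step resolution, using the
#' same rules as [extract_markers()] (first upward crossing in the window;
#' first downward crossing after it). This is the high-density-grid analogue
#' of trace-based extraction: every mesh node acts as a recording electrode.
#'
#' @param sim A `sim_result`.
#' @param beats Optional beat labels (defaults as in [extract_markers()]).
#' @return A `marker_map` with `electrode` equal to the mesh node index.
#' @export
markers_from_crossings <- function(sim, beats = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  onsets <- sort(sim$stim_times)
  nb <- length(onsets)
  beats <- beats %||% beat_labels(sim$protocol)
  stopifnot(length(beats) == nb)
  ends <- c(onsets[-1], Inf)

  cr <- sim$crossings
  ups <- cr[cr$type == "up", ]
  dns <- cr[cr$type == "down", ]
  N <- nrow(sim$mesh$nodes)
  dn_by_node <- split(dns$time, factor(dns$node, levels = seq_len(N)))
  dn_by_node <- lapply(dn_by_node, sort)

  maps <- purrr::map2_dfr(seq_len(nb), beats, function(b, lb) {
    sel <- ups$time >= onsets[b] & ups$time < ends[b]
    u <- ups[sel, ]
    # first activation per node in this window
    o <- order(u$node, u$time)
    u <- u[o, ]
    first <- !duplicated(u$node)
    at_abs <- u$time[first]
    nodev <- u$node[first]
    rt_abs <- vapply(seq_along(nodev), function(q) {
      d <- dn_by_node[[nodev[q]]]
      d <- d[d > at_abs[q]]
      if (length(d)) d[1] else NA_real_
    }, numeric(1))
    tibble(electrode = nodev, beat = lb,
           at = at_abs - onsets[b], rt = rt_abs - onsets[b])
  })
  new_marker_map(maps, sim$at_threshold, sim$rt_threshold,
                 onsets = setNames(onsets, beats))
}

#' Add Gaussian measurement noise to a marker map
#'
#' Perturbs every defined AT and RT independently with zero-mean Gaussian
#' noise, emulating marker uncertainty on catheter recordings. Undefined
#' entries stay undefined; the operation is reproducible under a fixed seed.
#'
#' @param map A `marker_map`.
#' @param sd_at,sd_rt Noise standard deviations, ms (default 5).
#' @param seed Integer seed.
#' @return A `marker_map`.
#' @export
add_marker_noise <- function(map, sd_at = 5, sd_rt = 5, seed = NULL) {
  stopifnot(sd_at >= 0, sd_rt >= 0)
  if (sd_at == 0 && sd_rt == 0) return(map)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  # draw noise in canonical (electrode, beat) order so the perturbation a
  # given marker receives does not depend on row order
  ord <- order(map$electrode, map$beat)
  eps_at <- rnorm(nrow(map), 0, sd_at)
  eps_rt <- rnorm(nrow(map), 0, sd_rt)
  map$at[ord] <- map$at[ord] + eps_at * !is.na(map$at[ord])
  map$rt[ord] <- map$rt[ord] + eps_rt * !is.na(map$rt[ord])
  map
}

#' Activation and APD restitution difference maps
#'
#' Per-electrode differences between a premature (S2) and a baseline (S1)
#' beat: `d_at = AT_S2 - AT_S1` (each beat-relative to its own stimulus) and
#' `d_apd = APD_S2 - APD_S1`. Positive `d_at` marks conduction slowing of the
#' premature beat; negative `d_apd` marks restitution-driven APD shortening.
#' Undefined markers propagate to `NA`.
#'
#' @param s1,s2 `marker_map`s (single beat each) on the same electrode set.
#' @return Tibble with `electrode`, `d_at`, `d_apd`.
#' @export
restitution_difference_maps <- function(s1, s2) {
  if (length(unique(s1$beat)) != 1 || length(unique(s2$beat)) != 1)
    abort("s1 and s2 must each contain a single beat; filter first")
  if (!setequal(s1$electrode, s2$electrode))
    abort("s1 and s2 must share the same electrode set")
  m2 <- s2[match(s1$electrode, s2$electrode), ]
  tibble(electrode = s1$electrode,
         d_at = m2$at - s1$at,
         d_apd = (m2$rt - m2$at) - (s1$rt - s1$at))
}

#' Select one beat from a marker map
#'
#' @param map A `marker_map`.
#' @param beat Beat label, e.g. `"S2"`.
#' @return The single-beat `marker_map`.
#' @export
marker_beat <- function(map, beat) {
  stopifnot(beat %in% map$beat)
  out <- map[map$beat == beat, ]
  new_marker_map(out, attr(map, "at_threshold"), attr(map, "rt_threshold"),
                 attr(map, "onsets"))
}
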