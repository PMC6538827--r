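# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an RVI map into a plain tibble
#' @param x An `rvi_map`.
#' @param ... Unused.
#' @return A tibble with one row per site, plus `method` and `radius` columns.
#' @export
tidy.rvi_map <- function(x, ...) {
  out <- as_tibble(x)
  out$method <- attr(x, "method")
  out$radius <- attr(x, "radius")
  out
}

#' One-row summary of an RVI map
#' @param x An `rvi_map`.
#' @param ... Unused.
#' @return One-row tibble: method, radius, site counts, vulnerable-region
#'   size and lowest RVI at the configured threshold.
#' @export
glance.rvi_map <- function(x, ...) {
  q <- quantify_vulnerable_region(x)
  dplyr::bind_cols(tibble(method = attr(x, "method"),
                          radius = attr(x, "radius"),
                          threshold = attr(x, "threshold")), q)
}

#' Tidy simulation traces into long format
#' @param x A `sim_result` with recorded traces.
#' @param ... Unused.
#' @return Tibble with `time`, `electrode`, `vm`.
#' @export
tidy.sim_result <- function(x, ...) {
  if (is.null(x$traces)) abort("sim_result has no traces")
  tidyr::pivot_longer(x$traces, -"time", names_to = "electrode",
                      values_to = "vm", names_prefix = "e",
                      names_transform = as.integer)
}

#' One-row summary of a simulation
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return One-row tibble with node counts, simulated time, stimulus count
#'   and activation counts.
#' @export
glance.sim_result <- function(x, ...) {
  tibble(n_nodes = nrow(x$mesh$nodes),
         n_scar = sum(x$mesh$nodes$region == "SCAR"),
         t_total = x$t_total,
         n_stimuli = length(x$stim_times),
         n_activations = sum(x$crossings$type == "up"))
}
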