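# Analytic activation/repolarization fields.
#
# These closed-form marker generators exercise the RVI core without running
# the tissue simulator: a planar wave with uniform APD, and an idealized line
# of block where the distal side activates after a fixed detour delay. The
# detour delay is a free parameter (not derived from path length and
# conduction velocity), which keeps every derived quantity closed-form.

#' Synthetic planar-wave marker field
#'
#' A plane wave travelling along `direction` at conduction velocity `cv` with
#' uniform action potential duration: `AT = (p . direction) / cv`,
#' `RT = AT + apd`. Any downstream pair then has
#' `RVI = apd - (AT_j - AT_i)`, so a minimum-interpolation map with search
#' radius R approaches `apd - R/cv` at interior sites.
#'
#' @param grid A `recording_grid` (or any tibble with `electrode`, `x`, `y`).
#' @param cv Conduction velocity, mm/ms (default 0.5).
#' @param apd Action potential duration, ms (default 200).
#' @param direction Propagation direction (default vertical).
#' @return A single-beat `marker_map` labeled `"SYN"`.
#' @export
planar_wave_field <- function(grid, cv = 0.5, apd = 200, direction = c(0, 1)) {
  stopifnot(cv > 0, apd >= 0)
  u <- direction / sqrt(sum(direction^2))
  at <- (grid$x * u[1] + grid$y * u[2]) / cv
  new_marker_map(tibble(electrode = grid$electrode, beat = "SYN",
                        at = at, rt = at + apd))
}

#' Synthetic line-of-block marker field
#'
#' A plane wave travelling upward at `cv` meets a horizontal line of block at
#' `block_y` spanning `block_x[1] <= x <= block_x[2]`. Sites beyond the line
#' (and within its x-extent) activate late, after the wavefront's detour
#' around the line: their AT is delayed by `at_offset`. Everywhere
#' `RT = AT + apd` (plus an optional linear repolarization gradient). Adjacent
#' pairs spanning the line then have `RVI = apd - at_offset` (up to their
#' separation over `cv`), so choosing `at_offset > apd` creates a strip of
#' negative RVI just proximal to the line — the analytic stand-in for a
#' re-entry-vulnerable region. [analytic_negative_strip()] gives its
#' closed-form extent for a given search radius.
#'
#' @inheritParams planar_wave_field
#' @param block_y Height of the block line, mm.
#' @param block_x Length-2 x-extent of the block line, mm.
#' @param at_offset Detour delay of the distal side, ms (default 260).
#' @param rt_gradient Optional repolarization gradient along y, ms/mm.
#' @return A single-beat `marker_map` labeled `"SYN"`, with the block
#'   geometry attached as attribute `"block"`.
#' @export
line_of_block_field <- function(grid, cv = 0.5, apd = 200, block_y = 20,
                                block_x = c(10, 30), at_offset = 260,
                                rt_gradient = 0) {
  stopifnot(cv > 0, apd > 0)
  distal <- grid$y > block_y & grid$x >= block_x[1] & grid$x <= block_x[2]
  at <- grid$y / cv + at_offset * distal
  rt <- at + apd + rt_gradient * grid$y
  out <- new_marker_map(tibble(electrode = grid$electrode, beat = "SYN",
                               at = at, rt = rt))
  attr(out, "block") <- list(cv = cv, apd = apd, block_y = block_y,
                             block_x = block_x, at_offset = at_offset)
  out
}

#' Analytic extent of the negative-RVI region of a line-of-block field
#'
#' The late-activating "block shadow" is the half-open rectangle beyond the
#' line and within its x-extent. Any site outside the shadow that can reach a
#' shadow site within the search radius R has a downstream pair of value
#' `apd - at_offset` or lower (a shadow neighbour further along the
#' propagation direction lowers it by the extra distance over `cv`, down to
#' `apd - at_offset - R/cv` for a site directly under the line). Whenever
#' `apd - at_offset < threshold`, the sub-threshold region is therefore
#' exactly the R-neighbourhood of the shadow, excluding the shadow itself:
#' the strip of width R proximal to the line plus flank bands of width R
#' along the shadow's sides. Shadow-interior sites pair only with deeper
#' shadow sites (plain plane-wave pairs) and stay at `apd` minus a small
#' positive activation difference, so they are not flagged.
#'
#' @param field A marker map from [line_of_block_field()] (or its `"block"`
#'   attribute as a list).
#' @param radius Search radius R, mm.
#' @param threshold Vulnerability threshold, ms (default 50).
#' @return A list with `strip` (the canonical proximal rectangle `xmin`,
#'   `xmax`, `ymin`, `ymax`, `NULL` when not sub-threshold), `contains` (a
#'   vectorized predicate `function(x, y)` for the full analytic region
#'   including the flank bands) and `min_rvi`, the attainable minimum.
#' @export
analytic_negative_strip <- function(field, radius, threshold = 50) {
  b <- if (is.list(field) && !is.data.frame(field)) field
       else attr(field, "block")
  if (is.null(b)) abort("field carries no block geometry")
  min_rvi <- b$apd - b$at_offset - radius / b$cv
  sub <- (b$apd - b$at_offset) < threshold
  rect <- NULL
  contains <- function(x, y) rep(FALSE, length(x))
  if (sub) {
    rect <- list(xmin = b$block_x[1], xmax = b$block_x[2],
                 ymin = b$block_y - radius, ymax = b$block_y)
    contains <- function(x, y) {
      in_shadow <- y > b$block_y & x >= b$block_x[1] & x <= b$block_x[2]
      dx <- pmax(b$block_x[1] - x, x - b$block_x[2], 0)
      dy <- pmax(b$block_y - y, 0)
      !in_shadow & dx^2 + dy^2 <= radius^2
    }
  }
  list(strip = rect, contains = contains, min_rvi = min_rvi)
}
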