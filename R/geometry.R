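#' Specify an idealized two-dimensional infarct sheet
#'
#' Describes a square sheet of cardiac tissue containing an idealized chronic
#' infarct: a circular necrotic scar cut by a straight conducting isthmus, the
#' whole surrounded by a thin border-zone (BZ) rim of electrically remodelled
#' but viable tissue. The default values give a 40 x 40 mm sheet at 0.2 mm
#' resolution with a 15 mm scar radius, a 15.5 mm BZ radius (0.5 mm rim) and a
#' 4 mm wide isthmus, the canonical configuration used throughout the package.
#'
#' The scar is constructed as the disc of radius `scar_radius` around `center`
#' minus an open straight band of width `isthmus_width` through the center,
#' oriented along `isthmus_axis` (vertical by default). The band interior is
#' border zone, as is the rim between `scar_radius` and `bz_radius`.
#'
#' @param sheet_size Numeric length-2, sheet extent in mm (default `c(40, 40)`).
#' @param resolution Grid spacing in mm; must divide both sheet dimensions.
#' @param center Infarct center in mm; defaults to the sheet center.
#' @param scar_radius,bz_radius Scar and border-zone radii in mm.
#' @param isthmus_width Width of the conducting channel through the scar, mm.
#'   `0` gives a solid scar disc with no channel.
#' @param isthmus_axis Unit direction of the channel (default vertical).
#' @return An object of class `infarct_spec`.
#' @seealso [build_idealized_infarct_sheet()]
#' @export
infarct_spec <- function(sheet_size = c(40, 40), resolution = 0.2,
                         center = NULL, scar_radius = 15, bz_radius = 15.5,
                         isthmus_width = 4, isthmus_axis = c(0, 1)) {
  if (length(sheet_size) == 1) sheet_size <- rep(sheet_size, 2)
  center <- center %||% (sheet_size / 2)
  if (resolution <= 0) abort("`resolution` must be positive.")
  if (bz_radius < scar_radius) abort("`bz_radius` must be >= `scar_radius`.")
  if (isthmus_width < 0) abort("`isthmus_width` must be >= 0.")
  if (isthmus_width > 2 * scar_radius)
    abort("`isthmus_width` exceeds the scar diameter: no scar would remain.")
  ncellx <- sheet_size[1] / resolution
  ncelly <- sheet_size[2] / resolution
  if (abs(ncellx - round(ncellx)) > 1e-8 || abs(ncelly - round(ncelly)) > 1e-8)
    abort("`resolution` must divide both sheet dimensions exactly.")
  if (any(center - bz_radius < -1e-9) ||
      any(center + bz_radius > sheet_size + 1e-9))
    abort("The sheet must contain the full border-zone disc.")
  axis <- isthmus_axis / sqrt(sum(isthmus_axis^2))
  structure(
    list(sheet_size = sheet_size, resolution = resolution, center = center,
         scar_radius = scar_radius, bz_radius = bz_radius,
         isthmus_width = isthmus_width, isthmus_axis = axis),
    class = "infarct_spec")
}

#' Build the labeled finite-difference mesh for an idealized infarct sheet
#'
#' Discretizes the sheet described by an [infarct_spec()] into a regular grid
#' of quadrilateral elements and labels every node `MYO` (healthy myocardium),
#' `BZ` (border zone) or `SCAR` (necrotic, non-conducting). Labeling is
#' node-wise; an element is scar tissue iff all four of its nodes are scar,
#' which is the convention the tissue simulator's no-flux treatment relies on.
#'
#' Each node carries an associated area: `resolution^2` for interior nodes,
#' with edge and corner nodes taking their clipped share, so node areas sum
#' exactly to the sheet area. Region-size statistics are defined in terms of
#' these nodal areas.
#'
#' @param spec An [infarct_spec()].
#' @return An object of class `labeled_mesh`: a list with
#'   * `nodes`: tibble with `node`, `x`, `y`, `region`, `area`;
#'   * `elements`: integer matrix (one row per quadrilateral, 1-based nodes);
#'   * `nx`, `ny`, `resolution`, `spec`.
#' @examples
#' mesh <- build_idealized_infarct_sheet(infarct_spec())
#' nrow(mesh$elements)        # 40,000 quadrilateral elements
#' table(mesh$nodes$region)
#' @export
build_idealized_infarct_sheet <- function(spec = infarct_spec()) {
  stopifnot(inherits(spec, "infarct_spec"))
  res <- spec$resolution
  nx <- as.integer(round(spec$sheet_size[1] / res)) + 1L
  ny <- as.integer(round(spec$sheet_size[2] / res)) + 1L
  x <- rep((seq_len(nx) - 1) * res, times = ny)
  y <- rep((seq_len(ny) - 1) * res, each = nx)

  dxc <- x - spec$center[1]
  dyc <- y - spec$center[2]
  r <- sqrt(dxc^2 + dyc^2)
  # perpendicular distance to the isthmus axis through the center
  ax <- spec$isthmus_axis
  d_perp <- abs(dxc * ax[2] - dyc * ax[1])

  scar <- r <= spec$scar_radius & d_perp >= spec$isthmus_width / 2
  bz <- !scar & r <= spec$bz_radius
  region <- ifelse(scar, "SCAR", ifelse(bz, "BZ", "MYO"))

  wx <- rep(res, nx); wx[c(1, nx)] <- res / 2
  wy <- rep(res, ny); wy[c(1, ny)] <- res / 2
  area <- rep(wy, each = nx) * rep(wx, times = ny)

  nodes <- tibble(node = seq_len(nx * ny), x = x, y = y,
                  region = region, area = area)

  # quadrilateral connectivity, counter-clockwise
  ci <- rep(seq_len(nx - 1), times = ny - 1)
  cj <- rep(seq_len(ny - 1), each = nx - 1)
  ll <- (cj - 1L) * nx + ci
  elements <- cbind(ll, ll + 1L, ll + nx + 1L, ll + nx)
  colnames(elements) <- NULL

  structure(list(nodes = nodes, elements = elements,
                 nx = nx, ny = ny, resolution = res, spec = spec),
            class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("<labeled_mesh> %d x %d nodes (%.3g mm), %d quad elements\n",
              x$nx, x$ny, x$resolution, nrow(x$elements)))
  print(table(x$nodes$region))
  invisible(x)
}

#' Identify the nodes inside the conducting isthmus
#'
#' The isthmus is the border-zone channel between the two scar segments:
#' nodes within `scar_radius` of the infarct center whose perpendicular
#' distance to the isthmus axis is less than half the channel width.
#'
#' @param mesh A `labeled_mesh` built by [build_idealized_infarct_sheet()].
#' @return Integer vector of node indices.
#' @export
isthmus_nodes <- function(mesh) {
  spec <- mesh$spec
  nd <- mesh$nodes
  dxc <- nd$x - spec$center[1]
  dyc <- nd$y - spec$center[2]
  r <- sqrt(dxc^2 + dyc^2)
  ax <- spec$isthmus_axis
  d_perp <- abs(dxc * ax[2] - dyc * ax[1])
  which(nd$region == "BZ" & r <= spec$scar_radius &
          d_perp < spec$isthmus_width / 2)
}

# nearest mesh node for arbitrary points on the regular grid; exact halfway
# ties resolve to the lower node index
nearest_node <- function(mesh, px, py) {
  res <- mesh$resolution
  i <- pmin(pmax(ceiling(px / res - 0.5), 0), mesh$nx - 1L)
  j <- pmin(pmax(ceiling(py / res - 0.5), 0), mesh$ny - 1L)
  as.integer(j) * mesh$nx + as.integer(i) + 1L
}

new_recording_grid <- function(df, kind, seed = NULL, mesh = NULL) {
  if (!is.null(mesh)) {
    df$host_node <- nearest_node(mesh, df$x, df$y)
    df$on_scar <- mesh$nodes$region[df$host_node] == "SCAR"
    d <- sqrt((df$x - mesh$nodes$x[df$host_node])^2 +
                (df$y - mesh$nodes$y[df$host_node])^2)
    if (any(d > mesh$resolution + 1e-9))
      abort("electrode further than one grid step from its host node")
  }
  out <- as_tibble(df)
  class(out) <- c("recording_grid", class(out))
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  out
}

check_in_bbox <- function(px, py, mesh) {
  xmax <- (mesh$nx - 1) * mesh$resolution
  ymax <- (mesh$ny - 1) * mesh$resolution
  bad <- which(px < -1e-9 | px > xmax + 1e-9 | py < -1e-9 | py > ymax + 1e-9)
  if (length(bad))
    abort(sprintf("electrode %d falls outside the mesh bounding box", bad[1]))
}

#' Place a linear (decapolar-style) recording catheter
#'
#' Lays electrodes along a straight line starting at `origin`, with
#' consecutive gaps given by `spacing_pattern`. The default pattern is the
#' clinical decapolar "2-8-2 mm" arrangement expanded to its nine alternating
#' gaps: five bipolar pairs 2 mm apart with 8 mm between pairs, i.e. 10
#' electrodes spanning 42 mm.
#'
#' @param mesh A `labeled_mesh`; electrodes must fall inside its bounding box
#'   and are snapped to their nearest mesh node as host.
#' @param origin Numeric length-2, position of the first electrode (mm).
#' @param direction Direction of the catheter (need not be normalized).
#' @param spacing_pattern Positive gaps between consecutive electrodes (mm).
#'   An empty pattern gives a single electrode at `origin`.
#' @return A `recording_grid` tibble with columns `electrode`, `x`, `y`,
#'   `cluster`, `host_node`, `on_scar`.
#' @export
place_decapolar <- function(mesh, origin, direction = c(0, 1),
                            spacing_pattern = c(2, 8, 2, 8, 2, 8, 2, 8, 2)) {
  if (length(spacing_pattern) && any(spacing_pattern <= 0))
    abort("spacing_pattern entries must be positive")
  u <- direction / sqrt(sum(direction^2))
  s <- cumsum(c(0, spacing_pattern))
  px <- origin[1] + s * u[1]
  py <- origin[2] + s * u[2]
  check_in_bbox(px, py, mesh)
  new_recording_grid(
    tibble(electrode = seq_along(s), x = px, y = py, cluster = 1L),
    kind = "decapolar", mesh = mesh)
}

#' Place catheters in a fan-like arrangement
#'
#' Several linear catheters share an origin and fan out at the given angles
#' (degrees, measured from `direction`). Each arm reproduces the decapolar
#' spacing pattern along its own direction, so a single arm at angle 0 is
#' identical to [place_decapolar()]. The exact fan geometry used in clinical
#' practice varies; arms are fully configurable here.
#'
#' @inheritParams place_decapolar
#' @param arm_angles Distinct arm angles in degrees.
#' @return A `recording_grid`; `cluster` identifies the arm.
#' @export
place_fan <- function(mesh, origin, arm_angles = c(-30, 0, 30),
                      direction = c(0, 1),
                      spacing_pattern = c(2, 8, 2, 8, 2, 8, 2, 8, 2)) {
  if (anyDuplicated(arm_angles)) abort("arm_angles must be distinct")
  arms <- purrr::imap(arm_angles, function(a, k) {
    th <- a * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    g <- place_decapolar(mesh, origin, as.numeric(rot %*% direction),
                         spacing_pattern)
    g$cluster <- as.integer(k)
    g
  })
  out <- bind_rows(arms)
  out$electrode <- seq_len(nrow(out))
  new_recording_grid(as.data.frame(out), kind = "fan", mesh = mesh)
}

#' Place random multipolar-catheter clusters
#'
#' Emulates data collection with a roving multipolar catheter: `n_clusters`
#' cluster centers are sampled uniformly without replacement from the mesh
#' nodes, and each cluster records from a random `node_fraction` of the nodes
#' within `cluster_radius` of its center. Fully reproducible under a fixed
#' seed. Electrodes landing on scar are flagged; they yield no markers.
#'
#' @inheritParams place_decapolar
#' @param n_clusters Number of catheter placements (default 50).
#' @param cluster_radius Cluster radius in mm (default 1.5).
#' @param node_fraction Fraction of in-radius nodes recorded (default 0.05).
#' @param seed Integer seed.
#' @return A `recording_grid`; `cluster` identifies the placement.
#' @export
place_multipolar_random <- function(mesh, n_clusters = 50,
                                    cluster_radius = 1.5,
                                    node_fraction = 0.05, seed = NULL) {
  if (node_fraction <= 0 || node_fraction > 1)
    abort("node_fraction must be in (0, 1]")
  nd <- mesh$nodes
  if (n_clusters > nrow(nd)) abort("n_clusters exceeds the node count")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  centers <- sample(nrow(nd), n_clusters)
  parts <- purrr::imap(centers, function(cn, k) {
    d2 <- (nd$x - nd$x[cn])^2 + (nd$y - nd$y[cn])^2
    ball <- which(d2 <= cluster_radius^2)
    take <- ceiling(node_fraction * length(ball))
    picked <- sort(ball[sample(length(ball), take)])
    tibble(x = nd$x[picked], y = nd$y[picked], cluster = as.integer(k))
  })
  out <- bind_rows(parts)
  out$electrode <- seq_len(nrow(out))
  new_recording_grid(as.data.frame(out[, c("electrode", "x", "y", "cluster")]),
                     kind = "multipolar_random", seed = seed, mesh = mesh)
}

#' High-density recording grid: every mesh node is an electrode
#'
#' @param mesh A `labeled_mesh`.
#' @return A `recording_grid` with one electrode per mesh node.
#' @export
place_high_density <- function(mesh) {
  nd <- mesh$nodes
  new_recording_grid(
    tibble(electrode = nd$node, x = nd$x, y = nd$y, cluster = 1L),
    kind = "high_density", mesh = mesh)
}
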