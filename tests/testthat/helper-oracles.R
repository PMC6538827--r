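# Independent brute-force oracles used across the RVI tests. These share no
# code with the package: plain double loops over all ordered pairs.

# all downstream pairs (i, j): both ATs defined, at[j] > at[i], dist <= R
brute_pairs <- function(pos, at, R) {
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(n)) {
    if (is.na(at[i])) next
    for (j in seq_len(n)) {
      if (i == j || is.na(at[j])) next
      if (!(at[j] > at[i])) next
      d <- sqrt(sum((pos[j, ] - pos[i, ])^2))
      if (d <= R) out[[length(out) + 1]] <- c(i = i, j = j, dist = d)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      dist = numeric()))
  as.data.frame(do.call(rbind, out))
}

# electrode-indexed minimum/average maps by brute force
brute_map <- function(pos, at, rt, R, method) {
  pr <- brute_pairs(pos, at, R)
  n <- nrow(pos)
  val <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    js <- pr$j[pr$i == i]
    if (!length(js) || is.na(rt[i])) next
    rvis <- rt[i] - at[js]
    val[i] <- if (method == "minimum") min(rvis) else mean(rvis)
  }
  val
}

# node-indexed nearest-neighbour map by brute force on a regular grid with
# origin 0, spacing res, nx-by-ny nodes; halfway ties go to the lower index
brute_nn_map <- function(pos, at, rt, R, res, nx, ny) {
  pr <- brute_pairs(pos, at, R)
  acc <- list(sum = rep(0, nx * ny), n = rep(0L, nx * ny))
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    if (is.na(rt[i])) next
    mid <- (pos[i, ] + pos[j, ]) / 2
    gi <- min(max(ceiling(mid[1] / res - 0.5), 0), nx - 1)
    gj <- min(max(ceiling(mid[2] / res - 0.5), 0), ny - 1)
    node <- gj * nx + gi + 1
    acc$sum[node] <- acc$sum[node] + (rt[i] - at[j])
    acc$n[node] <- acc$n[node] + 1L
  }
  ifelse(acc$n > 0, acc$sum / acc$n, NA_real_)
}

# a plain labeled_mesh fixture for nearest-neighbour tests: bare regular grid
grid_mesh <- function(nx, ny, res) {
  x <- rep((seq_len(nx) - 1) * res, times = ny)
  y <- rep((seq_len(ny) - 1) * res, each = nx)
  wx <- rep(res, nx); wx[c(1, nx)] <- res / 2
  wy <- rep(res, ny); wy[c(1, ny)] <- res / 2
  structure(list(
    nodes = tibble::tibble(node = seq_len(nx * ny), x = x, y = y,
                           region = "MYO",
                           area = rep(wy, each = nx) * rep(wx, times = ny)),
    elements = matrix(integer(), 0, 4), nx = nx, ny = ny, resolution = res),
    class = "labeled_mesh")
}

# marker map fixture from explicit vectors
make_markers <- function(at, rt, beat = "SYN") {
  rvimap:::new_marker_map(
    tibble::tibble(electrode = seq_along(at), beat = beat, at = at, rt = rt))
}

# recording grid fixture from explicit positions (no host mesh)
make_grid <- function(x, y, z = NULL) {
  df <- tibble::tibble(electrode = seq_along(x), x = x, y = y)
  if (!is.null(z)) df$z <- z
  rvimap:::new_recording_grid(df, kind = "fixture")
}
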