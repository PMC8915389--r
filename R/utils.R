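# Internal geometry helpers shared across modules.

#' Minimum-image displacement components
#'
#' Wraps per-axis displacement components into (-L/2, L/2] for an orthorhombic
#' box. With `box = NULL` the displacements are returned unchanged.
#' @noRd
min_image <- function(d, box_len) {
  if (is.null(box_len) || !is.finite(box_len)) return(d)
  d - box_len * round(d / box_len)
}

#' All pairwise distances between two coordinate sets
#'
#' @param a,b numeric matrices (n x 3), Angstrom.
#' @param box numeric length-3 box edges or NULL (no periodicity).
#' @param chunk rows of `a` processed per block to bound memory.
#' @return numeric matrix nrow(a) x nrow(b) of distances.
#' @noRd
pair_dists <- function(a, b, box = NULL, chunk = 500L) {
  a <- coord_matrix(a); b <- coord_matrix(b)
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  i <- 1L
  while (i <= na) {
    j <- min(na, i + chunk - 1L)
    dx <- outer(a[i:j, 1L], b[, 1L], "-")
    dy <- outer(a[i:j, 2L], b[, 2L], "-")
    dz <- outer(a[i:j, 3L], b[, 3L], "-")
    if (!is.null(box)) {
      dx <- min_image(dx, box[1L])
      dy <- min_image(dy, box[2L])
      dz <- min_image(dz, box[3L])
    }
    out[i:j, ] <- sqrt(dx * dx + dy * dy + dz * dz)
    i <- j + 1L
  }
  out
}

# Distance from each row of `a` to the nearest row of `b`.
min_dist_to_set <- function(a, b, box = NULL) {
  d <- pair_dists(a, b, box)
  apply(d, 1L, min)
}

coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  storage.mode(x) <- "double"
  x
}

# Angle (degrees, folded to [0, 90]) between two 3-vectors.
axis_angle_deg <- function(u, v) {
  cu <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  cu <- min(1, max(-1, abs(cu)))
  acos(cu) * 180 / pi
}

# Uniform random rotation matrix (Arvo / quaternion method).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

# Centered moving average; ends use the shorter available window.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dnacage <- function(...) stop(sprintf(...), call. = FALSE)
warn_dnacage <- function(...) warning(sprintf(...), call. = FALSE)
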