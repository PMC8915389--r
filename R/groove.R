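# Minor/major groove widths per base pair from cross-strand phosphate
# geometry (El Hassan-Calladine style register search), and periodicity of
# groove-width minima along a duplex.
#
# For base pair i, the minor-groove width is the shortest distance between
# the strand-I phosphate at bp i and a strand-II phosphate at bp i + k with
# k inside the minor-groove register window; the major width uses the
# opposite register window. The windows (half-width 3, centered at the
# offsets a uniform B-DNA helix selects) never contain the same pair. Raw
# P-P distances are reported by default; `subtract_vdw` removes the
# conventional 5.8 A phosphate van der Waals correction.

MINOR_REGISTER <- 0:6     # strand-II bp offset window across the minor groove
MAJOR_REGISTER <- -8:-2   # ... across the major groove

#' Minor and major groove widths per base pair
#'
#' @param traj a `"trajectory"`.
#' @param duplex a `"duplex"` with phosphates on both strands.
#' @param subtract_vdw subtract 5.8 A (two phosphate van der Waals radii)
#'   from the raw P-P distances (default FALSE: raw distances).
#' @return object of class `"groove_profile"`: data.frame with per-bp
#'   `minor_width`, `minor_sd`, `major_width`, `major_sd` (Angstrom; mean
#'   and sd over frames; NA where the register is undefined, e.g. terminal
#'   base pairs).
#' @export
groove_widths <- function(traj, duplex, subtract_vdw = FALSE) {
  nbp <- n_bp(duplex)
  if (nbp < 6L) stop_dnacage("groove registers undefined for < 6 bp")
  sys <- traj$topology
  pI <- duplex$phos$I
  pII <- duplex$phos$II
  rowI <- match(pI$P, sys$atoms$atom_id)    # indexed by bp via pI$bp
  rowII <- match(pII$P, sys$atoms$atom_id)
  bpI <- pI$bp; bpII <- pII$bp
  nf <- n_frames(traj)
  minor <- matrix(NA_real_, nbp, nf)
  major <- matrix(NA_real_, nbp, nf)
  for (f in seq_len(nf)) {
    fx <- frame_xyz(traj, f)
    okI <- which(!is.na(rowI))
    okII <- which(!is.na(rowII))
    d <- pair_dists(fx[rowI[okI], , drop = FALSE],
                    fx[rowII[okII], , drop = FALSE], sys$box)
    for (ii in seq_along(okI)) {
      b <- bpI[okI[ii]]
      offs <- bpII[okII] - b
      sel_min <- offs %in% MINOR_REGISTER
      sel_maj <- offs %in% MAJOR_REGISTER
      # width is defined only where the register's central offset exists;
      # truncated terminal windows would otherwise report spurious values
      if (any(sel_min) && any(offs == 3L)) minor[b, f] <- min(d[ii, sel_min])
      if (any(sel_maj) && any(offs == -5L)) major[b, f] <- min(d[ii, sel_maj])
    }
  }
  corr <- if (subtract_vdw) 5.8 else 0
  prof <- data.frame(
    bp = seq_len(nbp),
    base_pair = paste0(strsplit(duplex$sequence, "")[[1L]], ":",
                       complement_base(strsplit(duplex$sequence, "")[[1L]])),
    minor_width = rowMeans(minor) - corr,
    minor_sd = apply(minor, 1L, stats::sd),
    major_width = rowMeans(major) - corr,
    major_sd = apply(major, 1L, stats::sd)
  )
  structure(list(profile = prof, n_frames = nf, subtract_vdw = subtract_vdw,
                 minor_width = prof$minor_width,
                 major_width = prof$major_width),
            class = "groove_profile")
}

#' Periodicity of minor-groove width minima
#'
#' Smooths the per-bp minor-width series with a centered moving average,
#' finds strict local minima with at least `prominence` depth relative to
#' the neighbouring maxima, and reports their positions and mean spacing.
#' A profile whose total range is below `prominence` is reported as having
#' no minima (spacing NA), not a spacing of zero.
#'
#' @param profile a `"groove_profile"` (or numeric vector of widths).
#' @param smoothing_window centered moving-average window, bp (default 3).
#' @param prominence minimum depth of a reported minimum, Angstrom
#'   (default 0.2).
#' @return list with `minima` (bp positions), `mean_spacing` (bp, NA when
#'   fewer than two minima) and the smoothed series.
#' @export
minima_periodicity <- function(profile, smoothing_window = 3L,
                               prominence = 0.2) {
  w <- if (inherits(profile, "groove_profile")) profile$minor_width else
    as.numeric(profile)
  idx <- which(!is.na(w))
  x <- w[idx]
  if (length(x) < 3L) stop_dnacage("profile too short for minima detection")
  xs <- moving_average(x, smoothing_window)
  if (diff(range(xs)) < prominence)
    return(list(minima = integer(0), mean_spacing = NA_real_,
                smoothed = xs, positions = idx))
  n <- length(xs)
  is_min <- which(xs[2:(n - 1)] < xs[1:(n - 2)] & xs[2:(n - 1)] < xs[3:n]) + 1L
  # prominence: depth relative to the lower of the two flanking maxima
  keep <- vapply(is_min, function(i) {
    left <- max(xs[1:(i - 1)])
    right <- max(xs[(i + 1):n])
    min(left, right) - xs[i] >= prominence
  }, logical(1L))
  mins <- idx[is_min[keep]]
  spacing <- if (length(mins) >= 2L) mean(diff(mins)) else NA_real_
  list(minima = mins, mean_spacing = spacing, smoothed = xs, positions = idx)
}

#' @export
print.groove_profile <- function(x, ...) {
  p <- x$profile
  cat(sprintf("Groove widths over %d bp (%d frame(s)%s):\n", nrow(p),
              x$n_frames,
              if (x$subtract_vdw) ", vdW-corrected" else ", raw P-P"))
  cat(sprintf("  minor: %.1f-%.1f A, major: %.1f-%.1f A (interior bps)\n",
              min(p$minor_width, na.rm = TRUE), max(p$minor_width, na.rm = TRUE),
              min(p$major_width, na.rm = TRUE), max(p$major_width, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.groove_profile <- function(x, ...) {
  p <- x$profile
  graphics::matplot(p$bp, cbind(p$minor_width, p$major_width), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "base pair", ylab = "groove width (Å)", ...)
  graphics::legend("topright", c("minor", "major"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
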