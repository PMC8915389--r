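# Caged/uncaged classification of polyamines between parallel DNA duplexes,
# state time series, caged-count evolution, single/mixed-state ratio, and
# residence statistics.
#
# A molecule is "caged" when its central nitrogen lies within a
# system-specific threshold distance of at least one base-pair center of
# EACH of the two duplexes (or of each of the two parallel segments of a
# superhelical duplex). The inequality is strict: a molecule exactly at the
# threshold is uncaged.

CAGE_THRESHOLDS <- c(dd20 = 15, dd25 = 19, dd30 = 23, nucleosome = 22)

#' Caging criterion
#'
#' @param threshold distance threshold, Angstrom.
#' @param system_tag optional label; the tabulated defaults are
#'   dd20 = 15, dd25 = 19, dd30 = 23, nucleosome = 22 Angstrom.
#' @export
cage_criterion <- function(threshold = NULL, system_tag = NULL) {
  if (is.null(threshold)) {
    if (is.null(system_tag) || !system_tag %in% names(CAGE_THRESHOLDS))
      stop_dnacage("need a threshold or a known system_tag (%s)",
                   paste(names(CAGE_THRESHOLDS), collapse = ", "))
    threshold <- CAGE_THRESHOLDS[[system_tag]]
  }
  if (threshold <= 0) stop_dnacage("threshold must be positive")
  structure(list(threshold = threshold, system_tag = system_tag %||% ""),
            class = "cage_criterion")
}

#' Default caging threshold as a function of axis separation
#'
#' Linear rule `threshold = 0.8 * separation - 1` reproducing the tabulated
#' per-system defaults (20 -> 15, 25 -> 19, 30 -> 23 Angstrom); the mapping
#' is a convenience only and any threshold can be supplied explicitly.
#' @param separation axis-to-axis duplex separation, Angstrom.
#' @export
cage_criterion_for_separation <- function(separation) {
  cage_criterion(0.8 * separation - 1)
}

#' Base-pair center groups defining the cage
#'
#' For a two-duplex system, the base-pair center atoms of each duplex. For a
#' single long (superhelical) duplex, the two parallel segments
#' (`segments`, default base pairs 1-67 and 80-146 with the connecting bend
#' excluded).
#' @param system a `"molsys"`.
#' @param segments list of two base-pair index vectors for the single-duplex
#'   case.
#' @return list of two atom-id vectors (base-pair centers).
#' @export
cage_partners <- function(system, segments = list(1:67, 80:146)) {
  if (length(system$duplexes) >= 2L) {
    return(lapply(system$duplexes[1:2], `[[`, "bp_center_id"))
  }
  if (length(system$duplexes) == 1L) {
    d <- system$duplexes[[1L]]
    segs <- lapply(segments, function(s) s[s >= 1 & s <= n_bp(d)])
    if (any(vapply(segs, length, 1L) == 0L))
      stop_dnacage("segment ranges fall outside the duplex (%d bp)", n_bp(d))
    return(lapply(segs, function(s) d$bp_center_id[s]))
  }
  stop_dnacage("system has no duplexes")
}

#' Classify polyamines as caged or uncaged in one frame
#'
#' @param frame_xyz `n_atoms x 3` coordinate matrix for one frame.
#' @param system the topology `"molsys"`.
#' @param crit a [cage_criterion()].
#' @param partners two base-pair center groups; default [cage_partners()].
#' @return logical vector, TRUE = caged, one entry per polyamine.
#' @export
classify_caged <- function(frame_xyz, system, crit, partners = NULL) {
  partners <- partners %||% cage_partners(system)
  if (length(system$polyamines) == 0L) return(logical(0))
  cn_ids <- vapply(system$polyamines, `[[`, integer(1L), "central_N")
  if (anyNA(cn_ids))
    stop_dnacage("central N undefined for polyamine %s",
                 paste(which(is.na(cn_ids)), collapse = ","))
  rows <- match(cn_ids, system$atoms$atom_id)
  cn_xyz <- frame_xyz[rows, , drop = FALSE]
  box <- system$box
  within <- vapply(partners, function(ids) {
    cm <- frame_xyz[match(ids, system$atoms$atom_id), , drop = FALSE]
    min_dist_to_set(cn_xyz, cm, box) < crit$threshold   # strict: ties uncaged
  }, logical(length(system$polyamines)))
  if (is.null(dim(within))) within <- matrix(within, nrow = 1L)
  rowSums(within) == length(partners)
}

#' State series container
#'
#' @param caged logical matrix, molecules x samples (TRUE = caged).
#' @param times sample times, ns.
#' @param molecule_ids molecule identifiers (rownames).
#' @param sample_interval spacing of the samples, ns.
#' @export
new_state_series <- function(caged, times, molecule_ids = seq_len(nrow(caged)),
                             sample_interval = if (length(times) > 1L)
                               times[2L] - times[1L] else NA_real_) {
  stopifnot(is.matrix(caged), ncol(caged) == length(times))
  if (anyNA(caged)) stop_dnacage("state series must have no missing states")
  rownames(caged) <- molecule_ids
  structure(list(caged = caged, times = as.numeric(times),
                 sample_interval = sample_interval,
                 molecule_ids = molecule_ids),
            class = "state_series")
}

#' Caged/uncaged state series over a trajectory
#'
#' Applies [classify_caged()] at every sampled frame. The sampling interval
#' must be commensurate with the frame interval of the trajectory; sampling
#' includes the first frame (t = 0), so a 500 ns trajectory sampled every
#' 25 ns yields 21 samples (set `include_t0 = FALSE` for 20).
#'
#' @param traj a `"trajectory"`.
#' @param crit a [cage_criterion()].
#' @param sample_interval sampling interval, ns; default the frame interval.
#' @param partners see [classify_caged()].
#' @param include_t0 include the t = 0 frame (default TRUE).
#' @return a `"state_series"`.
#' @export
state_series <- function(traj, crit, sample_interval = NULL, partners = NULL,
                         include_t0 = TRUE) {
  times <- traj$times
  dt <- if (length(times) > 1L) times[2L] - times[1L] else NA_real_
  sample_interval <- sample_interval %||% (if (is.na(dt)) 1 else dt)
  if (is.na(dt)) {
    idx <- 1L
  } else {
    ratio <- sample_interval / dt
    if (abs(ratio - round(ratio)) > 1e-9)
      stop_dnacage("sample_interval %g ns is not a multiple of the frame interval %g ns; nearest valid value: %g ns",
                   sample_interval, dt, max(1, round(ratio)) * dt)
    idx <- seq(1L, length(times), by = as.integer(round(ratio)))
  }
  if (!include_t0 && length(idx) > 1L) idx <- idx[-1L]
  if (length(idx) == 0L) stop_dnacage("no frames selected by sampling")
  partners <- partners %||% cage_partners(traj$topology)
  caged <- vapply(idx, function(f)
    classify_caged(frame_xyz(traj, f), traj$topology, crit, partners),
    logical(length(traj$topology$polyamines)))
  if (is.null(dim(caged))) caged <- matrix(caged, nrow = 1L)
  new_state_series(caged, times[idx],
                   molecule_ids = vapply(traj$topology$polyamines, `[[`, 1,
                                         "id"),
                   sample_interval = sample_interval)
}

#' Single-state / mixed-state summary
#'
#' Classifies each molecule over the samples at `t >= t_start` as
#' always-caged, always-uncaged, or mixed (at least one sample of each
#' state), and forms the ratio of single-state to mixed-state molecules:
#' `(n_always_caged + n_always_uncaged) / n_mixed`, 0 when no molecule is
#' single-state, and flagged undefined (NA) when no molecule is mixed.
#'
#' @param series a `"state_series"`.
#' @param normalization divisor applied to the reported counts (e.g. 3 to
#'   compare a 146-bp superhelix against 22-bp duplex systems).
#' @param t_start discard samples before this time, ns.
#' @return object of class `"state_summary"`.
#' @export
state_summary <- function(series, normalization = 1, t_start = 0) {
  stopifnot(inherits(series, "state_series"))
  if (t_start > series$times[length(series$times)])
    stop_dnacage("t_start (%g ns) is beyond the last sample (%g ns)",
                 t_start, series$times[length(series$times)])
  m <- series$caged[, series$times >= t_start, drop = FALSE]
  n_caged_samples <- rowSums(m)
  n_samp <- ncol(m)
  n_always_caged <- sum(n_caged_samples == n_samp)
  n_always_uncaged <- sum(n_caged_samples == 0L)
  n_mixed <- nrow(m) - n_always_caged - n_always_uncaged
  ratio <- if (n_mixed == 0L) NA_real_ else
    (n_always_caged + n_always_uncaged) / n_mixed
  structure(list(
    n_always_caged = n_always_caged, n_always_uncaged = n_always_uncaged,
    n_mixed = n_mixed, n_molecules = nrow(m),
    ratio_single_to_mixed = ratio,
    ratio_undefined = n_mixed == 0L,
    normalization_factor = normalization, t_start = t_start,
    counts_normalized = c(always_caged = n_always_caged,
                          always_uncaged = n_always_uncaged,
                          mixed = n_mixed) / normalization
  ), class = "state_summary")
}

#' @export
print.state_summary <- function(x, ...) {
  cat(sprintf("State summary over %d molecules (t >= %g ns):\n",
              x$n_molecules, x$t_start))
  cat(sprintf("  always caged:   %d\n  always uncaged: %d\n  mixed:          %d\n",
              x$n_always_caged, x$n_always_uncaged, x$n_mixed))
  if (x$ratio_undefined) cat("  single/mixed ratio: undefined (no mixed-state molecules)\n")
  else cat(sprintf("  single/mixed ratio: %.3g\n", x$ratio_single_to_mixed))
  invisible(x)
}

#' Number of caged molecules per sample time
#'
#' @param series a `"state_series"`.
#' @param normalization divisor applied to the counts (3 for the
#'   146-bp superhelix vs 22-bp duplex comparison).
#' @return data.frame with columns `time` (ns) and `n_caged`.
#' @export
caged_count_series <- function(series, normalization = 1) {
  stopifnot(inherits(series, "state_series"))
  data.frame(time = series$times,
             n_caged = colSums(series$caged) / normalization)
}

#' Residence statistics on the sampled state chain
#'
#' Dwell lengths are maximal runs of consecutive caged samples, in units of
#' the sampling interval; transitions are state changes between consecutive
#' samples. Also reports the estimated per-step transition probabilities
#' (exit: caged to uncaged; enter: uncaged to caged) pooled over molecules.
#'
#' @param series a `"state_series"` with at least 2 samples.
#' @return list with `per_molecule` (data.frame: molecule, n_transitions,
#'   mean_caged_dwell, n_caged_samples) and pooled `p_exit_hat`,
#'   `p_enter_hat`.
#' @export
residence_stats <- function(series) {
  stopifnot(inherits(series, "state_series"))
  m <- series$caged
  if (ncol(m) < 2L) stop_dnacage("need at least 2 samples for residence statistics")
  per <- lapply(seq_len(nrow(m)), function(i) {
    s <- m[i, ]
    trans <- sum(s[-1L] != s[-length(s)])
    r <- rle(s)
    dwell <- r$lengths[r$values]
    data.frame(molecule = series$molecule_ids[i], n_transitions = trans,
               mean_caged_dwell = if (length(dwell)) mean(dwell) else NA_real_,
               n_caged_samples = sum(s))
  })
  from_caged <- m[, -ncol(m), drop = FALSE]
  to_state <- m[, -1L, drop = FALSE]
  n_c <- sum(from_caged)
  n_u <- sum(!from_caged)
  list(per_molecule = do.call(rbind, per),
       p_exit_hat = if (n_c) sum(from_caged & !to_state) / n_c else NA_real_,
       p_enter_hat = if (n_u) sum(!from_caged & to_state) / n_u else NA_real_,
       n_from_caged = n_c, n_from_uncaged = n_u)
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("State series: %d molecules x %d samples every %g ns (%.0f%% caged)\n",
              nrow(x$caged), ncol(x$caged), x$sample_interval,
              100 * mean(x$caged)))
  invisible(x)
}
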