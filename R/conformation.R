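# Polyamine conformational state from the end-to-end distance, detection of
# phosphate-bridging contacts between duplexes, and classification of the
# bridging interaction modes (parallel-perpendicular and C-shape).

#' Conformer thresholds
#'
#' Folded below `folded_max`, elongated above `elongated_min`, intermediate
#' between.
#' @param folded_max,elongated_min Angstrom (defaults 7 and 9).
#' @export
conformer_thresholds <- function(folded_max = 7, elongated_min = 9) {
  if (folded_max >= elongated_min)
    stop_dnacage("folded_max must be below elongated_min")
  structure(list(folded_max = folded_max, elongated_min = elongated_min),
            class = "conformer_thresholds")
}

#' End-to-end distance of a polyamine
#'
#' Euclidean distance between the two terminal nitrogens (minimum-image when
#' the system is periodic).
#' @param polyamine a `"polyamine"`.
#' @param frame_xyz `n_atoms x 3` frame coordinates.
#' @param system the topology `"molsys"`.
#' @return distance, Angstrom.
#' @export
end_to_end <- function(polyamine, frame_xyz, system) {
  tn <- polyamine$terminal_N
  if (length(tn) != 2L || anyNA(tn))
    stop_dnacage("polyamine %s: terminal nitrogens undefined", polyamine$id)
  rows <- match(tn, system$atoms$atom_id)
  d <- frame_xyz[rows[1L], ] - frame_xyz[rows[2L], ]
  if (!is.null(system$box))
    d <- mapply(min_image, d, system$box)
  sqrt(sum(d^2))
}

#' Classify a conformer by end-to-end distance
#'
#' @param ee end-to-end distance(s), Angstrom.
#' @param thr a [conformer_thresholds()].
#' @return factor over folded / intermediate / elongated.
#' @export
classify_conformer <- function(ee, thr = conformer_thresholds()) {
  stopifnot(all(ee >= 0))
  out <- ifelse(ee < thr$folded_max, "folded",
                ifelse(ee > thr$elongated_min, "elongated", "intermediate"))
  factor(out, levels = c("folded", "intermediate", "elongated"))
}

#' Conformer-state fractions partitioned by caged state
#'
#' Computes the end-to-end distance of every polyamine at the frames sampled
#' by a state series and tabulates the folded/intermediate/elongated
#' fractions separately for caged and uncaged molecule-samples. Fractions
#' within each partition sum to 1; a partition with no molecule-samples is
#' reported as absent (NULL), not as 0/0.
#'
#' @param traj a `"trajectory"`.
#' @param series a `"state_series"` computed on the same trajectory.
#' @param thr a [conformer_thresholds()].
#' @return list with `caged` and `uncaged` named fraction vectors (or NULL)
#'   and the underlying counts.
#' @export
ee_distribution <- function(traj, series, thr = conformer_thresholds()) {
  f_idx <- match(round(series$times, 9), round(traj$times, 9))
  if (anyNA(f_idx))
    stop_dnacage("state series times do not align with trajectory frames")
  sys <- traj$topology
  pa <- sys$polyamines
  states <- character(0)
  caged_flag <- logical(0)
  for (s in seq_along(f_idx)) {
    fx <- frame_xyz(traj, f_idx[s])
    ee <- vapply(pa, end_to_end, numeric(1L), frame_xyz = fx, system = sys)
    states <- c(states, as.character(classify_conformer(ee, thr)))
    caged_flag <- c(caged_flag, series$caged[, s])
  }
  lv <- c("folded", "intermediate", "elongated")
  tab <- function(sel) {
    if (!any(sel)) return(NULL)
    t0 <- table(factor(states[sel], levels = lv))
    stats::setNames(as.numeric(t0) / sum(t0), lv)
  }
  list(caged = tab(caged_flag), uncaged = tab(!caged_flag),
       n_caged_samples = sum(caged_flag),
       n_uncaged_samples = sum(!caged_flag))
}

#' Detect polyamine bridges between the phosphates of two duplexes
#'
#' A bridge is recorded when an amino nitrogen of a polyamine lies within
#' `n_o_cutoff` of at least one phosphate oxygen (O1P/O2P) on each duplex
#' (a single-N bridge, the heavy-atom signature of an O-HNH-O contact), or
#' when two nitrogens of the same molecule each contact a different duplex
#' (a molecule-level bridge).
#'
#' @param frame_xyz frame coordinates.
#' @param system the topology `"molsys"`.
#' @param duplex1,duplex2 the bridged duplexes.
#' @param n_o_cutoff N...O heavy-atom hydrogen-bond cutoff, Angstrom
#'   (default 3.5).
#' @return data.frame (class `"bridge_table"`): molecule, kind
#'   ("single_N" or "molecule"), N atom id(s), contacted O counts and
#'   minimum N-O distances per duplex.
#' @export
detect_bridges <- function(frame_xyz, system, duplex1, duplex2,
                           n_o_cutoff = 3.5) {
  o1 <- select_region(system, duplex1, "phosphate")$atom_ids
  o2 <- select_region(system, duplex2, "phosphate")$atom_ids
  r1 <- match(o1, system$atoms$atom_id)
  r2 <- match(o2, system$atoms$atom_id)
  box <- system$box
  rows_out <- list()
  for (p in system$polyamines) {
    n_ids <- c(p$terminal_N, p$central_N)
    rn <- match(n_ids, system$atoms$atom_id)
    d1 <- pair_dists(frame_xyz[rn, , drop = FALSE],
                     frame_xyz[r1, , drop = FALSE], box)
    d2 <- pair_dists(frame_xyz[rn, , drop = FALSE],
                     frame_xyz[r2, , drop = FALSE], box)
    hit1 <- rowSums(d1 <= n_o_cutoff) > 0
    hit2 <- rowSums(d2 <= n_o_cutoff) > 0
    both <- which(hit1 & hit2)
    for (i in both)
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        molecule = p$id, kind = "single_N", n_atom = n_ids[i],
        n_O_duplex1 = sum(d1[i, ] <= n_o_cutoff),
        n_O_duplex2 = sum(d2[i, ] <= n_o_cutoff),
        min_d1 = min(d1[i, ]), min_d2 = min(d2[i, ]))
    if (length(both) == 0L && any(hit1) && any(hit2)) {
      i1 <- which(hit1)[1L]; i2 <- which(hit2)[1L]
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        molecule = p$id, kind = "molecule",
        n_atom = NA_integer_,
        n_O_duplex1 = sum(d1[i1, ] <= n_o_cutoff),
        n_O_duplex2 = sum(d2[i2, ] <= n_o_cutoff),
        min_d1 = min(d1[i1, ]), min_d2 = min(d2[i2, ]))
    }
  }
  out <- if (length(rows_out)) do.call(rbind, rows_out) else
    data.frame(molecule = integer(0), kind = character(0),
               n_atom = integer(0), n_O_duplex1 = integer(0),
               n_O_duplex2 = integer(0), min_d1 = numeric(0),
               min_d2 = numeric(0))
  class(out) <- c("bridge_table", class(out))
  out
}

#' Classify the bridging interaction mode of one polyamine
#'
#' `pp` (parallel-perpendicular): the molecule bridges both duplexes, is
#' elongated, and its principal axis lies within `pp_parallel_max` of one
#' duplex's local backbone tangent and at least `pp_perpendicular_min` from
#' the other's. `c_shape`: the molecule bridges both duplexes in a folded
#' conformation. Everything else (including non-bridging molecules) is
#' `other`. The angle gates are reported with the label.
#'
#' @param polyamine a `"polyamine"`.
#' @param frame_xyz frame coordinates.
#' @param system the topology `"molsys"`.
#' @param duplex1,duplex2 the candidate bridged duplexes.
#' @param thr a [conformer_thresholds()].
#' @param n_o_cutoff bridge contact cutoff, Angstrom.
#' @param pp_parallel_max,pp_perpendicular_min angle gates, degrees
#'   (defaults 30 and 60).
#' @return list: `label` ("pp", "c_shape" or "other"), `ee`, `conformer`,
#'   `angles` (to each duplex tangent), `bridged`, and the gates used.
#' @export
classify_mode <- function(polyamine, frame_xyz, system, duplex1, duplex2,
                          thr = conformer_thresholds(), n_o_cutoff = 3.5,
                          pp_parallel_max = 30, pp_perpendicular_min = 60) {
  ee <- end_to_end(polyamine, frame_xyz, system)
  conf <- as.character(classify_conformer(ee, thr))
  bridges <- detect_bridges(frame_xyz, system, duplex1, duplex2, n_o_cutoff)
  bridged <- polyamine$id %in% bridges$molecule
  angles <- c(NA_real_, NA_real_)
  label <- "other"
  if (bridged) {
    axis <- principal_axis(frame_xyz[match(polyamine$atom_ids,
                                           system$atoms$atom_id), ,
                                     drop = FALSE])
    center <- colMeans(frame_xyz[match(polyamine$atom_ids,
                                       system$atoms$atom_id), , drop = FALSE])
    angles <- vapply(list(duplex1, duplex2), function(d)
      axis_angle_deg(axis, backbone_tangent(frame_xyz, system, d, center)),
      numeric(1L))
    if (conf == "folded") {
      label <- "c_shape"
    } else if (conf == "elongated" &&
               ((angles[1L] <= pp_parallel_max && angles[2L] >= pp_perpendicular_min) ||
                (angles[2L] <= pp_parallel_max && angles[1L] >= pp_perpendicular_min))) {
      label <- "pp"
    }
  }
  list(label = label, ee = ee, conformer = conf, angles = angles,
       bridged = bridged,
       gates = c(parallel_max = pp_parallel_max,
                 perpendicular_min = pp_perpendicular_min))
}

# Leading eigenvector of the heavy-atom coordinate covariance.
principal_axis <- function(xyz) {
  cv <- stats::cov(xyz)
  eigen(cv, symmetric = TRUE)$vectors[, 1L]
}

# Local backbone tangent: unit vector between the P atoms two steps before
# and after the phosphate nearest to `point`.
backbone_tangent <- function(frame_xyz, system, duplex, point) {
  tabs <- list(duplex$phos$I, duplex$phos$II)
  best <- NULL; best_d <- Inf
  for (tab in tabs) {
    ok <- which(!is.na(tab$P))
    if (length(ok) == 0L) next
    rows <- match(tab$P[ok], system$atoms$atom_id)
    d <- pair_dists(matrix(point, 1L), frame_xyz[rows, , drop = FALSE],
                    system$box)
    j <- which.min(d)
    if (d[j] < best_d) {
      best_d <- d[j]
      best <- list(tab = tab, ok = ok, j = j)
    }
  }
  ok <- best$ok; j <- best$j
  lo <- ok[max(1L, j - 2L)]; hi <- ok[min(length(ok), j + 2L)]
  rlo <- match(best$tab$P[lo], system$atoms$atom_id)
  rhi <- match(best$tab$P[hi], system$atoms$atom_id)
  v <- frame_xyz[rhi, ] - frame_xyz[rlo, ]
  v / sqrt(sum(v^2))
}
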