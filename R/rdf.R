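# Radial distribution functions and coordination numbers.
#
# g(r) = p(r) / (4 pi r^2 dr) / (N_p / V), where p(r) is the average number
# of selected pairs found at distance r within a shell of thickness dr, N_p
# is the number of selected atom pairs, and V the system volume. Shell
# thickness defaults to 0.1 A. The coordination number is the direct
# integral of the shell counts up to a cutoff.

#' Radial distribution function between two atom selections
#'
#' Time-averaged over all frames with pair distances under the
#' minimum-image convention when the topology carries a box. Distances are
#' binned into shells `(edge, edge + dr]` (closed upper edge, so a pair at
#' exactly an integration cutoff falls inside it).
#'
#' @param traj a `"trajectory"`.
#' @param sel_A,sel_B `"region_selection"`s (or integer atom-id vectors).
#' @param dr shell thickness, Angstrom (default 0.1).
#' @param r_max histogram range; default half the shortest box edge, or the
#'   largest observed distance for an aperiodic fixture.
#' @return object of class `"rdf_result"`: bin edges `r_edges`, midpoints
#'   `r_mid`, `g`, raw per-shell average pair counts `p_counts`, pair count
#'   `N_p`, volume `V`, and selection metadata.
#' @export
compute_rdf <- function(traj, sel_A, sel_B, dr = 0.1, r_max = NULL) {
  ids_A <- selection_ids(sel_A)
  ids_B <- selection_ids(sel_B)
  if (length(ids_A) == 0L || length(ids_B) == 0L)
    stop_dnacage("empty selection")
  same <- identical(sort(ids_A), sort(ids_B))
  if (same && length(ids_A) < 2L)
    stop_dnacage("self-RDF needs at least 2 atoms")
  sys <- traj$topology
  box <- sys$box
  periodic <- !is.null(box)
  if (is.null(r_max)) {
    r_max <- if (periodic) min(box) / 2 else NA_real_
  } else if (periodic && r_max > min(box) / 2 + 1e-9) {
    stop_dnacage("r_max (%g) exceeds half the shortest box edge (%g)",
                 r_max, min(box) / 2)
  }
  rows_A <- match(ids_A, sys$atoms$atom_id)
  rows_B <- match(ids_B, sys$atoms$atom_id)
  nf <- n_frames(traj)
  frame_d <- function(f) {
    fx <- frame_xyz(traj, f)
    d <- pair_dists(fx[rows_A, , drop = FALSE], fx[rows_B, , drop = FALSE], box)
    if (same) d[d < 1e-9] <- NA  # drop self pairs
    d
  }
  vols <- vapply(seq_len(nf), function(f)
    if (periodic) prod(box) else bounding_volume(frame_xyz(traj, f)),
    numeric(1L))
  if (is.na(r_max)) {  # aperiodic fixture without explicit range
    r_max <- max(vapply(seq_len(nf),
                        function(f) max(frame_d(f), na.rm = TRUE),
                        numeric(1L))) + dr
  }
  edges <- seq(0, r_max, by = dr)
  if (abs(edges[length(edges)] - r_max) > 1e-9)
    edges <- c(edges, edges[length(edges)] + dr)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (f in seq_len(nf)) {
    d <- frame_d(f)
    d <- d[!is.na(d) & d > edges[1L] & d <= edges[length(edges)]]
    bin <- ceiling((d - edges[1L]) / dr - 1e-12)
    bin[bin < 1L] <- 1L
    acc <- acc + tabulate(bin, nbins = nb)
  }
  p_counts <- acc / nf
  N_p <- length(ids_A) * length(ids_B) - if (same) length(ids_A) else 0L
  V <- mean(vols)
  r_mid <- edges[-length(edges)] + dr / 2
  g <- p_counts / (4 * pi * r_mid^2 * dr) / (N_p / V)
  structure(list(
    r_edges = edges, r_mid = r_mid, g = g, p_counts = p_counts,
    N_p = N_p, V = V, dr = dr, n_A = length(ids_A), n_B = length(ids_B),
    n_frames = nf, periodic = periodic,
    meta = list(tag_A = selection_tag(sel_A), tag_B = selection_tag(sel_B))
  ), class = "rdf_result")
}

selection_ids <- function(sel) {
  if (inherits(sel, "region_selection")) sel$atom_ids else as.integer(sel)
}
selection_tag <- function(sel) {
  if (inherits(sel, "region_selection")) sel$region_tag else "custom"
}

# Fallback volume for aperiodic fixtures (flagged via `periodic = FALSE`).
bounding_volume <- function(xyz) {
  prod(apply(xyz, 2L, function(v) max(diff(range(v)), 1)))
}

#' Coordination number from an RDF
#'
#' Direct integration of the stored shell counts: the average number of
#' B-selection neighbours of one A-selection atom within `r_cut`. The shell
#' containing `r_cut` is included, so a pair at exactly `r_cut` counts
#' inside; the integral therefore matches direct within-cutoff pair
#' counting to the bin-width resolution.
#'
#' @param rdf an `"rdf_result"`.
#' @param r_cut integration cutoff, Angstrom.
#' @return numeric coordination number.
#' @export
coordination_number <- function(rdf, r_cut) {
  edges <- rdf$r_edges
  if (r_cut > edges[length(edges)] + 1e-9)
    stop_dnacage("r_cut (%g) exceeds the histogram range (%g)",
                 r_cut, edges[length(edges)])
  inside <- edges[-length(edges)] < r_cut - 1e-9  # include the bin holding r_cut
  if (!any(inside)) {
    warn_dnacage("r_cut (%g) below the first bin; CN = 0", r_cut)
    return(0)
  }
  sum(rdf$p_counts[inside]) / rdf$n_A
}

#' Per-base-pair coordination numbers of polyamine heavy atoms
#'
#' For each base pair of the duplex, the time-averaged number of
#' (region atom, polyamine heavy atom) pairs within `r_cut` - the direct
#' integral of that base pair's RDF. Region atoms are the minor- or
#' major-groove reference atoms, or the phosphate O1P/O2P oxygens, of the
#' two residues of the pair.
#'
#' @param traj a `"trajectory"`.
#' @param polyamine_heavy selection of polyamine heavy atoms
#'   ([select_region()] with tag `"polyamine_heavy"`).
#' @param duplex the duplex analyzed, or a list of duplexes whose per-bp
#'   profiles are averaged position-wise (mean of per-duplex profiles).
#' @param region_tag `"minor"`, `"major"`, or `"phosphate"`.
#' @param r_cut integration cutoff, Angstrom (default 4.55).
#' @return object of class `"cn_profile"`: data.frame with bp, base, cn.
#' @export
per_residue_cn <- function(traj, polyamine_heavy, duplex, region_tag,
                           r_cut = 4.55) {
  if (!region_tag %in% c("minor", "major", "phosphate"))
    stop_dnacage("region_tag must be one of minor, major, phosphate")
  duplexes <- if (inherits(duplex, "duplex")) list(duplex) else duplex
  prof <- lapply(duplexes, function(d)
    per_residue_cn_one(traj, polyamine_heavy, d, region_tag, r_cut))
  cn <- Reduce(`+`, lapply(prof, `[[`, "cn")) / length(prof)
  out <- prof[[1L]]
  out$cn <- cn
  structure(list(profile = out, r_cut = r_cut, region_tag = region_tag,
                 n_duplexes = length(prof)), class = "cn_profile")
}

per_residue_cn_one <- function(traj, polyamine_heavy, duplex, region_tag,
                               r_cut) {
  sys <- traj$topology
  pa_rows <- match(selection_ids(polyamine_heavy), sys$atoms$atom_id)
  nbp <- n_bp(duplex)
  bases <- strsplit(duplex$sequence, "")[[1L]]
  nf <- n_frames(traj)
  cn <- numeric(nbp)
  flagged <- logical(nbp)
  region_rows <- lapply(seq_len(nbp), function(b) {
    ids <- bp_region_ids(sys, duplex, b, region_tag)
    match(ids, sys$atoms$atom_id)
  })
  for (f in seq_len(nf)) {
    fx <- frame_xyz(traj, f)
    pa_xyz <- fx[pa_rows, , drop = FALSE]
    for (b in seq_len(nbp)) {
      rows <- region_rows[[b]]
      if (length(rows) == 0L) { flagged[b] <- TRUE; next }
      d <- pair_dists(fx[rows, , drop = FALSE], pa_xyz, sys$box)
      cn[b] <- cn[b] + sum(d <= r_cut + 1e-9)
    }
  }
  data.frame(bp = seq_len(nbp), base = bases, cn = cn / nf,
             empty_region = flagged)
}

#' Inter-duplex phosphate RDF and contact coordination numbers
#'
#' RDF between the backbone P atoms of two duplexes, averaged over the two
#' directions (P of duplex 1 against duplex 2 and vice versa), plus a
#' per-nucleotide coordination number (own cutoff, default 6.5 A)
#' identifying the residues where close DNA-DNA contacts occur. The total
#' contact coordination number integrates the averaged RDF up to
#' `r_cut_total` (default 6.4 A).
#'
#' @param traj a `"trajectory"`.
#' @param duplex1,duplex2 distinct `"duplex"` objects (or the two parallel
#'   segments of a superhelical duplex expressed as P-atom id vectors).
#' @param r_cut_total cutoff for the total contact CN, Angstrom.
#' @param r_cut_per_P cutoff for the per-nucleotide CN, Angstrom.
#' @param dr,r_max histogram parameters as in [compute_rdf()].
#' @return list with `rdf` (an `"rdf_result"`), `cn_total`, and `per_P`
#'   (data.frame: strand, bp, cn) for duplex 1's phosphates.
#' @export
rdf_dd <- function(traj, duplex1, duplex2, r_cut_total = 6.4,
                   r_cut_per_P = 6.5, dr = 0.1, r_max = NULL) {
  if (identical(duplex1, duplex2))
    stop_dnacage("rdf_dd needs two distinct duplexes")
  p1 <- duplex_P_table(traj$topology, duplex1)
  p2 <- duplex_P_table(traj$topology, duplex2)
  rdf12 <- compute_rdf(traj, p1$id, p2$id, dr = dr, r_max = r_max)
  rdf21 <- compute_rdf(traj, p2$id, p1$id, dr = dr, r_max = r_max)
  rdf <- rdf12
  rdf$g <- (rdf12$g + rdf21$g) / 2
  rdf$p_counts <- (rdf12$p_counts + rdf21$p_counts) / 2
  rdf$meta <- list(tag_A = "P(duplex1)", tag_B = "P(duplex2)",
                   averaged_directions = TRUE)
  cn_total <- coordination_number(rdf12, r_cut_total)
  # per-phosphate contact CN on duplex 1
  sys <- traj$topology
  rows1 <- match(p1$id, sys$atoms$atom_id)
  rows2 <- match(p2$id, sys$atoms$atom_id)
  nf <- n_frames(traj)
  per <- numeric(length(rows1))
  for (f in seq_len(nf)) {
    fx <- frame_xyz(traj, f)
    d <- pair_dists(fx[rows1, , drop = FALSE], fx[rows2, , drop = FALSE],
                    sys$box)
    per <- per + rowSums(d <= r_cut_per_P + 1e-9)
  }
  per_P <- data.frame(strand = p1$strand, bp = p1$bp, cn = per / nf)
  list(rdf = rdf, cn_total = cn_total, per_P = per_P,
       r_cut_total = r_cut_total, r_cut_per_P = r_cut_per_P)
}

duplex_P_table <- function(system, duplex) {
  if (inherits(duplex, "duplex")) {
    tab <- rbind(
      data.frame(strand = "I", bp = duplex$phos$I$bp, id = duplex$phos$I$P),
      data.frame(strand = "II", bp = duplex$phos$II$bp, id = duplex$phos$II$P)
    )
    tab[!is.na(tab$id), ]
  } else {
    data.frame(strand = "I", bp = seq_along(duplex), id = as.integer(duplex))
  }
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("RDF %s vs %s: %d bins of %.3g A, N_p = %d, V = %.4g A^3%s\n",
              x$meta$tag_A, x$meta$tag_B, length(x$g), x$dr, x$N_p, x$V,
              if (!x$periodic) " (aperiodic: bounding-box volume)" else ""))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, xlab = "r (Å)", ylab = "g(r)",
                            type = "l", ...) {
  graphics::plot(x$r_mid, x$g, type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 1, lty = 3, col = "grey")
  invisible(x)
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("Per-bp coordination numbers (%s region, r_cut = %.2f A, %d duplex(es) averaged)\n",
              x$region_tag, x$r_cut, x$n_duplexes))
  print(utils::head(x$profile, 8L))
  if (nrow(x$profile) > 8L) cat("  ...\n")
  invisible(x)
}
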