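# Synthetic system assembly and pseudo-trajectory generation. These fixtures
# emulate the statistical structure the analyses assume: two parallel
# fiber-model duplexes (or the two juxtaposed gyres of a superhelical
# duplex) with polyamines exchanging between the inter-duplex ("caged")
# region and the outside, governed by a two-state Markov chain.

DD_SEQUENCE <- "CGCGAATTCGCGCGAATTCGCG"

#' Specification of a two-duplex system
#'
#' @param sequence duplex sequence (strand I, 5' to 3').
#' @param separation axis-to-axis distance between the duplexes, Angstrom.
#' @param n_polyamine,n_K,n_Cl,n_water composition; ions and water are
#'   bookkeeping counts only, never instantiated.
#' @param box orthorhombic box edges, Angstrom (default scales with the
#'   separation and duplex length).
#' @export
system_spec <- function(sequence = DD_SEQUENCE, separation = 20,
                        n_polyamine = 30L, n_K = 84L, n_Cl = 90L,
                        n_water = 31308L, box = NULL) {
  if (separation <= 0) stop_dnacage("separation must be positive")
  if (any(c(n_polyamine, n_K, n_Cl, n_water) < 0))
    stop_dnacage("composition counts must be non-negative")
  if (is.null(box))
    box <- c(separation + 70, 70, (nchar(sequence) - 1) * BDNA_RISE + 34)
  structure(list(sequence = sequence, n_bp = nchar(sequence),
                 separation = separation, n_polyamine = as.integer(n_polyamine),
                 n_K = as.integer(n_K), n_Cl = as.integer(n_Cl),
                 n_water = as.integer(n_water), box = as.numeric(box)),
            class = "system_spec")
}

#' Specification of the two-state exchange dynamics
#'
#' @param p_enter per-frame probability of an uncaged molecule entering the
#'   caged region.
#' @param p_exit per-frame probability of a caged molecule leaving.
#' @param noise_sigma per-atom Gaussian positional noise, Angstrom.
#' @param n_frames,frame_dt number of frames and frame interval (ns).
#' @param seed RNG seed used by [generate_trajectory()].
#' @export
dynamics_spec <- function(p_enter = 0.1, p_exit = 0.1, noise_sigma = 0.5,
                          n_frames = 21L, frame_dt = 25, seed = 1L) {
  stopifnot(p_enter >= 0, p_enter <= 1, p_exit >= 0, p_exit <= 1,
            noise_sigma >= 0, n_frames >= 1)
  structure(list(p_enter = p_enter, p_exit = p_exit,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 frame_dt = frame_dt, seed = seed), class = "dynamics_spec")
}

#' Assemble two parallel duplexes with placed polyamines
#'
#' Builds two fiber-model duplexes with axes along z separated by
#' `spec$separation` along x (the second duplex azimuthally offset so
#' backbones interleave), then places `spec$n_polyamine` spermidine
#' molecules: a fraction at "caged" sites (central N within
#' `threshold - margin` of at least one base-pair center of *each* duplex)
#' and the rest at outer sites at least `threshold + margin` away from one
#' of the duplexes, so the initial states are unambiguous under noise.
#'
#' @param spec a [system_spec()].
#' @param fraction_caged fraction of polyamines initially caged; the caged
#'   count is `round(fraction_caged * n_polyamine)`.
#' @param seed RNG seed (placement is reproducible given spec + seed).
#' @param crit caging criterion; default [cage_criterion_for_separation()]
#'   applied to `spec$separation`.
#' @param margin placement margin from the threshold, Angstrom.
#' @return a `"molsys"` with 2 duplexes and the placed polyamines.
#' @export
assemble_two_duplex_system <- function(spec, fraction_caged = 0.4, seed = 1L,
                                       crit = NULL, margin = 2) {
  stopifnot(inherits(spec, "system_spec"),
            fraction_caged >= 0, fraction_caged <= 1)
  if (is.null(crit)) crit <- cage_criterion_for_separation(spec$separation)
  set.seed(seed)
  half <- spec$separation / 2
  s1 <- build_bdna(spec$sequence, chain_ids = c("A", "B"))
  s2 <- build_bdna(spec$sequence, chain_ids = c("C", "D"), phase = 18)
  s1$atoms[, c("x")] <- s1$atoms$x - half
  s2$atoms[, c("x")] <- s2$atoms$x + half
  xyz1 <- atom_xyz(s1$atoms); xyz2 <- atom_xyz(s2$atoms)
  if (min(pair_dists(xyz1, xyz2)) < 1.5)
    stop_dnacage("separation %.1f A too small: inter-duplex atoms closer than 1.5 A",
                 spec$separation)
  atoms <- rbind(s1$atoms, s2$atoms)
  atoms$atom_id <- seq_len(nrow(atoms))
  sys <- molecular_system(atoms,
                          duplexes = list(duplex_from_atoms(atoms, "A", "B"),
                                          duplex_from_atoms(atoms, "C", "D")),
                          n_K = spec$n_K, n_Cl = spec$n_Cl,
                          n_water = spec$n_water, box = spec$box)
  place_polyamines(sys, n = spec$n_polyamine,
                   n_caged = round(fraction_caged * spec$n_polyamine),
                   crit = crit, margin = margin)
}

# Add n spermidine molecules to a system with two caging partners
# (two duplexes, or two superhelix segments). Caged sites satisfy the caging
# criterion with `margin` to spare; uncaged sites violate it by `margin`.
place_polyamines <- function(system, n, n_caged, crit, margin = 2,
                             partners = NULL) {
  if (n == 0L) return(system)
  partners <- partners %||% cage_partners(system)
  centers <- lapply(partners, function(ids) atom_xyz(system$atoms, ids))
  dna_xyz <- atom_xyz(system$atoms)
  box <- system$box
  tmpl <- spermidine_template()
  ctr_all <- do.call(rbind, centers)
  zr <- range(ctr_all[, 3L]); xr <- range(ctr_all[, 1L]); yr <- range(ctr_all[, 2L])
  caged_flag <- rep(c(TRUE, FALSE), c(n_caged, n - n_caged))
  placed <- list()
  occupied <- dna_xyz
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(20000L)) {
      if (caged_flag[i]) {
        p <- c(stats::runif(1, xr[1L] - 5, xr[2L] + 5),
               stats::runif(1, yr[1L] - 8, yr[2L] + 8),
               stats::runif(1, zr[1L], zr[2L]))
        good <- all(vapply(centers, function(cm)
          min(pair_dists(matrix(p, 1L), cm, box)) < crit$threshold - margin,
          logical(1L)))
      } else {
        p <- c(stats::runif(1, -box[1L] / 2, box[1L] / 2) + mean(xr),
               stats::runif(1, -box[2L] / 2, box[2L] / 2) + mean(yr),
               stats::runif(1, -box[3L] / 2, box[3L] / 2) + mean(zr))
        good <- any(vapply(centers, function(cm)
          min(pair_dists(matrix(p, 1L), cm, box)) >= crit$threshold + margin,
          logical(1L)))
      }
      if (!good) next
      mol <- sweep(tmpl %*% t(random_rotation()), 2L, p, "+")
      if (min(pair_dists(mol, occupied, box)) < 1.5) next
      placed[[i]] <- mol
      occupied <- rbind(occupied, mol)
      ok <- TRUE
      break
    }
    if (!ok)
      stop_dnacage("could not place polyamine %d without clashes; box or separation too tight", i)
  }
  n0 <- nrow(system$atoms)
  nm <- rownames(tmpl)
  spd_atoms <- atom_table(
    atom_id = n0 + seq_len(n * 10L),
    atom_name = rep(nm, n),
    residue_name = "SPD",
    residue_index = rep(seq_len(n), each = 10L),
    chain_id = "S",
    xyz = do.call(rbind, placed)
  )
  system$atoms <- rbind(system$atoms, spd_atoms)
  system$polyamines <- lapply(seq_len(n), function(i) {
    ids <- n0 + (i - 1L) * 10L + 1:10
    polyamine(id = i, atom_ids = ids,
              terminal_N = ids[c(1L, 10L)], central_N = ids[5L])
  })
  system
}

#' Generate a pseudo-trajectory with two-state Markov exchange
#'
#' Each polyamine carries a caged/uncaged state evolving per frame by the
#' Markov chain (`p_enter`, `p_exit`). On a state change the molecule is
#' translated to a freshly sampled site of the new kind (caged sites inside
#' the inter-duplex region with a `margin` to the threshold, uncaged sites
#' outside it); between changes it stays at its site. Independent Gaussian
#' noise of sd `noise_sigma` is added to every atom of every frame (DNA
#' included). The generator returns both the trajectory and its ground-truth
#' state matrix.
#'
#' @param system an assembled `"molsys"` with polyamines.
#' @param dyn a [dynamics_spec()].
#' @param crit caging criterion used for site sampling; default derived from
#'   the distance between the two caging partners' centers.
#' @param margin site-sampling margin from the threshold, Angstrom.
#' @return list with elements `trajectory` (a `"trajectory"`) and `states`
#'   (the ground-truth `"state_series"`).
#' @export
generate_trajectory <- function(system, dyn, crit = NULL, margin = 2) {
  stopifnot(inherits(dyn, "dynamics_spec"))
  if (!is.null(dyn$seed)) set.seed(dyn$seed)
  partners <- cage_partners(system)
  if (is.null(crit)) crit <- infer_criterion(system, partners)
  centers <- lapply(partners, function(ids) atom_xyz(system$atoms, ids))
  box <- system$box
  pa <- system$polyamines
  n_pa <- length(pa)
  nat <- nrow(system$atoms)
  base_xyz <- atom_xyz(system$atoms)
  dna_rows <- setdiff(seq_len(nat),
                      unlist(lapply(pa, `[[`, "atom_ids")))
  ctr_all <- do.call(rbind, centers)
  zr <- range(ctr_all[, 3L]); xr <- range(ctr_all[, 1L]); yr <- range(ctr_all[, 2L])

  sample_site <- function(caged) {
    for (try in seq_len(20000L)) {
      if (caged) {
        p <- c(stats::runif(1, xr[1L] - 5, xr[2L] + 5),
               stats::runif(1, yr[1L] - 8, yr[2L] + 8),
               stats::runif(1, zr[1L], zr[2L]))
        good <- all(vapply(centers, function(cm)
          min(pair_dists(matrix(p, 1L), cm, box)) < crit$threshold - margin,
          logical(1L)))
      } else {
        p <- c(stats::runif(1, -box[1L] / 2, box[1L] / 2) + mean(xr),
               stats::runif(1, -box[2L] / 2, box[2L] / 2) + mean(yr),
               stats::runif(1, -box[3L] / 2, box[3L] / 2) + mean(zr))
        good <- any(vapply(centers, function(cm)
          min(pair_dists(matrix(p, 1L), cm, box)) >= crit$threshold + margin,
          logical(1L)))
      }
      if (good &&
          min(pair_dists(matrix(p, 1L), base_xyz[dna_rows, ], box)) > 4)
        return(p)
    }
    stop_dnacage("site sampling failed; check box and threshold geometry")
  }

  # initial states from the assembled positions
  st0 <- classify_caged(base_xyz, system, crit, partners)
  states <- matrix(FALSE, n_pa, dyn$n_frames)
  states[, 1L] <- st0
  mol_xyz <- lapply(pa, function(p) base_xyz[p$atom_ids, , drop = FALSE])
  xyz <- array(0, dim = c(nat, 3L, dyn$n_frames))
  for (f in seq_len(dyn$n_frames)) {
    if (f > 1L) {
      flip <- stats::runif(n_pa) < ifelse(states[, f - 1L], dyn$p_exit, dyn$p_enter)
      states[, f] <- xor(states[, f - 1L], flip)
      for (i in which(flip)) {
        site <- sample_site(states[i, f])
        tmpl <- spermidine_template() %*% t(random_rotation())
        mol_xyz[[i]] <- sweep(tmpl, 2L, site, "+")
      }
    }
    fr <- base_xyz
    for (i in seq_len(n_pa)) fr[pa[[i]]$atom_ids, ] <- mol_xyz[[i]]
    if (dyn$noise_sigma > 0)
      fr <- fr + matrix(stats::rnorm(nat * 3L, sd = dyn$noise_sigma), nat, 3L)
    xyz[, , f] <- fr
  }
  times <- (seq_len(dyn$n_frames) - 1L) * dyn$frame_dt
  traj <- new_trajectory(xyz, times, system)
  list(trajectory = traj,
       states = new_state_series(states, times,
                                 molecule_ids = vapply(pa, `[[`, 1, "id"),
                                 sample_interval = dyn$frame_dt))
}

# Default criterion when none is supplied: derived from the mean distance
# between the two partners' base-pair center clouds.
infer_criterion <- function(system, partners) {
  c1 <- colMeans(atom_xyz(system$atoms, partners[[1L]]))
  c2 <- colMeans(atom_xyz(system$atoms, partners[[2L]]))
  sep <- sqrt(sum((c1 - c2)^2))
  cage_criterion_for_separation(sep)
}
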