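# Shared fixtures, built once per test run.

fx <- new.env()

# DD-20-like two-duplex system with 30 spermidine (12 initially caged).
dd20_system <- function() {
  if (is.null(fx$dd20)) {
    fx$dd20 <- assemble_two_duplex_system(system_spec(separation = 20),
                                          fraction_caged = 0.4, seed = 11)
  }
  fx$dd20
}

dd20_run <- function() {
  if (is.null(fx$dd20_run)) {
    dyn <- dynamics_spec(p_enter = 0.1, p_exit = 0.1, noise_sigma = 0.5,
                         n_frames = 11L, frame_dt = 25, seed = 21)
    fx$dd20_run <- generate_trajectory(dd20_system(), dyn,
                                       crit = cage_criterion(system_tag = "dd20"))
  }
  fx$dd20_run
}

one_frame <- function(system, time = 0) {
  xyz <- array(as.matrix(system$atoms[, c("x", "y", "z")]),
               dim = c(nrow(system$atoms), 3L, 1L))
  new_trajectory(xyz, times = time, topology = system)
}

# A straight "rail" of P/O1P pseudo-phosphates used as a minimal duplex-like
# object for bridge and orientation fixtures.
mk_rail <- function(id0, chain, n, origin, dir, spacing = 3.4) {
  pos <- t(vapply(0:(n - 1), function(i) origin + i * spacing * dir,
                  numeric(3L)))
  rbind(
    atom_table(id0 + seq_len(n), rep("P", n), rep("DA", n), 1:n, chain, pos),
    atom_table(id0 + n + seq_len(n), rep("O1P", n), rep("DA", n), 1:n, chain,
               sweep(pos, 2L, c(0.6, 0.6, 0), "+"))
  )
}

fake_rail_duplex <- function(atoms, chain, n) {
  sub <- atoms[atoms$chain_id == chain, ]
  pid <- sub$atom_id[sub$atom_name == "P"]
  oid <- sub$atom_id[sub$atom_name == "O1P"]
  structure(list(
    sequence = strrep("A", n), chains = c(I = chain, II = chain),
    base_pairs = data.frame(bp = 1:n, res_i = 1:n, res_ii = n:1),
    bp_center_id = pid,
    phos = list(
      I = data.frame(bp = 1:n, res = 1:n, P = pid, O1P = oid,
                     O2P = NA_integer_),
      II = data.frame(bp = 1:n, res = 1:n, P = NA_integer_,
                      O1P = NA_integer_, O2P = NA_integer_))
  ), class = "duplex")
}

# One hand-placed spermidine over two perpendicular rails; returns system,
# duplexes and polyamine for orientation/bridge tests.
rail_fixture <- function(mol_xyz, rail2_origin = c(0, 4.8, -1),
                         rail2_dir = c(1, 0, 0)) {
  n <- 8L
  a1 <- mk_rail(0L, "A", n, c(0, 0, 0), c(0, 0, 1))
  a2 <- mk_rail(100L, "C", n, rail2_origin, rail2_dir)
  sa <- atom_table(200L + 1:10, rownames(spermidine_template()),
                   rep("SPD", 10L), rep(1L, 10L), "S", mol_xyz)
  atoms <- rbind(a1, a2, sa)
  pa <- polyamine(1, 200L + 1:10, terminal_N = c(201L, 210L),
                  central_N = 205L)
  list(system = molecular_system(atoms, polyamines = list(pa)),
       d1 = fake_rail_duplex(atoms, "A", n),
       d2 = fake_rail_duplex(atoms, "C", n),
       pa = pa,
       xyz = as.matrix(atoms[, c("x", "y", "z")]))
}

# Rotate the all-trans template from the x axis onto the z axis.
rot_x_to_z <- matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3L, 3L, byrow = TRUE)

place_template <- function(tmpl, rot, anchor_target) {
  m <- tmpl %*% t(rot)
  sweep(m, 2L, anchor_target - m[1L, ], "+")
}

# Uniform-random points fixture for ideal-gas RDF checks.
ideal_gas_traj <- function(n_per_sel = 2000L, L = 60, n_frames = 5L,
                           seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_sel
  at <- atom_table(1:n, rep("C", n), rep("GAS", n), rep(1L, n),
                   rep(c("A", "B"), each = n_per_sel),
                   matrix(stats::runif(3L * n, 0, L), ncol = 3L))
  sys <- molecular_system(at, box = c(L, L, L))
  xyz <- array(0, dim = c(n, 3L, n_frames))
  for (f in seq_len(n_frames))
    xyz[, , f] <- matrix(stats::runif(3L * n, 0, L), ncol = 3L)
  new_trajectory(xyz, times = seq_len(n_frames) - 1, topology = sys)
}

# Independent brute-force RDF/CN oracle: plain double-loop histogram.
brute_rdf <- function(traj, ids_A, ids_B, dr, r_max) {
  sys <- traj$topology
  rows_A <- match(ids_A, sys$atoms$atom_id)
  rows_B <- match(ids_B, sys$atoms$atom_id)
  nb <- length(seq(0, r_max, by = dr)) - 1L
  acc <- numeric(nb)
  nf <- dim(traj$xyz)[3L]
  for (f in seq_len(nf)) {
    fxm <- traj$xyz[, , f]
    for (i in rows_A) for (j in rows_B) {
      d <- fxm[i, ] - fxm[j, ]
      if (!is.null(sys$box)) d <- d - sys$box * round(d / sys$box)
      r <- sqrt(sum(d^2))
      if (r > 1e-9 && r <= nb * dr) {
        b <- ceiling(r / dr - 1e-12)
        acc[b] <- acc[b] + 1
      }
    }
  }
  acc / nf
}

# Rigid-body motion helper: rotation about an arbitrary axis + translation.
rigid_transform <- function(xyz, angle = 0.7, shift = c(5, -3, 2)) {
  ax <- c(1, 2, 3) / sqrt(14)
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3) + s_ * K + (1 - c_) * (K %*% K)
  sweep(xyz %*% t(R), 2L, shift, "+")
}
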