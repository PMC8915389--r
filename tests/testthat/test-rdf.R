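test_that("rdf matches the brute-force double-loop oracle exactly", {
  # 3-atom one-frame fixture
  at <- atom_table(1:3, c("N", "O1P", "O2P"), c("SPD", "DG", "DG"),
                   c(1L, 1L, 2L), c("S", "A", "A"),
                   rbind(c(0, 0, 0), c(3.05, 0, 0), c(0, 4.2, 1)))
  sys <- molecular_system(at, box = c(40, 40, 40))
  tr <- one_frame(sys)
  r <- compute_rdf(tr, 1L, 2:3, dr = 0.1, r_max = 10)
  expect_identical(r$p_counts, brute_rdf(tr, 1L, 2:3, 0.1, 10))
  expect_equal(length(unique(round(diff(r$r_edges), 12))), 1L)
  expect_equal(diff(r$r_edges)[1], 0.1)

  # random 60-atom fixture over 2 frames
  set.seed(8)
  n <- 60L
  at2 <- atom_table(1:n, rep(c("N", "O1P"), n / 2), rep("X", n),
                    rep(1L, n), rep(c("S", "A"), n / 2),
                    matrix(runif(3 * n, 0, 20), ncol = 3))
  sys2 <- molecular_system(at2, box = c(25, 25, 25))
  xyz <- array(runif(n * 3 * 2, 0, 20), dim = c(n, 3, 2))
  tr2 <- new_trajectory(xyz, c(0, 1), sys2)
  ids_A <- at2$atom_id[at2$atom_name == "N"]
  ids_B <- at2$atom_id[at2$atom_name == "O1P"]
  r2 <- compute_rdf(tr2, ids_A, ids_B, dr = 0.1, r_max = 12)
  expect_equal(r2$p_counts, brute_rdf(tr2, ids_A, ids_B, 0.1, 12))
})

test_that("rdf normalization reaches the ideal-gas limit", {
  tr <- ideal_gas_traj(n_per_sel = 1500L, L = 60, n_frames = 4L)
  n <- 1500L
  r <- compute_rdf(tr, 1:n, n + 1:n, dr = 0.1)
  sel <- r$r_mid > 6 & r$r_mid < 15
  expect_lt(max(abs(r$g[sel] - 1)), 0.05)
  # self-consistency of the normalization identity
  g2 <- r$p_counts / (4 * pi * r$r_mid^2 * r$dr) / (r$N_p / r$V)
  expect_lt(max(abs(g2 - r$g)), 1e-12)
})

test_that("rdf is symmetric in its selections up to the per-atom role", {
  tr <- dd20_run()$trajectory
  sys <- tr$topology
  a <- select_region(sys, sys$duplexes[[1]], "P")$atom_ids
  b <- select_region(sys, sys$duplexes[[2]], "P")$atom_ids
  r_ab <- compute_rdf(tr, a, b, r_max = 20)
  r_ba <- compute_rdf(tr, b, a, r_max = 20)
  expect_equal(r_ab$g, r_ba$g, tolerance = 1e-12)
  expect_equal(r_ab$N_p, r_ba$N_p)
})

test_that("coordination numbers integrate shell counts with closed cutoff", {
  at <- atom_table(1:2, c("N", "O1P"), c("SPD", "DA"), c(1L, 1L),
                   c("S", "A"), rbind(c(0, 0, 0), c(3, 0, 0)))
  tr <- one_frame(molecular_system(at, box = c(30, 30, 30)))
  r <- compute_rdf(tr, 1L, 2L)
  expect_equal(coordination_number(r, 4.55), 1)
  expect_equal(suppressWarnings(coordination_number(r, 2)), 0)
  # pair exactly at the cutoff counts inside
  at2 <- at; at2$x[2] <- 4.55
  tr2 <- one_frame(molecular_system(at2, box = c(30, 30, 30)))
  r2 <- compute_rdf(tr2, 1L, 2L)
  expect_equal(coordination_number(r2, 4.55), 1)

  # monotone in the cutoff, and equal to direct pair counting
  set.seed(13)
  n <- 100L
  at3 <- atom_table(1:(2 * n), rep("C", 2 * n), rep("X", 2 * n), rep(1L, 2 * n),
                    rep(c("A", "B"), each = n),
                    matrix(runif(6 * n, 0, 18), ncol = 3))
  sys3 <- molecular_system(at3, box = c(20, 20, 20))
  tr3 <- one_frame(sys3)
  r3 <- compute_rdf(tr3, 1:n, n + 1:n, dr = 0.1)
  cuts <- seq(1, 9, by = 0.5)
  cns <- vapply(cuts, function(ct) coordination_number(r3, ct), numeric(1))
  expect_true(all(diff(cns) >= 0))
  # direct distance-count oracle, within one pair in the boundary bin
  xyz <- as.matrix(at3[, c("x", "y", "z")])
  for (ct in c(3, 5, 8)) {
    d <- dnacage:::pair_dists(xyz[1:n, ], xyz[n + 1:n, ], sys3$box)
    expect_lt(abs(coordination_number(r3, ct) - sum(d <= ct) / n), 1 / n + 1e-9)
  }
})

test_that("per-base-pair coordination profiles localize contacts", {
  sys <- build_bdna("CGCGAATTCGCG")
  d <- sys$duplexes[[1]]
  # one polyamine held 3 A away from the minor-groove atoms of bp 6 only
  minor6 <- dnacage:::bp_region_ids(sys, d, 6L, "minor")
  target <- colMeans(as.matrix(sys$atoms[match(minor6, sys$atoms$atom_id),
                                         c("x", "y", "z")]))
  # step radially outward in the base-pair plane: moves away from the
  # neighbouring base pairs as well as the helix axis
  away <- c(target[1], target[2], 0) / sqrt(sum(target[1:2]^2))
  pos <- sweep(spermidine_template() * 0.05, 2L, target + 3 * away, "+")
  n0 <- nrow(sys$atoms)
  sa <- atom_table(n0 + 1:10, rownames(spermidine_template()), rep("SPD", 10),
                   rep(1L, 10), "S", pos)
  sys$atoms <- rbind(sys$atoms, sa)
  sys$polyamines <- list(polyamine(1, n0 + 1:10, c(n0 + 1L, n0 + 10L),
                                   n0 + 5L))
  tr <- one_frame(sys)
  heavy <- select_region(sys, NULL, "polyamine_heavy")
  prof <- per_residue_cn(tr, heavy, d, "minor", r_cut = 4.55)
  expect_equal(prof$r_cut, 4.55)
  nz <- prof$profile$bp[prof$profile$cn > 0]
  expect_true(all(nz == 6L))
})

test_that("inter-duplex phosphate rdf flags contact sites", {
  run <- dd20_run()
  tr <- run$trajectory
  sys <- tr$topology
  expect_error(rdf_dd(tr, sys$duplexes[[1]], sys$duplexes[[1]]), "distinct")

  # 30 A separation: no short-distance contacts
  far <- assemble_two_duplex_system(system_spec(separation = 30),
                                    fraction_caged = 0, seed = 2)
  trf <- one_frame(far)
  ddf <- rdf_dd(trf, far$duplexes[[1]], far$duplexes[[2]], r_max = 20)
  expect_true(all(ddf$rdf$g[ddf$rdf$r_mid < 8] == 0))

  # constructed single cross-duplex P-P pair at 5.5 A
  sys1 <- build_bdna("ACGTACGTAC", chain_ids = c("A", "B"))
  sys2 <- build_bdna("ACGTACGTAC", chain_ids = c("C", "D"))
  # duplex2 far away (min cross distance > 40 A), except one P moved to
  # exactly 5.5 A from one P of duplex1
  sys2$atoms$x <- sys2$atoms$x + 60
  p1 <- sys1$duplexes[[1]]$phos$I; p1 <- p1[!is.na(p1$P), ]
  p2 <- sys2$duplexes[[1]]$phos$I; p2 <- p2[!is.na(p2$P), ]
  i1 <- match(p1$P[3], sys1$atoms$atom_id)
  i2 <- match(p2$P[3], sys2$atoms$atom_id)
  # 5.5 A radially outward from duplex1's axis: farther than 5.5 from every
  # other phosphorus of duplex1
  p3 <- unlist(sys1$atoms[i1, c("x", "y", "z")])
  u <- c(p3[1], p3[2], 0) / sqrt(sum(p3[1:2]^2))
  sys2$atoms[i2, c("x", "y", "z")] <- p3 + 5.5 * u
  sys2$atoms$atom_id <- sys2$atoms$atom_id + nrow(sys1$atoms)
  atoms <- rbind(sys1$atoms, sys2$atoms)
  both <- molecular_system(atoms,
                           duplexes = list(duplex_from_atoms(atoms, "A", "B"),
                                           duplex_from_atoms(atoms, "C", "D")))
  trb <- one_frame(both)
  dd <- rdf_dd(trb, both$duplexes[[1]], both$duplexes[[2]], r_max = 40)
  first_nonzero <- dd$rdf$r_mid[min(which(dd$rdf$g > 0))]
  expect_equal(first_nonzero, 5.45, tolerance = 0.06)  # bin containing 5.5
  hit <- dd$per_P[dd$per_P$cn > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$cn, 1)
})
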