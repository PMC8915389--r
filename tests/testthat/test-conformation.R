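test_that("end-to-end distance matches the chain-geometry closed form", {
  tmpl <- spermidine_template()
  at <- atom_table(1:10, rownames(tmpl), rep("SPD", 10), rep(1L, 10), "S",
                   tmpl)
  pa <- polyamine(1, 1:10, c(1L, 10L), 5L)
  sys <- molecular_system(at, polyamines = list(pa))
  fx1 <- as.matrix(at[, c("x", "y", "z")])
  # oracle: 9 bonds of 1.5 A at 112 degrees, planar all-trans zig-zag
  step <- 1.5 * sin(112 * pi / 360)
  amp <- 1.5 * cos(112 * pi / 360)
  ee_expect <- sqrt((9 * step)^2 + amp^2)
  expect_equal(end_to_end(pa, fx1, sys), ee_expect, tolerance = 1e-12)
  expect_equal(as.character(classify_conformer(ee_expect)), "elongated")

  # coincident termini
  fx0 <- fx1; fx0[10, ] <- fx0[1, ]
  expect_equal(end_to_end(pa, fx0, sys), 0)

  # rigid-motion invariance
  fx2 <- rigid_transform(fx1)
  expect_equal(end_to_end(pa, fx2, sys), end_to_end(pa, fx1, sys),
               tolerance = 1e-9)
})

test_that("conformer classification respects the folded/elongated thresholds", {
  expect_equal(as.character(classify_conformer(6.9)), "folded")
  expect_equal(as.character(classify_conformer(9.1)), "elongated")
  expect_equal(as.character(classify_conformer(8.0)), "intermediate")
  # boundary values are not in the open outer classes
  expect_equal(as.character(classify_conformer(7.0)), "intermediate")
  expect_equal(as.character(classify_conformer(9.0)), "intermediate")
  expect_error(conformer_thresholds(9, 7), "below")
})

test_that("ee distributions partition by caged state and sum to one", {
  run <- dd20_run()
  st <- state_series(run$trajectory, cage_criterion(system_tag = "dd20"))
  d <- ee_distribution(run$trajectory, st)
  expect_equal(sum(d$caged), 1, tolerance = 1e-12)
  expect_equal(sum(d$uncaged), 1, tolerance = 1e-12)
  # every molecule-sample is in exactly one partition
  expect_equal(d$n_caged_samples + d$n_uncaged_samples,
               nrow(st$caged) * ncol(st$caged))
  # rigid templates in this generator are all-trans, hence elongated
  expect_equal(unname(d$uncaged["elongated"]), 1, tolerance = 0.05)

  # all-uncaged series: caged partition absent, not 0/0
  st_all <- st
  st_all$caged[] <- FALSE
  d2 <- ee_distribution(run$trajectory, st_all)
  expect_null(d2$caged)
})

test_that("generator mixtures of folded/elongated placements are recovered", {
  # 30 molecules per frame, 20% folded placements, 5 frames
  set.seed(31)
  n_mol <- 30L; nf <- 5L
  folded <- spermidine_folded_template()
  straight <- spermidine_template()
  atoms_list <- list()
  for (i in seq_len(n_mol))
    atoms_list[[i]] <- atom_table((i - 1) * 10 + 1:10, rownames(straight),
                                  rep("SPD", 10), rep(i, 10), "S", straight)
  at <- do.call(rbind, atoms_list)
  pas <- lapply(seq_len(n_mol), function(i)
    polyamine(i, (i - 1) * 10 + 1:10,
              c((i - 1) * 10 + 1L, (i - 1) * 10 + 10L), (i - 1) * 10 + 5L))
  sys <- molecular_system(at, polyamines = pas)
  xyz <- array(0, dim = c(nrow(at), 3, nf))
  p_fold <- 0.2
  is_folded <- matrix(runif(n_mol * nf) < p_fold, n_mol, nf)
  for (f in seq_len(nf)) for (i in seq_len(n_mol)) {
    tmpl <- if (is_folded[i, f]) folded else straight
    xyz[(i - 1) * 10 + 1:10, , f] <- sweep(tmpl, 2, c(20 * i, 0, 40 * f), "+")
  }
  tr <- new_trajectory(xyz, 25 * (seq_len(nf) - 1), sys)
  st <- new_state_series(matrix(TRUE, n_mol, nf), tr$times)
  d <- ee_distribution(tr, st)
  se <- sqrt(p_fold * (1 - p_fold) / (n_mol * nf))
  expect_lt(abs(d$caged["folded"] - p_fold), 3 * se)
  expect_equal(unname(d$caged["folded"]), mean(is_folded), tolerance = 1e-12)
})

test_that("bridge detection matches the all-pairs scan on every fixture", {
  mol <- place_template(spermidine_template(), rot_x_to_z, c(0.6, 2.5, 10.2))
  f <- rail_fixture(mol)
  br <- detect_bridges(f$xyz, f$system, f$d1, f$d2)
  expect_equal(nrow(br), 1L)
  expect_equal(br$kind, "single_N")

  # no bridge when the nearest cross-duplex N...O exceeds the cutoff
  far <- rail_fixture(mol, rail2_origin = c(0, 9, -1))
  expect_equal(nrow(detect_bridges(far$xyz, far$system, far$d1, far$d2)), 0L)

  # multi-polyamine fixture vs independent all-pairs oracle
  set.seed(23)
  n <- 8L
  a1 <- mk_rail(0L, "A", n, c(0, 0, 0), c(0, 0, 1))
  a2 <- mk_rail(100L, "C", n, c(0, 6, 0), c(0, 0, 1))
  spd <- list()
  pas <- list()
  for (i in 1:3) {
    pos <- sweep(spermidine_template() %*% t(rot_x_to_z), 2,
                 c(runif(1, -1, 1), runif(1, 1, 5), runif(1, 0, 20)), "+")
    ids <- 200L + (i - 1L) * 10L + 1:10
    spd[[i]] <- atom_table(ids, rownames(spermidine_template()),
                           rep("SPD", 10), rep(i, 10), "S", pos)
    pas[[i]] <- polyamine(i, ids, ids[c(1, 10)], ids[5])
  }
  atoms <- rbind(a1, a2, do.call(rbind, spd))
  sys <- molecular_system(atoms, polyamines = pas)
  d1 <- fake_rail_duplex(atoms, "A", n)
  d2 <- fake_rail_duplex(atoms, "C", n)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  br <- detect_bridges(xyz, sys, d1, d2, n_o_cutoff = 3.5)

  # oracle: exhaustive N x O scan
  o1 <- atoms$atom_id[atoms$chain_id == "A" & atoms$atom_name == "O1P"]
  o2 <- atoms$atom_id[atoms$chain_id == "C" & atoms$atom_name == "O1P"]
  expected <- list()
  for (p in pas) {
    for (nid in c(p$terminal_N, p$central_N)) {
      np <- xyz[match(nid, atoms$atom_id), ]
      h1 <- any(sqrt(colSums((t(xyz[match(o1, atoms$atom_id), ]) - np)^2)) <= 3.5)
      h2 <- any(sqrt(colSums((t(xyz[match(o2, atoms$atom_id), ]) - np)^2)) <= 3.5)
      if (h1 && h2) expected[[length(expected) + 1]] <- c(p$id, nid)
    }
  }
  got <- br[br$kind == "single_N", c("molecule", "n_atom")]
  exp_df <- if (length(expected)) do.call(rbind, expected) else
    matrix(numeric(0), 0, 2)
  expect_equal(nrow(got), nrow(exp_df))
  if (nrow(got) > 0)
    expect_equal(unname(as.matrix(got)), unname(exp_df))
})

test_that("bridging modes are classified from conformer and axis angles", {
  mol <- place_template(spermidine_template(), rot_x_to_z, c(0.6, 2.5, 10.2))
  f <- rail_fixture(mol)   # elongated, along rail 1, perpendicular to rail 2
  m <- classify_mode(f$pa, f$xyz, f$system, f$d1, f$d2)
  expect_equal(m$label, "pp")
  expect_lt(m$angles[1], 30)
  expect_gt(m$angles[2], 60)

  # folded molecule bridging both duplexes -> c_shape
  molf <- place_template(spermidine_folded_template(), rot_x_to_z,
                         c(0.6, 2.5, 1.8))
  ff <- rail_fixture(molf, rail2_origin = c(0, 4.8, 3.0))
  mf <- classify_mode(ff$pa, ff$xyz, ff$system, ff$d1, ff$d2)
  expect_lt(mf$ee, 7)
  expect_equal(mf$label, "c_shape")

  # non-bridging molecule -> other
  molx <- place_template(spermidine_template(), rot_x_to_z, c(30, 30, 0))
  fo <- rail_fixture(molx)
  expect_equal(classify_mode(fo$pa, fo$xyz, fo$system, fo$d1, fo$d2)$label,
               "other")

  # rigid-motion invariance of the label and angles
  f2 <- f
  f2$xyz <- rigid_transform(f$xyz)
  m2 <- classify_mode(f$pa, f2$xyz, f$system, f$d1, f$d2)
  expect_equal(m2$label, m$label)
  expect_equal(m2$angles, m$angles, tolerance = 1e-6)
})
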