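# Controlled fixture: two single-point "bp center" groups at a set distance,
# one polyamine whose central N can be placed exactly.
caging_fixture <- function(d1, d2) {
  at <- rbind(
    atom_table(1L, "N1", "DA", 1L, "A", matrix(c(0, 0, 0), 1)),
    atom_table(2L, "N1", "DA", 1L, "C", matrix(c(40, 0, 0), 1)),
    atom_table(2L + 1:10, rownames(spermidine_template()), rep("SPD", 10),
               rep(1L, 10), "S",
               sweep(spermidine_template() * 0.1, 2, c(d1, 0, 0), "+"))
  )
  # place central N exactly at x = d1; partner 2 at distance |40 - d1| = d2
  stopifnot(abs((40 - d1) - d2) < 1e-9)
  sys <- molecular_system(at, polyamines = list(
    polyamine(1, 2L + 1:10, c(3L, 12L), 7L)))
  sys$atoms[sys$atoms$atom_id == 7L, c("x", "y", "z")] <- c(d1, 0, 0)
  sys
}

test_that("caging classification uses a strict AND over both duplexes", {
  crit <- cage_criterion(system_tag = "dd20")
  expect_equal(crit$threshold, 15)
  partners <- list(1L, 2L)

  sys <- caging_fixture(14, 26)  # 14 A from partner 1, 26 A from partner 2
  fx1 <- as.matrix(sys$atoms[, c("x", "y", "z")])
  expect_false(classify_caged(fx1, sys, crit, partners))

  sys2 <- caging_fixture(20, 20)
  sys2$atoms[2, c("x", "y", "z")] <- c(34, 0, 0)  # now 20 and 14 A
  fx2 <- as.matrix(sys2$atoms[, c("x", "y", "z")])
  expect_false(classify_caged(fx2, sys2, crit, list(1L, 2L)))

  # 14 A from both: caged
  sys3 <- caging_fixture(14, 26)
  sys3$atoms[2, c("x", "y", "z")] <- c(28, 0, 0)
  fx3 <- as.matrix(sys3$atoms[, c("x", "y", "z")])
  expect_true(classify_caged(fx3, sys3, crit, list(1L, 2L)))

  # exactly at the threshold: uncaged (strict <)
  sys4 <- caging_fixture(15, 25)
  sys4$atoms[2, c("x", "y", "z")] <- c(30, 0, 0)
  fx4 <- as.matrix(sys4$atoms[, c("x", "y", "z")])
  expect_false(classify_caged(fx4, sys4, crit, list(1L, 2L)))
})

test_that("tabulated thresholds and strict boundaries hold for all systems", {
  thr <- c(dd20 = 15, dd25 = 19, dd30 = 23, nucleosome = 22)
  for (tag in names(thr)) {
    crit <- cage_criterion(system_tag = tag)
    expect_equal(crit$threshold, unname(thr[tag]))
    d_in <- thr[[tag]] - 0.5
    sys <- caging_fixture(14, 26)
    sys$atoms[1, c("x", "y", "z")] <- c(14 - d_in, 0, 0)
    sys$atoms[2, c("x", "y", "z")] <- c(14 + d_in, 0, 0)
    fx1 <- as.matrix(sys$atoms[, c("x", "y", "z")])
    expect_true(classify_caged(fx1, sys, crit, list(1L, 2L)))
    # exactly at the threshold on one side: uncaged
    sys$atoms[2, c("x", "y", "z")] <- c(14 + thr[[tag]], 0, 0)
    fx2 <- as.matrix(sys$atoms[, c("x", "y", "z")])
    expect_false(classify_caged(fx2, sys, crit, list(1L, 2L)))
  }
})

test_that("enlarging the threshold never uncages a molecule", {
  run <- dd20_run()
  fx1 <- run$trajectory$xyz[, , 3]
  sys <- run$trajectory$topology
  prev <- rep(FALSE, length(sys$polyamines))
  for (t in seq(5, 40, by = 2.5)) {
    cur <- classify_caged(fx1, sys, cage_criterion(t))
    expect_true(all(prev <= cur))  # monotone: caged set only grows
    prev <- cur
  }
})

test_that("state series sampling is commensurate and complete", {
  run <- dd20_run()
  crit <- cage_criterion(system_tag = "dd20")
  st <- state_series(run$trajectory, crit, sample_interval = 25)
  expect_equal(ncol(st$caged), 11L)   # t = 0 included
  st2 <- state_series(run$trajectory, crit, sample_interval = 50)
  expect_equal(ncol(st2$caged), 6L)
  st3 <- state_series(run$trajectory, crit, include_t0 = FALSE)
  expect_equal(ncol(st3$caged), 10L)
  expect_error(state_series(run$trajectory, crit, sample_interval = 30),
               "not a multiple")
  # partition invariant: caged + uncaged == n at every sample
  counts <- caged_count_series(st)
  expect_true(all(counts$n_caged + colSums(!st$caged) == 30))
  # single-frame trajectory: one sample per molecule
  single <- new_trajectory(run$trajectory$xyz[, , 1, drop = FALSE], 0,
                           run$trajectory$topology)
  st1 <- state_series(single, crit)
  expect_equal(ncol(st1$caged), 1L)
})

test_that("state summary reproduces the printed single/mixed ratios", {
  mk <- function(n_ac, n_au, n_mixed, n_samp = 21L) {
    m <- rbind(
      matrix(TRUE, n_ac, n_samp),
      matrix(FALSE, n_au, n_samp),
      matrix(rep(c(TRUE, FALSE), length.out = n_samp * n_mixed),
             n_mixed, n_samp, byrow = TRUE)
    )
    new_state_series(m, times = (0:(n_samp - 1)) * 25)
  }
  expect_equal(state_summary(mk(11, 15, 4))$ratio_single_to_mixed, 6.5)
  expect_equal(state_summary(mk(7, 13, 10))$ratio_single_to_mixed, 2)
  expect_equal(state_summary(mk(18, 57, 25))$ratio_single_to_mixed, 3)
  expect_equal(state_summary(mk(0, 0, 30))$ratio_single_to_mixed, 0)
  s_undef <- state_summary(mk(10, 20, 0))
  expect_true(s_undef$ratio_undefined)
  expect_true(is.na(s_undef$ratio_single_to_mixed))
  # counts partition the molecules
  s <- state_summary(mk(11, 15, 4))
  expect_equal(s$n_always_caged + s$n_always_uncaged + s$n_mixed,
               s$n_molecules)
  expect_error(state_summary(mk(1, 1, 1), t_start = 1e6), "beyond")
})

test_that("caged-count series supports normalization for long duplexes", {
  m <- matrix(FALSE, 100, 3)
  m[1:36, 2] <- TRUE
  st <- new_state_series(m, times = c(0, 25, 50))
  counts <- caged_count_series(st, normalization = 3)
  expect_equal(counts$n_caged, c(0, 12, 0))
})

test_that("residence statistics count dwells and transitions on the chain", {
  const <- new_state_series(matrix(TRUE, 1, 20), times = (0:19) * 25)
  rs <- residence_stats(const)
  expect_equal(rs$per_molecule$n_transitions, 0L)
  expect_equal(rs$per_molecule$mean_caged_dwell, 20)

  alt <- new_state_series(matrix(rep(c(TRUE, FALSE), 10), 1), (0:19) * 25)
  expect_equal(residence_stats(alt)$per_molecule$n_transitions, 19L)
})

test_that("markov transition probabilities are recovered from the generator", {
  sys <- dd20_system()
  gen <- generate_trajectory(sys, dynamics_spec(p_enter = 0.2, p_exit = 0.2,
                                                noise_sigma = 0,
                                                n_frames = 50L, seed = 17))
  st <- state_series(gen$trajectory, cage_criterion(system_tag = "dd20"))
  rs <- residence_stats(st)
  se_exit <- sqrt(0.2 * 0.8 / rs$n_from_caged)
  se_enter <- sqrt(0.2 * 0.8 / rs$n_from_uncaged)
  expect_lt(abs(rs$p_exit_hat - 0.2), 3 * se_exit)
  expect_lt(abs(rs$p_enter_hat - 0.2), 3 * se_enter)
})

test_that("classifier agrees with generator ground truth at low noise", {
  run <- dd20_run()   # noise 0.5 A, margin 2 A
  st <- state_series(run$trajectory, cage_criterion(system_tag = "dd20"))
  expect_gte(mean(st$caged == run$states$caged), 0.99)
})

test_that("nucleosome-style partners use the two parallel segments", {
  sh <- build_superhelix(superhelix_spec(146, 10, 0))
  partners <- cage_partners(sh)
  expect_length(partners, 2L)
  expect_length(partners[[1]], 67L)
  expect_length(partners[[2]], 67L)
  # the excluded bend (bps 68-79) appears in neither group
  d <- sh$duplexes[[1]]
  excluded <- d$bp_center_id[68:79]
  expect_length(intersect(excluded, unlist(partners)), 0L)
})
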