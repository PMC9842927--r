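# Ground-truth generation, structural masks, and cohort simulation.

test_that("ground-truth EC respects density, range, and reproducibility", {
  # empty graph
  g0 <- generate_ground_truth_ec(6, density = 0, seed = 1)
  expect_equal(max(abs(as_matrix(g0$ec_true))), 0)

  # reproducibility and binomial count of nonzero links
  g1 <- generate_ground_truth_ec(10, density = 0.2, seed = 5)
  g1b <- generate_ground_truth_ec(10, density = 0.2, seed = 5)
  expect_identical(as_matrix(g1$ec_true), as_matrix(g1b$ec_true))
  k <- sum(as_matrix(g1$ec_true) != 0)
  bounds <- qbinom(c(0.025, 0.975), 90, 0.2)
  expect_gte(k, bounds[1]); expect_lte(k, bounds[2])

  # weight range contract (nonzero entries in [lo, 0.2])
  w <- as_matrix(g1$ec_true)[as_matrix(g1$ec_true) != 0]
  expect_true(all(w >= 0.02 & w <= 0.2))
  expect_equal(diag(as_matrix(g1$ec_true)), rep(0, 10), ignore_attr = TRUE)

  # count law holds across seeds (property-style)
  ks <- vapply(1:20, function(s)
    sum(as_matrix(generate_ground_truth_ec(10, density = 0.2,
                                           seed = s)$ec_true) != 0),
    numeric(1))
  expect_lt(abs(mean(ks) - 0.2 * 90), 3)

  # homotopic links, when drawn, carry boosted weight
  gh <- generate_ground_truth_ec(10, density = 1, weight_range = c(0.05, 0.08),
                                 homotopic_boost = 2, seed = 6)
  E <- as_matrix(gh$ec_true)
  p <- gh$pairing
  homot <- p[col(E)] == row(E)
  expect_true(all(E[homot] >= 0.1 - 1e-12))
  expect_true(all(E[!homot & row(E) != col(E)] <= 0.08 + 1e-12))

  expect_error(generate_ground_truth_ec(10, weight_range = c(0, 0.3)), "weight")
  expect_error(generate_ground_truth_ec(7), "even")
})

test_that("parcellation pairing is a fixed-point-free involution", {
  for (n in c(6, 10, 20)) {
    parc <- make_parcellation(n)
    p <- parc$pairing
    expect_identical(p[p], seq_len(n))
    expect_true(all(p != seq_len(n)))
    expect_true(all(parc$table$hemisphere[p] != parc$table$hemisphere))
    expect_identical(parc$table$name[p], parc$table$name)
  }
})

test_that("structural mask covers truth, drops contra links, adds spurious ones", {
  gt <- generate_ground_truth_ec(10, density = 0.25, seed = 8)
  sup_true <- (as_matrix(gt$ec_true) != 0) | t(as_matrix(gt$ec_true) != 0)

  # no dropout, no extras: mask == symmetric closure of the truth
  m0 <- as_matrix(structural_mask_from_ec(gt, contra_dropout = 0,
                                          extra_edges = 0, seed = 9)) != 0
  expect_identical(m0, sup_true)

  # total contralateral dropout leaves no cross-hemisphere link
  m1 <- as_matrix(structural_mask_from_ec(gt, contra_dropout = 1,
                                          extra_edges = 0, seed = 9)) != 0
  hemi <- gt$parcellation$hemisphere
  cross <- outer(hemi, hemi, `!=`)
  expect_true(all(!m1[cross]))
  expect_true(all(m1 == t(m1)))

  # spurious edge count follows the binomial law on absent pairs
  n_absent <- sum(upper.tri(sup_true) & !sup_true)
  ks <- vapply(1:10, function(s) {
    m <- as_matrix(structural_mask_from_ec(gt, contra_dropout = 0,
                                           extra_edges = 0.1,
                                           seed = 100 + s)) != 0
    sum(upper.tri(m) & m & !sup_true)
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.1 * n_absent), qbinom(0.975, n_absent, 0.1) / 2)
  expect_error(structural_mask_from_ec(gt, contra_dropout = 2), "fraction")
})

test_that("cohorts are deterministic, distinct across subjects, and reliable", {
  gt <- generate_ground_truth_ec(10, density = 0.2, seed = 7)
  c1 <- simulate_cohort(gt, n_subjects = 2, n_sessions = 1, n_volumes = 900,
                        subject_jitter = 0, seed = 70)
  c2 <- simulate_cohort(gt, n_subjects = 2, n_sessions = 1, n_volumes = 900,
                        subject_jitter = 0, seed = 70)
  expect_identical(c1[[1]]$data, c2[[1]]$data)
  expect_false(identical(c1[[1]]$data, c1[[2]]$data))  # distinct noise streams
  expect_identical(c1[[1]]$subject_id, "sub001")
  expect_identical(c1[[2]]$subject_id, "sub002")

  # two sessions of one subject differ but their FCs agree well
  cs <- simulate_cohort(gt, n_subjects = 1, n_sessions = 2, n_volumes = 900,
                        subject_jitter = 0, seed = 8)
  expect_false(identical(cs[[1]]$data, cs[[2]]$data))
  fcs <- lapply(cs, function(ts) functional_connectivity(bandpass_filter(ts)))
  expect_gt(cor(od(as_matrix(fcs[[1]])), od(as_matrix(fcs[[2]]))), 0.5)
})

test_that("cohort signals live inside the analysis band", {
  gt <- generate_ground_truth_ec(6, density = 0.2, seed = 12)
  ts <- simulate_cohort(gt, n_subjects = 1, n_sessions = 1, n_volumes = 900,
                        seed = 13)[[1]]
  for (i in seq_len(nrow(ts$data))) {
    psd <- welch_psd(ts$data[i, ], fs = 1)
    inband <- psd$freq >= 0.008 & psd$freq <= 0.08
    expect_gt(sum(psd$power[inband]), 0.5 * sum(psd$power))
  }
})

test_that("group matrices have the right symmetry and asymmetry", {
  gt <- generate_ground_truth_ec(6, density = 0.3, seed = 14)
  cohort <- simulate_cohort(gt, n_subjects = 3, n_sessions = 2, n_volumes = 900,
                            seed = 15)
  emp <- empirical_pair_from_cohort(cohort)
  expect_s3_class(emp$fc_emp, "connectivity_matrix")
  expect_identical(emp$fc_emp$kind, "FC")
  expect_identical(emp$fc_tau_emp$kind, "FC_tau")
  F1 <- as_matrix(emp$fc_emp)
  expect_equal(F1, t(F1), tolerance = 1e-12)
  # unidirectional truth induces measurable lagged asymmetry
  M <- as_matrix(emp$fc_tau_emp)
  expect_gt(max(abs(M - t(M))), 0.005)

  # a cohort of identical runs averages to the single-run matrices
  one <- cohort[[1]]
  dup <- list(one, one)
  e2 <- empirical_pair_from_cohort(dup)
  single <- functional_connectivity(bandpass_filter(one))
  expect_equal(as_matrix(e2$fc_emp), as_matrix(single), tolerance = 1e-12)
})

test_that("group-FC standard error shrinks roughly as sqrt(n_subjects)", {
  gt <- generate_ground_truth_ec(6, density = 0.25, seed = 9)
  group_fc <- function(n_subj, seed) {
    coh <- simulate_cohort(gt, n_subjects = n_subj, n_sessions = 2,
                           n_volumes = 900, seed = seed)
    od(as_matrix(empirical_pair_from_cohort(coh)$fc_emp))
  }
  m1 <- sapply(1:6, function(r) group_fc(1, 5000 + r))
  m16 <- sapply(1:6, function(r) group_fc(16, 6000 + r))
  ratio <- mean(apply(m1, 1, sd)) / mean(apply(m16, 1, sd))
  expect_gt(ratio, 2)       # sqrt(16) = 4 expected; allow sampling slack
  expect_lt(ratio, 8)
})
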