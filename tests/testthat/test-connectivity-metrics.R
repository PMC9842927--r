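# Band-limiting, intrinsic-frequency estimation, FC and lagged FC.

test_that("bandpass keeps in-band power and rejects out-of-band power", {
  ts_in <- sine_ts(0.03, n = 900)
  out_in <- bandpass_filter(ts_in)
  expect_gte(spectral_amp(out_in$data[1, ], 1, 0.03) /
             spectral_amp(ts_in$data[1, ], 1, 0.03), 0.9)

  ts_out <- sine_ts(0.2, n = 900)
  out_out <- bandpass_filter(ts_out)
  expect_lte(spectral_amp(out_out$data[1, ], 1, 0.2) /
             spectral_amp(ts_out$data[1, ], 1, 0.2), 0.1)

  # constant series: everything below f_lo, output ~ 0 and mean-free
  const <- bold_timeseries(matrix(5, 1, 900), tr = 1)
  expect_lt(max(abs(bandpass_filter(const)$data)), 1e-10)
  mixed <- bandpass_filter(sine_ts(0.04, n = 900, noise = 0.5, seed = 3))
  expect_lt(abs(mean(mixed$data[1, ])), 1e-10)
})

test_that("bandpass validates band feasibility and series length", {
  ts <- sine_ts(0.03, n = 900)
  expect_error(bandpass_filter(ts, 0.02, 0.6), "infeasible")
  expect_error(bandpass_filter(ts, -0.01, 0.08), "infeasible")
  short <- sine_ts(0.03, n = 300)
  expect_error(bandpass_filter(short), "too short")
})

test_that("bandpass is idempotent and zero-phase", {
  ts <- sine_ts(c(0.02, 0.05), n = 900, noise = 0.3, seed = 7)
  once <- bandpass_filter(ts)
  twice <- bandpass_filter(once)
  expect_lt(sqrt(mean((twice$data - once$data)^2)) /
            sqrt(mean(once$data^2)), 0.01)
  # zero phase: pure in-band sinusoid keeps its phase (max cross-corr at lag 0)
  pure <- sine_ts(0.03, n = 900)
  filt <- bandpass_filter(pure)
  cc <- ccf(filt$data[1, ], pure$data[1, ], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("intrinsic frequency estimation finds dominant in-band peaks", {
  # pure sinusoid recovered within one Welch bin (segment n/4 -> 4/n Hz)
  ts <- sine_ts(0.03, n = 900)
  f1 <- estimate_intrinsic_frequencies(ts)
  expect_lt(abs(f1 - 0.03), 4 / 900 + 1e-9)

  # dominant of two components wins
  t <- 1:900
  two <- bold_timeseries(rbind(2 * sin(2 * pi * 0.05 * t) +
                               1 * sin(2 * pi * 0.02 * t)), tr = 1)
  f2 <- estimate_intrinsic_frequencies(two)
  expect_lt(abs(f2 - 0.05), 4 / 900 + 1e-9)

  # cross-session averaging is an arithmetic mean of per-run peaks
  s1 <- sine_ts(0.02, n = 900)
  s2 <- sine_ts(0.04, n = 900)
  f3 <- estimate_intrinsic_frequencies(list(s1, s2))
  p1 <- estimate_intrinsic_frequencies(s1)
  p2 <- estimate_intrinsic_frequencies(s2)
  expect_equal(unname(f3), unname((p1 + p2) / 2), tolerance = 1e-12)
  expect_lt(abs(f3 - 0.03), 4 / 900)

  expect_error(estimate_intrinsic_frequencies(list()), "empty")
  expect_error(
    estimate_intrinsic_frequencies(bold_timeseries(matrix(1, 1, 900), tr = 1)),
    "degenerate")
})

test_that("functional connectivity matches its defining cases", {
  x <- sin(2 * pi * 0.03 * (1:200)) + 0.1 * sin(2 * pi * 0.011 * (1:200))
  ts <- bold_timeseries(rbind(x, x, -x), tr = 1)
  fc <- as_matrix(functional_connectivity(ts))
  expect_equal(fc[1, 2], 1.0, tolerance = 1e-12)
  expect_equal(fc[1, 3], -1.0, tolerance = 1e-12)
  expect_equal(diag(fc), rep(1, 3), ignore_attr = TRUE)

  # sampling null: independent noise stays within ~1/sqrt(n)
  set.seed(5)
  noise <- bold_timeseries(matrix(rnorm(3000), 3, 1000), tr = 1)
  fcn <- as_matrix(functional_connectivity(noise))
  expect_lt(max(abs(od(fcn))), 0.1)

  # brute-force Pearson oracle on a small case
  set.seed(6)
  small <- bold_timeseries(matrix(rnorm(40), 4, 10), tr = 1)
  fcs <- as_matrix(functional_connectivity(small))
  for (i in 1:4) for (j in 1:4)
    expect_equal(fcs[i, j],
                 brute_pearson(small$data[i, ], small$data[j, ]),
                 tolerance = 1e-8)

  expect_error(functional_connectivity(bold_timeseries(matrix(1, 2, 10) +
    rbind(0, 1:10 * 0), tr = 1)), "constant")
})

test_that("lagged FC puts the leading source in the column", {
  # region 2 is region 1 delayed by exactly tau: entry [2, 1] = 1
  set.seed(8)
  base <- cumsum(rnorm(500))
  lagged <- rbind(base[3:500], base[1:498])
  ts <- bold_timeseries(lagged, tr = 1)
  m <- as_matrix(lagged_functional_connectivity(ts, tau = 2))
  expect_equal(m[2, 1], 1.0, tolerance = 1e-12)
  expect_lt(m[1, 2], 1.0)

  # sampling null
  set.seed(9)
  noise <- bold_timeseries(matrix(rnorm(6000), 3, 2000), tr = 1)
  mn <- as_matrix(lagged_functional_connectivity(noise, tau = 2))
  expect_lt(max(abs(mn)), 0.1)

  # a shared undelayed signal gives a symmetric matrix
  t <- 1:600
  common <- sin(2 * pi * 0.04 * t)
  ts2 <- bold_timeseries(rbind(common + 0.01 * sin(2 * pi * 0.02 * t),
                               common + 0.01 * cos(2 * pi * 0.02 * t)), tr = 1)
  ms <- as_matrix(lagged_functional_connectivity(ts2, tau = 2))
  expect_lt(abs(ms[1, 2] - ms[2, 1]), 0.02)

  # brute-force oracle for one off-diagonal entry
  set.seed(10)
  d <- matrix(rnorm(60), 2, 30)
  tsd <- bold_timeseries(d, tr = 1)
  md <- as_matrix(lagged_functional_connectivity(tsd, tau = 3))
  expect_equal(md[1, 2], brute_pearson(d[2, 1:27], d[1, 4:30]), tolerance = 1e-10)
  expect_equal(md[2, 1], brute_pearson(d[1, 1:27], d[2, 4:30]), tolerance = 1e-10)

  expect_error(lagged_functional_connectivity(tsd, tau = 2.5), "multiple")
  expect_error(lagged_functional_connectivity(
    bold_timeseries(matrix(rnorm(8), 2, 4), tr = 1), tau = 2), "short")
})

test_that("lag-0 consistency: degenerate lag reproduces plain FC", {
  ts <- sine_ts(c(0.02, 0.03, 0.05), n = 900, noise = 0.05, seed = 11)
  tsf <- bandpass_filter(ts)
  fc <- as_matrix(functional_connectivity(tsf))
  m0 <- as_matrix(lagged_functional_connectivity(tsf, tau = 0))
  expect_lt(max(abs(m0 - fc)), 1e-6)
  # and a genuinely positive lag on a smooth signal stays close but distinct
  m1 <- as_matrix(lagged_functional_connectivity(tsf, tau = 1))
  expect_false(isTRUE(all.equal(m1, fc, tolerance = 1e-12)))
})

test_that("average_connectivity is an element-wise mean with checks", {
  set.seed(12)
  mk <- function(v12) {
    m <- diag(0, 3)
    m[1, 2] <- v12
    connectivity_matrix(m, kind = "FC_tau", tau = 2)
  }
  mats <- lapply(c(0.1, 0.2, 0.3, 0.4), mk)
  expect_equal(as_matrix(average_connectivity(mats))[1, 2], 0.25)
  one <- average_connectivity(mats[1])
  expect_equal(as_matrix(one), as_matrix(mats[[1]]))
  # cancellation
  m <- matrix(rnorm(9) / 10, 3, 3)
  pair <- list(connectivity_matrix(m, "FC_tau", tau = 2),
               connectivity_matrix(-m, "FC_tau", tau = 2))
  expect_equal(max(abs(as_matrix(average_connectivity(pair)))), 0)
  # kind / ordering guards
  fc <- functional_connectivity(sine_ts(c(0.02, 0.03, 0.04), n = 900,
                                        noise = 0.1, seed = 13))
  expect_error(average_connectivity(list(fc, mats[[1]])), "kind")
})
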