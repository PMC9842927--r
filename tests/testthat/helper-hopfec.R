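# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, textbook formulas) so it stays independent of the package's
# implementation paths.

od <- function(m) m[row(m) != col(m)]

# Pearson correlation from the textbook sum formula.
brute_pearson <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

# Reference Euler integration of the coupled Stuart-Landau system built from
# repeated calls to the pure-R single-step transition (independent of the
# compiled loop).
r_integrate <- function(ec, params, n_steps, init) {
  state <- list(x = init$x, y = init$y, t = 0)
  xs <- matrix(NA_real_, length(init$x), n_steps)
  for (k in seq_len(n_steps)) {
    state <- step_oscillators(state, ec, params)
    xs[, k] <- state$x
  }
  xs
}

# From-scratch balanced two-way ANOVA (factors A, B; r replicates per cell):
# returns the interaction F statistic.
brute_interaction_F <- function(value, fA, fB) {
  fA <- as.factor(fA); fB <- as.factor(fB)
  a <- nlevels(fA); b <- nlevels(fB)
  r <- length(value) / (a * b)
  grand <- mean(value)
  mA <- tapply(value, fA, mean)
  mB <- tapply(value, fB, mean)
  mAB <- tapply(value, list(fA, fB), mean)
  ss_int <- r * sum((sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  ss_err <- sum((value - mAB[cbind(fA, fB)])^2)
  df_int <- (a - 1) * (b - 1)
  df_err <- a * b * (r - 1)
  (ss_int / df_int) / (ss_err / df_err)
}

# Cohort of sinusoids with per-region frequency and noise, as a quick
# bold_timeseries factory.
sine_ts <- function(freqs, n = 900, tr = 1, amp = 1, noise = 0, seed = 1,
                    phase = 0) {
  withr_seed <- function(code) { set.seed(seed); code }
  t <- seq_len(n) * tr
  data <- withr_seed(t(sapply(seq_along(freqs), function(i)
    amp * sin(2 * pi * freqs[i] * t + phase) + noise * rnorm(n))))
  bold_timeseries(data, tr = tr)
}

# Spectral amplitude of a (near-)sinusoid at frequency f via the DFT bin.
spectral_amp <- function(x, tr, f) {
  n <- length(x)
  k <- round(f * n * tr)
  2 * Mod(fft(x)[k + 1]) / n
}

# A tiny deterministic one-subject cohort from a given EC.
mini_cohort <- function(C, params, n_sessions = 4, n_volumes = 900, seed = 1) {
  seeds <- seed + seq_len(n_sessions)
  lapply(seq_len(n_sessions), function(r) {
    ts <- simulate_hopf(C, params, n_volumes = n_volumes, seed = seeds[r])
    ts$subject_id <- "sub1"
    ts$session_id <- sprintf("ses%d", r)
    ts
  })
}
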