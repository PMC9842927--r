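# Ground-truth networks and multi-subject, multi-session synthetic
# "resting-state" cohorts. Defaults mirror the emulated acquisition protocol:
# 4 sessions of 900 volumes at tr = 1 s per subject, node frequencies inside
# the 0.008-0.08 Hz band.

#' Bilateral parcellation table
#'
#' Builds a stand-in region table: n/2 homotopic name pairs split over the two
#' hemispheres, with a cyclic group label. The homotopic pairing maps region i
#' in the left hemisphere to region i + n/2 in the right.
#'
#' @param n_regions Even region count.
#' @param n_groups Number of group labels cycled over the pairs (default 3).
#' @return List with \code{table} (data.frame: region_id, name, hemisphere,
#'   group) and \code{pairing} (integer involution).
#' @export
make_parcellation <- function(n_regions, n_groups = 3) {
  if (n_regions %% 2L != 0L) stop("bilateral layout needs an even n_regions")
  half <- as.integer(n_regions / 2)
  nm <- sprintf("A%02d", seq_len(half))
  tab <- data.frame(
    region_id = c(paste0(nm, "_L"), paste0(nm, "_R")),
    name = rep(nm, 2),
    hemisphere = rep(c("L", "R"), each = half),
    group = rep(paste0("Group", (seq_len(half) - 1L) %% n_groups + 1L), 2),
    stringsAsFactors = FALSE)
  list(table = tab, pairing = c(seq_len(half) + half, seq_len(half)))
}

#' Generate a ground-truth sparse directed effective-connectivity matrix
#'
#' Every off-diagonal entry is nonzero independently with probability
#' \code{density}, with weight drawn uniformly from \code{weight_range}.
#' Entries that land on a homotopic (contralateral counterpart) link get their
#' weight multiplied by \code{homotopic_boost}, capped at 0.2 -- emulating the
#' strong contralateral-counterpart connectivity of real cortex. The matrix is
#' asymmetric (each direction drawn independently) and fully reproducible from
#' the seed.
#'
#' @param n_regions Even region count (bilateral layout).
#' @param density Probability that any off-diagonal link exists.
#' @param weight_range Length-2 vector (lo, hi), a subset of (0, 0.2].
#' @param homotopic_boost Multiplier for homotopic link weights (default 2).
#' @param seed Integer seed.
#' @return List of class \code{ground_truth}: \code{ec_true} (kind EC),
#'   \code{params} (population \code{\link{hopf_params}}), \code{pairing},
#'   \code{parcellation}.
#' @export
generate_ground_truth_ec <- function(n_regions, density = 0.15,
                                     weight_range = c(0.02, 0.12),
                                     homotopic_boost = 2, seed = 1L) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  if (weight_range[1] <= 0 || weight_range[2] > 0.2 ||
      weight_range[1] > weight_range[2])
    stop("weight_range must satisfy 0 < lo <= hi <= 0.2")
  parc <- make_parcellation(n_regions)
  p <- parc$pairing
  ec <- with_seed(seed, {
    m <- matrix(0, n_regions, n_regions)
    off <- which(row(m) != col(m))
    on <- off[runif(length(off)) < density]
    m[on] <- runif(length(on), weight_range[1], weight_range[2])
    homot <- which(p[col(m)] == row(m))        # links onto the mirror region
    m[homot] <- pmin(m[homot] * homotopic_boost, 0.2)
    m
  })
  fpop <- with_seed((as.numeric(seed) + 7) %% (.Machine$integer.max - 1),
                    runif(n_regions, 0.02, 0.06))
  structure(list(
    ec_true = connectivity_matrix(ec, kind = "EC",
                                  region_ids = parc$table$region_id),
    params = hopf_params(a = -0.02, f = fpop, G = 1, beta = 0.02,
                         dt = 0.1, tr = 1, n = n_regions),
    pairing = p, parcellation = parc$table),
    class = "ground_truth")
}

#' Derive a structural-connectivity mask from a ground truth
#'
#' Emulates a tractography mask: the symmetric closure of the true link
#' support, with a fraction of cross-hemisphere (contralateral) links removed
#' -- tractography reveals contralateral connections poorly -- and a fraction
#' of spurious symmetric edges added among absent pairs. Dropout is applied
#' after the spurious additions, so \code{contra_dropout = 1} guarantees a
#' mask with no cross-hemisphere link.
#'
#' @param gt A \code{ground_truth}.
#' @param contra_dropout Probability of removing each cross-hemisphere pair.
#' @param extra_edges Probability of adding each absent ipsi/contra pair.
#' @param seed Integer seed.
#' @return A binary \code{connectivity_matrix} of kind SC.
#' @export
structural_mask_from_ec <- function(gt, contra_dropout = 0.8,
                                    extra_edges = 0.02, seed = 1L) {
  if (contra_dropout < 0 || contra_dropout > 1 ||
      extra_edges < 0 || extra_edges > 1)
    stop("fractions must be in [0, 1]")
  ec <- as_matrix(gt$ec_true)
  n <- nrow(ec)
  hemi <- gt$parcellation$hemisphere
  sup <- (ec != 0) | t(ec != 0)               # symmetric closure of support
  with_seed(seed, {
    up <- which(upper.tri(sup))
    absent <- up[!sup[up]]
    add <- absent[runif(length(absent)) < extra_edges]
    sup[add] <- TRUE
    sup <- sup | t(sup)
    cross <- outer(hemi, hemi, `!=`)
    drop_pair <- upper.tri(sup) & sup & cross &
      matrix(runif(n * n), n, n) < contra_dropout
    sup[drop_pair] <- FALSE
    sup[t(drop_pair)] <- FALSE                # symmetric removal
    connectivity_matrix(sup + 0, kind = "SC",
                        region_ids = gt$parcellation$region_id)
  })
}

#' Simulate a multi-subject, multi-session synthetic cohort
#'
#' Each subject receives bifurcation parameters and intrinsic frequencies
#' jittered multiplicatively around the population values (Gaussian,
#' sd = \code{subject_jitter}, frequencies clamped to stay inside the band),
#' then \code{n_sessions} independent runs are simulated from the true EC.
#' Sub-seeds are derived hierarchically from the master seed, so the whole
#' cohort is reproducible and subjects/sessions have distinct noise streams.
#'
#' @param gt A \code{ground_truth}.
#' @param n_subjects,n_sessions,n_volumes Cohort shape (defaults 20, 4, 900).
#' @param subject_jitter Fractional sd of the per-subject parameter jitter
#'   (default 0.05).
#' @param seed Master seed.
#' @return List of \code{\link{bold_timeseries}} tagged with subject/session.
#' @export
simulate_cohort <- function(gt, n_subjects = 20, n_sessions = 4,
                            n_volumes = 900, subject_jitter = 0.05,
                            seed = 1L) {
  stopifnot(n_subjects >= 1, n_sessions >= 1)
  pop <- gt$params
  subj_seeds <- derive_seeds(seed, n_subjects, salt = 11L)
  cohort <- vector("list", n_subjects * n_sessions)
  k <- 1L
  for (s in seq_len(n_subjects)) {
    sp <- with_seed(subj_seeds[s], {
      a <- pop$a * (1 + subject_jitter * rnorm(pop$n))
      f <- pop$f * (1 + subject_jitter * rnorm(pop$n))
      f <- pmin(pmax(f, 0.009), 0.079)        # keep in-band
      hopf_params(a = a, f = f, G = pop$G, beta = pop$beta,
                  dt = pop$dt, tr = pop$tr, n = pop$n)
    })
    sess_seeds <- derive_seeds(subj_seeds[s], n_sessions, salt = 13L)
    for (r in seq_len(n_sessions)) {
      ts <- simulate_hopf(gt$ec_true, sp, n_volumes = n_volumes,
                          seed = sess_seeds[r])
      ts$subject_id <- sprintf("sub%03d", s)
      ts$session_id <- sprintf("ses%d", r)
      cohort[[k]] <- ts
      k <- k + 1L
    }
  }
  cohort
}

#' Group empirical FC and lagged FC from a cohort
#'
#' Band-limits every run, computes FC and lagged FC per run, averages the four
#' (or however many) session matrices within each subject, then averages
#' across subjects. These are the matrices the EC fitter consumes.
#'
#' @param cohort List of \code{\link{bold_timeseries}} with subject tags.
#' @param band Pass-band in Hz (default c(0.008, 0.08)).
#' @param tau Lag in seconds (default 2).
#' @return List with \code{fc_emp} (kind FC) and \code{fc_tau_emp}
#'   (kind FC_tau).
#' @export
empirical_pair_from_cohort <- function(cohort, band = c(0.008, 0.08), tau = 2) {
  if (length(cohort) == 0L) stop("empty cohort")
  ids <- cohort[[1]]$region_ids
  for (ts in cohort)
    if (!identical(ts$region_ids, ids)) stop("inconsistent region ordering")
  per_run <- lapply(cohort, function(ts) {
    tsf <- bandpass_filter(ts, band[1], band[2])
    list(subject = ts$subject_id,
         fc = functional_connectivity(tsf),
         fct = lagged_functional_connectivity(tsf, tau))
  })
  subjects <- vapply(per_run, `[[`, character(1), "subject")
  by_subj <- split(per_run, subjects)
  fc_subj <- lapply(by_subj, function(runs)
    average_connectivity(lapply(runs, `[[`, "fc")))
  fct_subj <- lapply(by_subj, function(runs)
    average_connectivity(lapply(runs, `[[`, "fct")))
  list(fc_emp = average_connectivity(fc_subj),
       fc_tau_emp = average_connectivity(fct_subj))
}
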