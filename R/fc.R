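# Functional connectivity (instantaneous and lagged).

check_no_constant <- function(ts) {
  sds <- apply(ts$data, 1, sd)
  if (any(sds == 0))
    stop(sprintf("constant region(s) make the correlation undefined: %s",
                 paste(ts$region_ids[sds == 0], collapse = ", ")))
}

#' Functional connectivity (Pearson correlation matrix)
#'
#' Pairwise Pearson correlation between region signal timeseries; symmetric
#' with a unit diagonal by construction.
#'
#' @param ts A \code{\link{bold_timeseries}} with at least 3 timepoints and no
#'   constant region.
#' @return A \code{connectivity_matrix} of kind FC.
#' @export
functional_connectivity <- function(ts) {
  stopifnot(inherits(ts, "bold_timeseries"))
  if (n_volumes(ts) < 3L) stop("need at least 3 timepoints")
  check_no_constant(ts)
  fc <- cor(t(ts$data))
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  connectivity_matrix(fc, kind = "FC", region_ids = ts$region_ids)
}

#' Lagged functional connectivity FC(tau)
#'
#' Entry (i, j) is the Pearson correlation of region j at time t with region i
#' at time t + tau: the source (column) leads the target (row), consistent
#' with the column-to-row orientation of the EC matrix. Unlike FC, this matrix
#' is generally asymmetric; the asymmetry carries the directional information
#' the EC fit exploits.
#'
#' @param ts A \code{\link{bold_timeseries}}.
#' @param tau Lag in seconds; must be a positive integer multiple of tr
#'   (tau = 0 is accepted as the degenerate case and reproduces the plain FC,
#'   returned with kind FC).
#' @return A \code{connectivity_matrix} of kind FC_tau (kind FC when tau = 0).
#' @export
lagged_functional_connectivity <- function(ts, tau = 2) {
  stopifnot(inherits(ts, "bold_timeseries"))
  lag <- tau / ts$tr
  if (tau < 0 || abs(lag - round(lag)) > 1e-8)
    stop(sprintf("tau = %g s is not a nonnegative integer multiple of tr = %g s",
                 tau, ts$tr))
  lag <- as.integer(round(lag))
  n <- n_volumes(ts)
  if (n <= lag + 2L) stop("series too short for this lag")
  check_no_constant(ts)
  early <- t(ts$data[, 1:(n - lag), drop = FALSE])        # sources at t
  late  <- t(ts$data[, (lag + 1):n, drop = FALSE])        # targets at t + tau
  m <- cor(late, early)                                   # m[i, j] = cor(x_i(t+tau), x_j(t))
  if (lag == 0L) {
    m <- (m + t(m)) / 2
    diag(m) <- 1
    return(connectivity_matrix(m, kind = "FC", region_ids = ts$region_ids))
  }
  connectivity_matrix(m, kind = "FC_tau", tau = tau, region_ids = ts$region_ids)
}
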