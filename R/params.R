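#' Hopf model parameters
#'
#' Container for the node-level and global parameters of the coupled
#' Stuart-Landau system. Each node i has a bifurcation parameter \code{a[i]}
#' (noisy fixed point for a < 0, limit cycle of radius sqrt(a) for a > 0) and
#' an intrinsic frequency \code{f[i]} in Hz (angular velocity omega = 2 pi f).
#'
#' @param a Per-node bifurcation parameter; recycled to length \code{n} if
#'   scalar. Default -0.02, the noisy regime just below the bifurcation.
#' @param f Per-node intrinsic frequency in Hz; recycled if scalar. Must lie
#'   strictly inside (0, 1/(2 tr)) (sub-Nyquist).
#' @param G Global coupling weight scaling the whole effective-connectivity
#'   matrix; default 1 so the EC entries carry the full coupling scale.
#' @param beta Standard deviation of the additive Gaussian noise; default 0.02.
#' @param dt Integration step in seconds; default 0.1.
#' @param tr Output sampling interval (repetition time) in seconds; must be a
#'   positive integer multiple of \code{dt}. Default 1.
#' @param n Number of nodes; inferred from \code{a}/\code{f} when either is a
#'   vector.
#' @return An object of class \code{hopf_params}.
#' @examples
#' p <- hopf_params(n = 4, a = 0.25, f = 0.05)
#' p$a
#' @export
hopf_params <- function(a = -0.02, f = 0.04, G = 1, beta = 0.02,
                        dt = 0.1, tr = 1, n = NULL) {
  n <- n %||% max(length(a), length(f))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(f) == 1L) f <- rep(f, n)
  if (length(a) != n || length(f) != n)
    stop("lengths of `a` and `f` must match `n`")
  check_scalar(G, "G", lower = 0)
  check_scalar(beta, "beta", lower = 0)
  check_scalar(dt, "dt", lower = 1e-12)
  check_scalar(tr, "tr", lower = dt)
  spt <- tr / dt
  if (abs(spt - round(spt)) > 1e-8)
    stop("`tr` must be a positive integer multiple of `dt`")
  if (any(!is.finite(a)) || any(!is.finite(f)))
    stop("`a` and `f` must be finite")
  if (any(f <= 0) || any(f >= 1 / (2 * tr)))
    stop("all intrinsic frequencies must lie in (0, 1/(2*tr)) (sub-Nyquist)")
  structure(list(a = as.numeric(a), f = as.numeric(f), G = G, beta = beta,
                 dt = dt, tr = tr, n = as.integer(n)),
            class = "hopf_params")
}

#' @export
print.hopf_params <- function(x, ...) {
  cat(sprintf("<hopf_params> %d nodes | a in [%.3g, %.3g] | f in [%.3g, %.3g] Hz\n",
              x$n, min(x$a), max(x$a), min(x$f), max(x$f)))
  cat(sprintf("  G = %g, beta = %g, dt = %g s, tr = %g s\n",
              x$G, x$beta, x$dt, x$tr))
  invisible(x)
}
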