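# Stuart-Landau (Hopf normal form) network simulation.
#
# Node dynamics (x is the read-out, y the auxiliary coordinate):
#   dx_i = [(a_i - x_i^2 - y_i^2) x_i - w_i y_i + G sum_j C_ij (x_j - x_i)] dt + beta dW
#   dy_i = [(a_i - x_i^2 - y_i^2) y_i + w_i x_i + G sum_j C_ij (y_j - y_i)] dt + beta dW
# with diffusive coupling read column-to-row (C_ij: source j -> target i).

#' One Euler-Maruyama step of the coupled Stuart-Landau system
#'
#' Pure-R single-step transition, primarily useful for inspection and as an
#' independent reference for the compiled integrator. The noise increment is
#' supplied explicitly (already scaled draws are multiplied by beta*sqrt(dt)
#' internally, i.e. pass standard-normal draws).
#'
#' @param state List with numeric vectors \code{x}, \code{y} and elapsed time
#'   \code{t} in seconds.
#' @param ec Effective connectivity: \code{connectivity_matrix} of kind EC or a
#'   plain square matrix with zero diagonal.
#' @param params A \code{\link{hopf_params}} object.
#' @param noise N x 2 matrix of standard-normal draws (columns: x, y channel);
#'   defaults to zeros (deterministic step).
#' @return The updated state list.
#' @export
step_oscillators <- function(state, ec, params, noise = NULL) {
  C <- as_matrix(ec)
  N <- params$n
  if (length(state$x) != N || length(state$y) != N)
    stop("state dimension does not match params")
  if (nrow(C) != N) stop("ec dimension does not match params")
  if (any(diag(C) != 0)) stop("ec must have a zero diagonal")
  if (any(!is.finite(state$x)) || any(!is.finite(state$y)))
    stop("non-finite state: numerical blow-up, reduce dt")
  if (is.null(noise)) noise <- matrix(0, N, 2)
  x <- state$x; y <- state$y
  w <- 2 * pi * params$f
  r2 <- x^2 + y^2
  # diffusive coupling: rowSums(C * outer difference) == C %*% x - rowSums(C) * x
  cx <- drop(C %*% x) - rowSums(C) * x
  cy <- drop(C %*% y) - rowSums(C) * y
  sq <- params$beta * sqrt(params$dt)
  list(
    x = x + params$dt * ((params$a - r2) * x - w * y + params$G * cx) + sq * noise[, 1],
    y = y + params$dt * ((params$a - r2) * y + w * x + params$G * cy) + sq * noise[, 2],
    t = (state$t %||% 0) + params$dt
  )
}

#' Simulate BOLD-like signals from an effective-connectivity matrix
#'
#' Integrates the coupled Stuart-Landau stochastic system with the
#' Euler-Maruyama scheme at step \code{dt}, discards \code{burn_in} seconds,
#' and retains the x coordinate of every node at each sampling interval
#' \code{tr}. Identical inputs and seed give bit-identical output.
#'
#' @param ec Effective connectivity (kind EC) or plain square matrix; the
#'   diagonal is forced to zero.
#' @param params A \code{\link{hopf_params}} object.
#' @param n_volumes Number of retained samples (>= 2).
#' @param burn_in Seconds discarded before sampling starts (default 200).
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @param init Optional list(x, y) initial state; default drawn uniformly in
#'   [-0.1, 0.1] per coordinate from the seeded generator.
#' @return A \code{\link{bold_timeseries}} (regions x volumes).
#' @examples
#' p <- hopf_params(n = 2, a = 0.25, f = 0.05, beta = 0)
#' ts <- simulate_hopf(diag(0, 2), p, n_volumes = 50, burn_in = 0, seed = 1)
#' dim(ts$data)
#' @export
simulate_hopf <- function(ec, params, n_volumes, burn_in = 200, seed = NULL,
                          init = NULL) {
  C <- as_matrix(ec)
  if (nrow(C) != ncol(C)) stop("ec must be square")
  if (nrow(C) != params$n) stop("ec dimension does not match params")
  diag(C) <- 0
  if (n_volumes < 2L) stop("n_volumes must be >= 2")
  if (burn_in < 0) stop("burn_in must be >= 0")
  steps_per_tr <- as.integer(round(params$tr / params$dt))
  burn_steps <- as.integer(round(burn_in / params$dt))
  ids <- if (inherits(ec, "connectivity_matrix")) ec$region_ids else
    rownames(C) %||% paste0("R", seq_len(nrow(C)))
  with_seed(seed, {
    if (is.null(init))
      init <- list(x = runif(params$n, -0.1, 0.1),
                   y = runif(params$n, -0.1, 0.1))
    out <- .hopf_integrate(C, params$a, 2 * pi * params$f, params$G,
                           params$beta, params$dt, steps_per_tr,
                           as.integer(n_volumes), burn_steps,
                           as.numeric(init$x), as.numeric(init$y))
    bold_timeseries(out, tr = params$tr, region_ids = ids)
  })
}
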