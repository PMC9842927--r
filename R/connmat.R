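#' Square connectivity matrix tagged by kind
#'
#' A labelled N x N matrix with a `kind` tag distinguishing effective (EC),
#' structural (SC), functional (FC) and lagged functional (FC_tau)
#' connectivity, plus the lag in seconds for FC_tau. The orientation
#' convention for directed kinds is column-to-row: entry (i, j) refers to the
#' influence of source j on target i.
#'
#' @param values Square numeric matrix.
#' @param kind One of "EC", "SC", "FC", "FC_tau".
#' @param tau Lag in seconds (0 for FC; > 0 for FC_tau; ignored otherwise).
#' @param region_ids Region labels; default from dimnames or "R1"..."Rn".
#' @param ec_cap Upper bound checked for EC entries (default 0.2).
#' @return An object of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(values, kind = c("EC", "SC", "FC", "FC_tau"),
                                tau = 0, region_ids = NULL, ec_cap = 0.2) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (any(!is.finite(values))) stop("connectivity matrix has non-finite entries")
  region_ids <- region_ids %||% rownames(values) %||%
    paste0("R", seq_len(nrow(values)))
  if (length(region_ids) != nrow(values))
    stop("length of `region_ids` must match matrix dimension")
  dimnames(values) <- list(region_ids, region_ids)
  if (kind == "EC") {
    if (any(diag(values) != 0)) stop("EC must have a zero diagonal")
    if (any(values < -1e-12) || any(values > ec_cap + 1e-12))
      stop(sprintf("EC entries must lie in [0, %g]", ec_cap))
  }
  if (kind %in% c("FC", "FC_tau")) {
    if (any(values < -1 - 1e-9) || any(values > 1 + 1e-9))
      stop("correlation entries must lie in [-1, 1]")
  }
  if (kind == "FC") {
    if (max(abs(values - t(values))) > 1e-9) stop("FC must be symmetric")
    if (max(abs(diag(values) - 1)) > 1e-9) stop("FC must have a unit diagonal")
  }
  if (kind == "FC_tau" && tau <= 0) stop("FC_tau requires tau > 0")
  structure(list(values = values, kind = kind,
                 tau = if (kind == "FC_tau") tau else 0,
                 region_ids = as.character(region_ids)),
            class = "connectivity_matrix")
}

#' Extract the plain numeric matrix from a connectivity object
#' @param m A \code{connectivity_matrix} or plain matrix.
#' @return A base numeric matrix.
#' @export
as_matrix <- function(m) {
  if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix:%s> %d x %d", x$kind,
              nrow(x$values), ncol(x$values)))
  if (x$kind == "FC_tau") cat(sprintf(", tau = %g s", x$tau))
  cat(sprintf(" | range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Element-wise average of connectivity matrices of one kind
#'
#' Session/subject averaging: a plain arithmetic mean of the matrices (no
#' Fisher-z transform).
#'
#' @param mats List of \code{connectivity_matrix} objects of identical kind,
#'   lag and region ordering.
#' @return A \code{connectivity_matrix} of the same kind.
#' @export
average_connectivity <- function(mats) {
  if (length(mats) < 1L) stop("need at least one matrix")
  kinds <- vapply(mats, function(m) m$kind, character(1))
  if (length(unique(kinds)) != 1L) stop("all matrices must share one kind")
  ids <- mats[[1]]$region_ids
  for (m in mats[-1])
    if (!identical(m$region_ids, ids)) stop("region ordering mismatch")
  taus <- vapply(mats, function(m) m$tau, numeric(1))
  if (length(unique(taus)) != 1L) stop("lag mismatch across matrices")
  avg <- Reduce(`+`, lapply(mats, as_matrix)) / length(mats)
  connectivity_matrix(avg, kind = kinds[1], tau = taus[1], region_ids = ids)
}
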