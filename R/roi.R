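# Reporting computations on fitted connectivity: directional differences,
# display thresholding, ROI connectivity-profile comparisons, and
# ipsi/contralateral summaries.

#' Directional difference of an effective-connectivity matrix
#'
#' D = C - t(C): positive entries mean the connectivity is stronger in the
#' column-to-row direction. The raw antisymmetric matrix is retained; a
#' display copy zeroes entries with |D| below the display threshold so only
#' the larger directional differences are shown.
#'
#' @param ec EC matrix (\code{connectivity_matrix} or plain square matrix).
#' @param display_threshold Magnitude below which entries are blanked in the
#'   display copy (default 0.01).
#' @return List of class \code{direction_difference}: \code{raw},
#'   \code{display}, \code{threshold}.
#' @export
direction_difference <- function(ec, display_threshold = 0.01) {
  C <- as_matrix(ec)
  if (nrow(C) != ncol(C)) stop("EC must be square")
  D <- C - t(C)
  disp <- D
  disp[abs(disp) < display_threshold] <- 0
  structure(list(raw = D, display = disp, threshold = display_threshold),
            class = "direction_difference")
}

#' Display-threshold a connectivity matrix
#'
#' Entries strictly below the threshold are set to zero; entries at or above
#' it are retained unchanged (boundary inclusive).
#'
#' @param m Connectivity matrix or plain matrix.
#' @param threshold Retention threshold (e.g. 0.4 for FC displays).
#' @return Object of the same type with sub-threshold entries zeroed.
#' @export
threshold_matrix <- function(m, threshold) {
  v <- as_matrix(m)
  v[v < threshold] <- 0
  if (inherits(m, "connectivity_matrix")) {
    m$values[] <- v
    m
  } else v
}

#' Compare two ROI connectivity profiles across subjects (two-way ANOVA)
#'
#' Tests whether the vectors of effective connectivities of two ROIs (each
#' row: EC from every other region TO the ROI) differ across subjects, via
#' the interaction term of a two-way ANOVA with factors ROI (2 levels) and
#' target region, with subjects as replicates. The returned p-value is also
#' Bonferroni-corrected for the number of ROI pairs examined.
#'
#' @param per_subject_ec List of per-subject EC matrices (same ordering).
#' @param roi_a,roi_b Region ids or indices of the two ROIs.
#' @param n_pairs_for_correction Number of pairwise comparisons for the
#'   Bonferroni correction (default 1).
#' @return Object of class \code{roi_comparison}: \code{roi_a}, \code{roi_b},
#'   \code{f_stat}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{p_bonferroni}, \code{n_subjects}, \code{n_targets}.
#' @export
roi_profile_anova <- function(per_subject_ec, roi_a, roi_b,
                              n_pairs_for_correction = 1) {
  if (length(per_subject_ec) < 2L) stop("need at least 2 subjects")
  m1 <- as_matrix(per_subject_ec[[1]])
  ids <- rownames(m1) %||% paste0("R", seq_len(nrow(m1)))
  idx <- function(r) {
    if (is.character(r)) r <- match(r, ids)
    if (is.na(r) || r < 1 || r > nrow(m1)) stop("unknown ROI")
    as.integer(r)
  }
  ia <- idx(roi_a); ib <- idx(roi_b)
  if (ia == ib) stop("ROIs must be distinct")
  targets <- setdiff(seq_len(nrow(m1)), c(ia, ib))
  n_subj <- length(per_subject_ec)
  rows <- lapply(seq_len(n_subj), function(s) {
    m <- as_matrix(per_subject_ec[[s]])
    if (!identical(dim(m), dim(m1))) stop("EC dimension mismatch across subjects")
    data.frame(value = c(m[ia, targets], m[ib, targets]),
               roi = rep(c("a", "b"), each = length(targets)),
               target = factor(rep(targets, 2)))
  })
  d <- do.call(rbind, rows)
  d$roi <- factor(d$roi)
  tab <- anova(lm(value ~ roi * target, data = d))
  f <- tab["roi:target", "F value"]
  p <- tab["roi:target", "Pr(>F)"]
  if (is.na(f)) { f <- 0; p <- 1 }  # zero-variance interaction cell
  structure(list(roi_a = ids[ia], roi_b = ids[ib], f_stat = f,
                 df1 = tab["roi:target", "Df"],
                 df2 = tab["Residuals", "Df"],
                 p_value = p,
                 p_bonferroni = min(1, p * n_pairs_for_correction),
                 n_subjects = n_subj, n_targets = length(targets)),
            class = "roi_comparison")
}

#' @export
print.roi_comparison <- function(x, ...) {
  cat(sprintf("<roi_comparison> %s vs %s: interaction F(%d, %d) = %.3f, p = %.3g (Bonferroni %.3g)\n",
              x$roi_a, x$roi_b, x$df1, x$df2, x$f_stat, x$p_value,
              x$p_bonferroni))
  invisible(x)
}

#' Contralateral-to-ipsilateral connectivity ratio
#'
#' Ratio of the mean positive off-diagonal contralateral EC to the mean
#' positive off-diagonal ipsilateral EC, as a percentage (ratio of means, not
#' mean of ratios).
#'
#' @param ec_ipsi,ec_contra Matched connectivity matrices (ipsilateral and
#'   contralateral EC maps over the same ROI set).
#' @return Scalar percentage.
#' @export
ipsi_contra_ratio <- function(ec_ipsi, ec_contra) {
  pick <- function(m) {
    v <- as_matrix(m)
    if (nrow(v) == ncol(v)) v <- matrix(offdiag(v))   # drop self-links
    v[v > 0]
  }
  ipsi <- pick(ec_ipsi); contra <- pick(ec_contra)
  if (length(ipsi) == 0L || mean(ipsi) == 0) stop("zero ipsilateral mass")
  if (length(contra) == 0L) return(0)
  100 * mean(contra) / mean(ipsi)
}
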