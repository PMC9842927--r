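#' Region-by-time signal container
#'
#' Holds a region x time matrix of (simulated or observed) BOLD-like signals
#' together with its sampling interval and region labels. This is the unit on
#' which all correlations in the package are computed.
#'
#' @param data Numeric matrix, one row per region, one column per timepoint.
#' @param tr Sampling interval in seconds.
#' @param region_ids Character vector of region labels; defaults to rownames
#'   of \code{data} or \code{"R1"..."Rn"}.
#' @param subject_id,session_id Optional provenance tags.
#' @return An object of class \code{bold_timeseries}.
#' @export
bold_timeseries <- function(data, tr, region_ids = NULL,
                            subject_id = NA_character_,
                            session_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric")
  if (ncol(data) < 2L) stop("a timeseries needs at least 2 timepoints")
  if (any(!is.finite(data))) stop("`data` contains non-finite entries")
  check_scalar(tr, "tr", lower = 1e-12)
  region_ids <- region_ids %||% rownames(data) %||% paste0("R", seq_len(nrow(data)))
  if (length(region_ids) != nrow(data))
    stop("length of `region_ids` must equal nrow(data)")
  rownames(data) <- region_ids
  structure(list(data = data, tr = tr, region_ids = as.character(region_ids),
                 subject_id = subject_id, session_id = session_id),
            class = "bold_timeseries")
}

#' @export
print.bold_timeseries <- function(x, ...) {
  cat(sprintf("<bold_timeseries> %d regions x %d volumes, tr = %g s",
              nrow(x$data), ncol(x$data), x$tr))
  if (!is.na(x$subject_id)) cat(sprintf(" [%s/%s]", x$subject_id, x$session_id))
  cat("\n")
  invisible(x)
}

n_regions <- function(ts) nrow(ts$data)
n_volumes <- function(ts) ncol(ts$data)
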