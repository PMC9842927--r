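# Readers/writers for the package's delimited text formats, plus the
# end-to-end pipeline. All files are TSV with explicit region labels; numeric
# values are written at full double precision, locale-independent. Each data
# file has a JSON sidecar (<path>.meta.json) carrying its metadata.

meta_path <- function(path) paste0(path, ".meta.json")

write_meta <- function(path, meta) {
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
}

read_meta <- function(path) {
  mp <- meta_path(path)
  if (!file.exists(mp)) return(NULL)
  jsonlite::read_json(mp, simplifyVector = TRUE)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a labelled connectivity matrix (TSV)
#'
#' The file has a header row of region labels and a leading label column;
#' kind and tau go to a JSON sidecar. Writing then reading reproduces values
#' to full double precision and labels exactly.
#'
#' @param m A \code{connectivity_matrix} (or plain labelled matrix for
#'   \code{write_matrix}).
#' @param path File path.
#' @param kind,tau Used when the sidecar is absent (defaults "FC", 0).
#' @param regions Optional label vector: the matrix is permuted to this
#'   ordering on read.
#' @return \code{read_matrix} returns a \code{connectivity_matrix};
#'   \code{write_matrix} returns the path invisibly.
#' @export
write_matrix <- function(m, path, kind = NULL, tau = NULL) {
  if (inherits(m, "connectivity_matrix")) {
    v <- m$values; ids <- m$region_ids
    kind <- m$kind; tau <- m$tau
  } else {
    v <- as.matrix(m)
    if (nrow(v) != ncol(v)) stop("matrix must be square")
    ids <- rownames(v) %||% paste0("R", seq_len(nrow(v)))
    kind <- kind %||% "raw"; tau <- tau %||% 0
  }
  body <- cbind(ids, matrix(fmt_num(v), nrow(v), ncol(v)))
  lines <- c(paste(c("region", ids), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  write_meta(path, list(format = "connectivity_matrix", kind = kind,
                        tau = tau))
  invisible(path)
}

parse_tsv_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file has no body: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1]))
    stop(sprintf("ragged matrix file %s: line %d has %d fields, expected %d",
                 path, which(widths != widths[1])[1],
                 widths[widths != widths[1]][1], widths[1]))
  header <- cells[[1]][-1]
  ids <- vapply(cells[-1], `[[`, character(1), 1)
  vals <- vapply(cells[-1], function(r) {
    x <- suppressWarnings(as.numeric(r[-1]))
    if (any(is.na(x))) stop("non-numeric cell in ", path)
    x
  }, numeric(length(header)))
  m <- t(vals)
  dimnames(m) <- list(ids, header)
  if (!identical(ids, header))
    stop("row/column label mismatch in ", path)
  m
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, kind = NULL, tau = NULL, regions = NULL) {
  m <- parse_tsv_matrix(path)
  meta <- read_meta(path)
  kind <- kind %||% meta$kind %||% "FC"
  tau <- tau %||% meta$tau %||% 0
  if (!is.null(regions)) {
    if (!all(regions %in% rownames(m))) stop("requested labels missing from file")
    m <- m[regions, regions, drop = FALSE]
  }
  if (!kind %in% c("EC", "SC", "FC", "FC_tau")) return(m)  # untyped matrix
  connectivity_matrix(m, kind = kind, tau = tau, region_ids = rownames(m))
}

#' Write / read a region-by-time signal matrix (TSV)
#'
#' Rows are regions (first column = label, header = t1..tn); tr, subject and
#' session ride in the JSON sidecar. The sampling interval is mandatory at
#' read time.
#'
#' @param ts A \code{\link{bold_timeseries}}.
#' @param path File path.
#' @param n_regions_expected Optional check on the region count at read time.
#' @return \code{read_timeseries} returns a \code{bold_timeseries};
#'   \code{write_timeseries} returns the path invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "bold_timeseries"))
  body <- cbind(ts$region_ids,
                matrix(fmt_num(ts$data), nrow(ts$data), ncol(ts$data)))
  lines <- c(paste(c("region", paste0("t", seq_len(ncol(ts$data)))),
                   collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  write_meta(path, list(format = "bold_timeseries", tr = ts$tr,
                        subject_id = ts$subject_id,
                        session_id = ts$session_id))
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, n_regions_expected = NULL) {
  lines <- readLines(path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1]))
    stop(sprintf("ragged timeseries file %s at line %d", path,
                 which(widths != widths[1])[1]))
  ids <- vapply(cells[-1], `[[`, character(1), 1)
  vals <- vapply(cells[-1], function(r) {
    x <- suppressWarnings(as.numeric(r[-1]))
    if (any(is.na(x))) stop("non-numeric cell in ", path)
    x
  }, numeric(widths[1] - 1L))
  data <- t(vals)
  rownames(data) <- ids
  meta <- read_meta(path)
  if (is.null(meta) || is.null(meta$tr))
    stop("missing sidecar metadata (tr) for ", path)
  meta$tr <- as.numeric(meta$tr)
  if (!is.null(n_regions_expected) && nrow(data) != n_regions_expected)
    stop(sprintf("region count mismatch: file has %d, expected %d",
                 nrow(data), n_regions_expected))
  bold_timeseries(data, tr = meta$tr, region_ids = ids,
                  subject_id = meta$subject_id %||% NA_character_,
                  session_id = meta$session_id %||% NA_character_)
}

#' Run the full synthesize / measure / fit / analyze pipeline
#'
#' Composes the package end to end: generate a synthetic cohort from a seeded
#' ground truth (or load timeseries from disk), band-limit, compute the group
#' FC and lagged FC, fit the effective connectivity, and write the analysis
#' products plus a machine-readable JSON manifest (seeds, sizes, final fit
#' metrics). Reruns with the same config are bit-identical.
#'
#' @param config Named list (or path to a JSON file) with elements:
#'   \code{outdir}; \code{seed}; \code{synth} (list: n_regions, density,
#'   n_subjects, n_sessions, n_volumes, subject_jitter) or \code{timeseries}
#'   (character vector of TSV paths); \code{band} (f_lo, f_hi); \code{fit}
#'   (overrides for \code{\link{fit_config}}); \code{analyze} (list:
#'   fc_threshold, ec_display_threshold).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  outdir <- config$outdir %||% stop("config$outdir is required")
  seed <- as.integer(config$seed %||% stop("config$seed is required"))
  band <- as.numeric(config$band %||% c(0.008, 0.08))
  fit_over <- config$fit %||% list()
  cfg <- do.call(fit_config, c(fit_over, list(seed = seed)))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # -- validation before any compute
  tr <- config$tr %||% 1
  if (abs(cfg$tau / tr - round(cfg$tau / tr)) > 1e-8)
    stop("config: tau must be an integer multiple of tr")

  # -- stage: inputs
  stage <- "synth"
  gt <- NULL
  cohort <- tryCatch({
    if (!is.null(config$synth)) {
      s <- config$synth
      gt <- generate_ground_truth_ec(
        n_regions = s$n_regions %||% 20,
        density = s$density %||% 0.15,
        homotopic_boost = s$homotopic_boost %||% 2,
        seed = seed)
      write_matrix(gt$ec_true, file.path(outdir, "ec_true.tsv"))
      write_matrix(structural_mask_from_ec(gt, seed = seed + 1L),
                   file.path(outdir, "sc_mask.tsv"))
      utils::write.table(gt$parcellation,
                         file.path(outdir, "parcellation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      simulate_cohort(gt,
                      n_subjects = s$n_subjects %||% 20,
                      n_sessions = s$n_sessions %||% 4,
                      n_volumes = s$n_volumes %||% 900,
                      subject_jitter = s$subject_jitter %||% 0.05,
                      seed = seed + 2L)
    } else if (!is.null(config$timeseries)) {
      lapply(config$timeseries, read_timeseries)
    } else stop("config needs either `synth` or `timeseries`")
  }, error = function(e) stop(sprintf("pipeline stage `%s` failed: %s",
                                      stage, conditionMessage(e)), call. = FALSE))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  emp <- run_stage("connectivity", {
    pair <- empirical_pair_from_cohort(cohort, band = band, tau = cfg$tau)
    write_matrix(pair$fc_emp, file.path(outdir, "fc_emp.tsv"))
    write_matrix(pair$fc_tau_emp, file.path(outdir, "fc_tau_emp.tsv"))
    pair
  })

  fit <- run_stage("fit", {
    f_hat <- estimate_intrinsic_frequencies(cohort, band = band)
    params <- hopf_params(a = config$a %||% -0.02, f = f_hat,
                          beta = config$beta %||% 0.02,
                          dt = config$dt %||% 0.1, tr = tr,
                          n = length(f_hat))
    res <- fit_effective_connectivity(emp$fc_emp, emp$fc_tau_emp, params, cfg)
    write_matrix(res$ec, file.path(outdir, "ec_fitted.tsv"))
    utils::write.table(res$metric_history, file.path(outdir, "fit_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  run_stage("analyze", {
    az <- config$analyze %||% list()
    dd <- direction_difference(fit$ec, az$ec_display_threshold %||% 0.01)
    write_matrix(dd$display, file.path(outdir, "ec_direction_difference.tsv"),
                 kind = "raw")
    write_matrix(threshold_matrix(emp$fc_emp, az$fc_threshold %||% 0.4),
                 file.path(outdir, "fc_thresholded.tsv"))
  })

  manifest <- list(
    seed = seed, band = band, tau = cfg$tau,
    n_regions = length(cohort[[1]]$region_ids),
    n_runs = length(cohort),
    iterations = fit$iterations, converged = fit$converged,
    best_iter = fit$best_iter,
    final_fc_corr = fit$final_fc_corr,
    final_fc_tau_corr = fit$final_fc_tau_corr,
    ec_true_recovery = if (!is.null(gt))
      cor(offdiag(as_matrix(fit$ec)), offdiag(as_matrix(gt$ec_true)))
    else NULL)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
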