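#' Run the full immunostimulation analysis
#'
#' The one-call pipeline: detection-limit substitution, global-SD
#' normalization, control QC, significance grids against the pooled
#' negative control, signature-cytokine calls (paired, strict `p < alpha`
#' by default), top-k selection (unpaired, inclusive `p <= alpha` by
#' default — the induction-matrix convention), minimal covering panels,
#' drug co-exposure modulation calls, and hierarchical clustering of the
#' condition-by-cytokine response matrix.
#'
#' @param study A [study_table()], e.g. from [read_study()] or
#'   [generate_study()].
#' @param alpha Significance level used throughout.
#' @param signature_mode,topk_mode Wilcoxon mode for the signature and
#'   top-k grids (`"paired"`/`"unpaired"`).
#' @param signature_strict,topk_strict Strict (`p < alpha`) vs inclusive
#'   (`p <= alpha`) significance for each grid.
#' @param k Panel size of the top-k selection.
#' @param linkage Dendrogram linkage, `"complete"` or `"ward"`.
#' @param co_label Drug co-exposure label; modulation calls are skipped
#'   when no arm carries it.
#' @param cohort Cohort to analyse; default the study's first.
#' @param strict_qc Abort when the control QC fails?
#' @return An object of class `"iirmi_analysis"` with components `qc`,
#'   `grid_signature`, `grid_topk`, `signatures`, `topk`, `induction`,
#'   `covers`, `modulation`, `response_matrix`, `tree_conditions`,
#'   `tree_cytokines`, `correlation`, `scale_factors`, and the echoed
#'   settings in `$settings`.
#' @seealso [write_report_bundle()] to export every table.
#' @export
iirmi_analysis <- function(study, alpha = 0.05,
                           signature_mode = "paired",
                           topk_mode = "unpaired",
                           signature_strict = TRUE, topk_strict = FALSE,
                           k = 3L, linkage = c("complete", "ward"),
                           co_label = "TP", cohort = NULL,
                           strict_qc = FALSE) {
  stopifnot(inherits(study, "study_table"), alpha > 0, alpha < 1, k >= 1L)
  linkage <- match.arg(linkage)
  censored <- apply_censoring(study)
  norm <- normalize_by_global_sd(censored)
  qc <- qc_controls(norm, alpha = alpha)
  if (strict_qc && !qc$overall_pass) {
    stop("control QC failed (strict_qc = TRUE): ",
         paste(qc$cytokine_tests$cytokine[!qc$cytokine_tests$pass],
               collapse = ", "))
  }
  means <- average_replicates(.strip_norm(norm))
  if (is.null(cohort)) cohort <- means$cohort[1]

  grid_sig <- significance_grid(means, alpha, mode = signature_mode,
                                strict = signature_strict)
  grid_topk <- if (identical(signature_mode, topk_mode) &&
                   identical(signature_strict, topk_strict)) grid_sig
               else significance_grid(means, alpha, mode = topk_mode,
                                      strict = topk_strict)

  stimuli <- unique(study$design$stimulus)
  signatures <- lapply(stimuli, function(s)
    select_signature(grid_sig, s, cohort = cohort))
  names(signatures) <- stimuli
  topk <- lapply(stimuli, function(s)
    select_top_k(grid_topk, s, k = k, cohort = cohort))
  names(topk) <- stimuli

  induction <- matrix_from_topk(topk, study$panel)
  covers <- tryCatch(minimal_covers(induction),
                     error = function(e) structure(list(error =
                       conditionMessage(e)), class = "cover_report_failed"))

  has_co <- any(means$co_exposure == co_label)
  modulation <- if (has_co) {
    modulation_calls(means, co_label = co_label, alpha = alpha,
                     cohort = cohort)
  } else NULL

  rm_ <- build_response_matrix(means, cohort = cohort)
  tree_cond <- if (nrow(rm_) >= 2L) hier_cluster(rm_, "rows", linkage)
               else NULL
  tree_cyt <- if (ncol(rm_) >= 2L) hier_cluster(rm_, "columns", linkage)
              else NULL
  corr <- tryCatch(correlation_cluster(rm_, "columns", linkage),
                   error = function(e) NULL)

  out <- list(qc = qc, grid_signature = grid_sig, grid_topk = grid_topk,
              signatures = signatures, topk = topk, induction = induction,
              covers = covers, modulation = modulation,
              response_matrix = rm_, tree_conditions = tree_cond,
              tree_cytokines = tree_cyt, correlation = corr,
              scale_factors = norm$scale_factors,
              settings = list(alpha = alpha,
                              signature_mode = signature_mode,
                              topk_mode = topk_mode,
                              signature_strict = signature_strict,
                              topk_strict = topk_strict, k = k,
                              linkage = linkage, co_label = co_label,
                              cohort = cohort))
  class(out) <- "iirmi_analysis"
  out
}

#' Tabulate signature calls
#'
#' @param x An `"iirmi_analysis"` object (or a list of `signature_call`s).
#' @return data.frame with one row per stimulus: `stimulus`,
#'   `signature_cytokine`, `concentration`, `p_value`, `co_induced`
#'   (comma-joined), `n_co_induced`. Stimuli with no call get `NA`s.
#' @export
signature_table <- function(x) {
  calls <- if (inherits(x, "iirmi_analysis")) x$signatures else x
  do.call(rbind, lapply(names(calls), function(s) {
    cl <- calls[[s]]
    if (is.null(cl)) {
      data.frame(stimulus = s, signature_cytokine = NA_character_,
                 concentration = NA_real_, p_value = NA_real_,
                 co_induced = "", n_co_induced = 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(stimulus = s, signature_cytokine = cl$signature_cytokine,
                 concentration = cl$concentration, p_value = cl$p_value,
                 co_induced = paste(cl$co_induced, collapse = ", "),
                 n_co_induced = length(cl$co_induced),
                 stringsAsFactors = FALSE)
    }
  }))
}

#' @export
print.iirmi_analysis <- function(x, ...) {
  cat("IIRMI immunostimulation analysis\n")
  cat(sprintf("  alpha = %g | signature: %s/%s | top-%d: %s/%s | linkage: %s\n",
              x$settings$alpha, x$settings$signature_mode,
              if (x$settings$signature_strict) "p<a" else "p<=a",
              x$settings$k, x$settings$topk_mode,
              if (x$settings$topk_strict) "p<a" else "p<=a",
              x$settings$linkage))
  cat(sprintf("  QC: %s\n", if (x$qc$overall_pass) "PASS" else "FAIL"))
  st <- signature_table(x)
  called <- !is.na(st$signature_cytokine)
  cat(sprintf("  signatures called for %d/%d stimuli\n", sum(called),
              nrow(st)))
  if (inherits(x$covers, "cover_report")) {
    cat(sprintf("  minimum covering panel size: %d (%d alternatives)\n",
                x$covers$min_size, x$covers$n_covers))
  }
  if (!is.null(x$modulation)) {
    cat(sprintf("  co-exposure modulation calls: %d (%d inhibited, %d enhanced)\n",
                nrow(x$modulation),
                sum(x$modulation$direction == "inhibited"),
                sum(x$modulation$direction == "enhanced")))
  }
  invisible(x)
}

#' @export
summary.iirmi_analysis <- function(object, ...) {
  out <- list(signatures = signature_table(object),
              induction = object$induction, covers = object$covers,
              qc_pass = object$qc$overall_pass,
              modulation = object$modulation,
              settings = object$settings)
  class(out) <- "summary.iirmi_analysis"
  out
}

#' @export
print.summary.iirmi_analysis <- function(x, ...) {
  cat("Signature cytokines (lowest qualifying dose, winning p):\n")
  print(x$signatures, row.names = FALSE)
  cat("\nTop-k induction matrix (row sums):\n")
  print(rowSums(x$induction))
  if (inherits(x$covers, "cover_report")) {
    cat("\n")
    print(x$covers)
  }
  if (!is.null(x$modulation) && nrow(x$modulation)) {
    cat("\nCo-exposure modulation calls:\n")
    print(x$modulation[, c("stimulus", "cytokine", "direction", "p")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Heatmap of the clustered response matrix
#'
#' @param x An `"iirmi_analysis"` object.
#' @param ... Passed to [stats::heatmap()].
#' @export
plot.iirmi_analysis <- function(x, ...) {
  stats::heatmap(x$response_matrix,
                 Rowv = stats::as.dendrogram(x$tree_conditions),
                 Colv = stats::as.dendrogram(x$tree_cytokines),
                 scale = "none", ...)
  invisible(x)
}

#' Write every analysis artifact to a directory
#'
#' CSV tables for the grids, signatures, induction matrix (TRUE/FALSE
#' literals), modulation calls, response matrix and QC; Newick files for
#' the dendrograms; JSON for the covers report and a manifest echoing the
#' settings. Identical analyses write byte-identical bundles.
#'
#' @param fit An `"iirmi_analysis"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(fit, dir) {
  stopifnot(inherits(fit, "iirmi_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(as.data.frame(fit$grid_signature), "significance_grid_signature.csv")
  wcsv(as.data.frame(fit$grid_topk), "significance_grid_topk.csv")
  wcsv(signature_table(fit), "signatures.csv")
  im <- data.frame(stimulus = rownames(fit$induction),
                   ifelse(unclass(fit$induction), "TRUE", "FALSE"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  wcsv(im, "induction_matrix.csv")
  if (!is.null(fit$modulation)) wcsv(as.data.frame(fit$modulation),
                                     "modulation_calls.csv")
  rm_ <- data.frame(condition = rownames(fit$response_matrix),
                    fit$response_matrix, check.names = FALSE)
  wcsv(rm_, "response_matrix.csv")
  wcsv(fit$qc$cytokine_tests, "qc_cytokine_tests.csv")
  wcsv(fit$qc$replicate_cv, "qc_replicate_cv.csv")
  if (!is.null(fit$qc$replicate_correlation)) {
    wcsv(fit$qc$replicate_correlation, "qc_replicate_correlation.csv")
  }
  if (!is.null(fit$tree_conditions)) {
    p <- file.path(dir, "dendrogram_conditions.nwk")
    dendrogram_newick(fit$tree_conditions, p); paths <- c(paths, p)
  }
  if (!is.null(fit$tree_cytokines)) {
    p <- file.path(dir, "dendrogram_cytokines.nwk")
    dendrogram_newick(fit$tree_cytokines, p); paths <- c(paths, p)
  }
  if (inherits(fit$covers, "cover_report")) {
    p <- file.path(dir, "covers.json")
    jsonlite::write_json(list(min_size = fit$covers$min_size,
                              covers = fit$covers$covers),
                         p, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, p)
  }
  manifest <- list(package = "cytosig",
                   version = as.character(utils::packageVersion("cytosig")),
                   settings = fit$settings, qc_pass = fit$qc$overall_pass)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
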