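#' Normalize readings by each cytokine's global standard deviation
#'
#' Every reading is divided by its cytokine's sample standard deviation
#' (n-1 denominator) computed across all donors, conditions and cohorts in
#' the table, controls included. This brings cytokines onto roughly the
#' same scale without letting high-abundance analytes swamp global
#' analyses; because the scaling is a positive per-cytokine factor, every
#' downstream rank-test p-value is unchanged by it. Cytokines with zero
#' variance are flagged and passed through unscaled.
#'
#' @param table A censored [study_table()] (well-level; the default used by
#'   the pipeline, so the SD is taken over every collected value before
#'   replicate averaging) or any data.frame with `cytokine` and `value`
#'   columns, e.g. a `cytokine_means` table.
#' @return The input with `value` replaced by the normalized value and the
#'   original kept as `raw_value`; the per-cytokine scale factors are
#'   attached as a data.frame (`cytokine`, `sd`, `flagged`) under
#'   `scale_factors` (an attribute, or the `$scale_factors` element for a
#'   `study_table`).
#' @export
normalize_by_global_sd <- function(table) {
  is_study <- inherits(table, "study_table")
  df <- if (is_study) table$records else table
  if (!is.data.frame(df) || nrow(df) == 0L) stop("empty table")
  if (anyNA(df$value)) stop("absent values present; run apply_censoring() first")
  cyt <- unique(df$cytokine)
  sds <- vapply(cyt, function(k) {
    v <- df$value[df$cytokine == k]
    if (length(v) < 2L) stop("cytokine ", k, " has fewer than 2 values")
    stats::sd(v)
  }, numeric(1))
  flagged <- sds == 0
  scales <- data.frame(cytokine = cyt, sd = unname(sds),
                       flagged = unname(flagged), stringsAsFactors = FALSE)
  div <- ifelse(flagged, 1, sds)[match(df$cytokine, cyt)]
  df$raw_value <- df$value
  df$value <- df$value / div
  if (is_study) {
    table$records <- df
    table$scale_factors <- scales
    table
  } else {
    attr(df, "scale_factors") <- scales
    df
  }
}

#' Control-based quality checks
#'
#' Three checks on a normalized study: (1) per cytokine, a one-sided
#' Wilcoxon test that positive-control values exceed negative-control
#' values on replicate-averaged normalized readings; (2) per duplicate set,
#' the replicate percent CV on the raw (pg/mL) scale against a threshold;
#' (3) per treatment condition, the Pearson correlation between the first
#' and second replicate across donors and cytokines. CV is undefined when
#' the replicate mean is zero; such sets are flagged, not failed. The
#' overall pass flag is the conjunction of the per-cytokine NC-vs-PC
#' checks.
#'
#' @param table A normalized [study_table()] (see
#'   [normalize_by_global_sd()]); replicate-level records are required for
#'   the CV and correlation checks.
#' @param alpha Significance level for the NC-vs-PC test.
#' @param mode `"unpaired"` (default) pools control wells across donors;
#'   `"paired"` pairs each donor's PC with its own NC.
#' @param cv_threshold Percent CV acceptance threshold for duplicates.
#' @return An object of class `"qc_report"` with elements
#'   `cytokine_tests`, `replicate_cv`, `replicate_correlation`,
#'   `overall_pass`.
#' @export
qc_controls <- function(table, alpha = 0.05,
                        mode = c("unpaired", "paired"), cv_threshold = 25) {
  stopifnot(inherits(table, "study_table"))
  mode <- match.arg(mode)
  r <- table$records
  if (!any(r$role == "negative_control")) stop("no negative-control records")
  if (!any(r$role == "positive_control")) stop("no positive-control records")

  means <- average_replicates(.strip_norm(table))
  nc <- means[means$role == "negative_control", , drop = FALSE]
  pc <- means[means$role == "positive_control", , drop = FALSE]
  tests <- do.call(rbind, lapply(table$panel$name, function(k) {
    x <- pc$value[pc$cytokine == k]
    y <- nc$value[nc$cytokine == k]
    if (mode == "paired") {
      dn <- intersect(pc$donor[pc$cytokine == k], nc$donor[nc$cytokine == k])
      x <- x[match(dn, pc$donor[pc$cytokine == k])]
      y <- y[match(dn, nc$donor[nc$cytokine == k])]
    }
    res <- wilcoxon_test(x, y, mode)
    data.frame(cytokine = k, p = res$p_greater,
               pass = res$p_greater < alpha &&
                 stats::median(x) > stats::median(y),
               stringsAsFactors = FALSE)
  }))

  raw <- if ("raw_value" %in% names(r)) r$raw_value else r$value
  key <- paste(r$donor, r$cohort, .condition_key(r), r$cytokine, sep = "\r")
  first <- !duplicated(key)
  n_k <- rowsum(rep(1L, nrow(r)), key)
  s_k <- rowsum(raw, key)
  s2_k <- rowsum(raw^2, key)
  idx <- match(key[first], rownames(n_k))
  n_v <- n_k[idx, 1]; m_v <- s_k[idx, 1] / n_v
  var_v <- pmax(0, (s2_k[idx, 1] - n_v * m_v^2) / pmax(1, n_v - 1))
  cv <- ifelse(m_v == 0 | n_v < 2L, NA_real_, 100 * sqrt(var_v) / m_v)
  cvs <- data.frame(donor = r$donor[first], cohort = r$cohort[first],
                    condition = .condition_label(r$stimulus[first],
                                                 r$concentration[first],
                                                 r$co_exposure[first]),
                    cytokine = r$cytokine[first], n = as.integer(n_v),
                    cv = cv, flagged = is.na(cv),
                    pass = is.na(cv) | cv < cv_threshold,
                    stringsAsFactors = FALSE)
  rownames(cvs) <- NULL

  ckey <- paste(r$cohort, .condition_key(r), sep = "\r")
  reps <- sort(unique(r$replicate))
  cors <- NULL
  if (length(reps) >= 2L) {
    cors <- do.call(rbind, lapply(split(seq_len(nrow(r)), ckey), function(idx) {
      a <- r[idx, , drop = FALSE]
      va <- a$value[a$replicate == reps[1]]
      ka <- paste(a$donor, a$cytokine)[a$replicate == reps[1]]
      vb <- a$value[a$replicate == reps[2]]
      kb <- paste(a$donor, a$cytokine)[a$replicate == reps[2]]
      shared <- intersect(ka, kb)
      rr <- if (length(shared) >= 3L &&
                stats::sd(va[match(shared, ka)]) > 0 &&
                stats::sd(vb[match(shared, kb)]) > 0) {
        stats::cor(va[match(shared, ka)], vb[match(shared, kb)])
      } else NA_real_
      data.frame(cohort = a$cohort[1],
                 condition = .condition_label(a$stimulus[1],
                                              a$concentration[1],
                                              a$co_exposure[1]),
                 r = rr, n_pairs = length(shared), stringsAsFactors = FALSE)
    }))
    rownames(cors) <- NULL
  }

  structure(list(cytokine_tests = tests, replicate_cv = cvs,
                 replicate_correlation = cors,
                 overall_pass = all(tests$pass), alpha = alpha, mode = mode,
                 cv_threshold = cv_threshold),
            class = "qc_report")
}

# drop normalization bookkeeping so average_replicates sees one value column
.strip_norm <- function(table) {
  table$records$raw_value <- NULL
  table
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  NC vs PC (one-sided Wilcoxon, alpha = %g): %d/%d cytokines pass\n",
              x$alpha, sum(x$cytokine_tests$pass), nrow(x$cytokine_tests)))
  n_cv <- sum(!x$replicate_cv$flagged)
  cat(sprintf("  replicate %%CV < %g: %d/%d duplicate sets pass (%d flagged)\n",
              x$cv_threshold,
              sum(x$replicate_cv$pass & !x$replicate_cv$flagged), n_cv,
              sum(x$replicate_cv$flagged)))
  if (!is.null(x$replicate_correlation)) {
    cat(sprintf("  median replicate correlation: %.3f\n",
                stats::median(x$replicate_correlation$r, na.rm = TRUE)))
  }
  cat(sprintf("  overall: %s\n", if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}
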