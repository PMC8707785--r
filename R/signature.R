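#' Select the signature cytokine for one stimulus
#'
#' Scans the stimulus's tested doses in ascending order and stops at the
#' first dose where at least one cytokine is significantly elevated over
#' the pooled negative control; among the significant cytokines at that
#' dose, the one with the lowest p-value wins (ties broken by fixed panel
#' order). The other significant cytokines at the winning dose are reported
#' as co-induced.
#'
#' @param grid A [significance_grid()].
#' @param stimulus Stimulus name (must appear in the grid).
#' @param alpha Optional override of the grid's significance level; when
#'   given, significance is recomputed as `elevated & p < alpha` (or
#'   `<= alpha` when the grid was built with `strict = FALSE`).
#' @param cohort Cohort to analyse; defaults to the grid's first.
#' @return A list of class `"signature_call"` (`stimulus`,
#'   `signature_cytokine`, `concentration`, `dose_rank`, `p_value`,
#'   `co_induced`), or `NULL` when no dose qualifies.
#' @export
select_signature <- function(grid, stimulus, alpha = NULL, cohort = NULL) {
  g <- .grid_slice(grid, stimulus, cohort, alpha)
  for (dr in sort(unique(g$dose_rank))) {
    cell <- g[g$dose_rank == dr & g$significant, , drop = FALSE]
    if (nrow(cell) == 0L) next
    cell <- .order_by_p(cell, attr(grid, "panel"))
    out <- list(stimulus = stimulus,
                signature_cytokine = cell$cytokine[1],
                concentration = cell$concentration[1],
                dose_rank = dr,
                p_value = cell$p[1],
                co_induced = cell$cytokine[-1])
    class(out) <- "signature_call"
    return(out)
  }
  NULL
}

#' Select the top-k cytokines for one stimulus
#'
#' Ascending dose scan: the selection dose is the first at which at least
#' `k` cytokines are significantly elevated; the `k` with the lowest
#' p-values are returned (ties broken by panel order). When no dose yields
#' `k` significant cytokines, the significant set at the top dose is
#' returned and flagged short.
#'
#' @inheritParams select_signature
#' @param k Number of cytokines to select (3 reproduces the top-3
#'   induction-matrix convention).
#' @return A list of class `"topk_call"` (`stimulus`, `selected`,
#'   `p_values`, `concentration_used`, `dose_rank`, `short`).
#' @export
select_top_k <- function(grid, stimulus, k = 3L, alpha = NULL,
                         cohort = NULL) {
  stopifnot(k >= 1L)
  g <- .grid_slice(grid, stimulus, cohort, alpha)
  ranks <- sort(unique(g$dose_rank))
  for (dr in ranks) {
    cell <- g[g$dose_rank == dr & g$significant, , drop = FALSE]
    if (nrow(cell) < k) next
    cell <- .order_by_p(cell, attr(grid, "panel"))
    out <- list(stimulus = stimulus, selected = cell$cytokine[seq_len(k)],
                p_values = cell$p[seq_len(k)],
                concentration_used = cell$concentration[1], dose_rank = dr,
                short = FALSE)
    class(out) <- "topk_call"
    return(out)
  }
  top <- ranks[length(ranks)]
  cell <- g[g$dose_rank == top & g$significant, , drop = FALSE]
  cell <- .order_by_p(cell, attr(grid, "panel"))
  out <- list(stimulus = stimulus, selected = cell$cytokine,
              p_values = cell$p,
              concentration_used = if (nrow(cell)) cell$concentration[1]
                                   else NA_real_,
              dose_rank = if (nrow(cell)) top else NA_integer_,
              short = TRUE)
  class(out) <- "topk_call"
  out
}

.grid_slice <- function(grid, stimulus, cohort, alpha) {
  stopifnot(inherits(grid, "significance_grid"))
  if (!stimulus %in% grid$stimulus) {
    stop("stimulus not present in grid: ", stimulus)
  }
  if (is.null(cohort)) cohort <- grid$cohort[1]
  g <- grid[grid$stimulus == stimulus & grid$cohort == cohort &
              grid$co_exposure == "", , drop = FALSE]
  if (!is.null(alpha)) {
    strict <- isTRUE(attr(grid, "strict"))
    ok <- !is.na(g$p) & g$elevated %in% TRUE
    g$significant <- ok & (if (strict) g$p < alpha else g$p <= alpha)
  }
  g
}

.order_by_p <- function(cell, panel) {
  po <- panel$panel_order[match(cell$cytokine, panel$name)]
  cell[order(cell$p, po), , drop = FALSE]
}

#' @export
print.signature_call <- function(x, ...) {
  cat(sprintf("%s: signature cytokine %s at %g pg/mL (p = %.4g); %d co-induced%s\n",
              x$stimulus, x$signature_cytokine, x$concentration, x$p_value,
              length(x$co_induced),
              if (length(x$co_induced))
                paste0(": ", paste(x$co_induced, collapse = ", ")) else ""))
  invisible(x)
}

#' @export
print.topk_call <- function(x, ...) {
  cat(sprintf("%s: top-%d {%s} at %s pg/mL%s\n", x$stimulus,
              length(x$selected), paste(x$selected, collapse = ", "),
              format(x$concentration_used),
              if (x$short) " [short: design exhausted]" else ""))
  invisible(x)
}

#' Drug co-exposure modulation calls
#'
#' Tests, per (stimulus, cytokine), whether co-exposure to the drug
#' product changes the IIRMI-induced response: the values from matched
#' (donor, dose) arms with and without co-exposure are compared by a
#' two-sided Wilcoxon test, pooled over the stimulus's doses by default
#' (or per dose). Calls are emitted at `p < alpha`; the direction is
#' `"enhanced"` when the co-exposed median exceeds the stimulus-alone
#' median, `"inhibited"` otherwise.
#'
#' @param means A `cytokine_means` table (see [average_replicates()]).
#' @param co_label The co-exposure label to test (e.g. `"TP"`).
#' @param alpha Significance level.
#' @param mode `"paired"` (default) pairs matched (donor, dose) arms by
#'   signed-rank; `"unpaired"` compares the pooled samples by rank-sum.
#' @param per_dose Call per dose instead of pooling the stimulus's doses.
#' @param cohort Cohort to analyse; defaults to the first in the table.
#' @return A data.frame of class `"modulation_calls"`: `stimulus`
#'   (`concentration` when `per_dose`), `cytokine`, `direction`, `p`,
#'   `median_with`, `median_without`, `n_pairs`; one row per significant
#'   call.
#' @export
modulation_calls <- function(means, co_label = "TP", alpha = 0.05,
                             mode = c("paired", "unpaired"),
                             per_dose = FALSE, cohort = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(means))
  if (is.null(cohort)) cohort <- means$cohort[1]
  m <- means[means$cohort == cohort & means$role == "treatment", ,
             drop = FALSE]
  with_co <- m[m$co_exposure == co_label, , drop = FALSE]
  without <- m[m$co_exposure == "", , drop = FALSE]
  shared <- intersect(unique(with_co$stimulus), unique(without$stimulus))
  if (length(shared) == 0L) {
    stop("no stimulus has matched arms with and without co-exposure '",
         co_label, "'")
  }
  panel <- attr(means, "panel")
  cyt <- if (!is.null(panel)) panel$name else unique(m$cytokine)
  out <- list()
  for (s in shared) {
    doses <- if (per_dose) {
      sort(intersect(with_co$concentration[with_co$stimulus == s],
                     without$concentration[without$stimulus == s]))
    } else list(NULL)
    for (d in doses) {
      for (k in cyt) {
        a <- with_co[with_co$stimulus == s & with_co$cytokine == k, ,
                     drop = FALSE]
        b <- without[without$stimulus == s & without$cytokine == k, ,
                     drop = FALSE]
        if (!is.null(d)) {
          a <- a[a$concentration == d, , drop = FALSE]
          b <- b[b$concentration == d, , drop = FALSE]
        }
        ka <- paste(a$donor, a$concentration)
        kb <- paste(b$donor, b$concentration)
        pairs <- intersect(ka, kb)
        if (length(pairs) == 0L) next
        x <- a$value[match(pairs, ka)]
        y <- b$value[match(pairs, kb)]
        res <- wilcoxon_test(x, y, mode)
        if (res$p_two_sided < alpha) {
          out[[length(out) + 1L]] <- data.frame(
            stimulus = s,
            concentration = if (is.null(d)) NA_real_ else d,
            cytokine = k,
            direction = if (stats::median(x) > stats::median(y))
              "enhanced" else "inhibited",
            p = res$p_two_sided, median_with = stats::median(x),
            median_without = stats::median(y), n_pairs = length(pairs),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(stimulus = character(), concentration = numeric(),
               cytokine = character(), direction = character(),
               p = numeric(), median_with = numeric(),
               median_without = numeric(), n_pairs = integer(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  attr(calls, "alpha") <- alpha
  attr(calls, "mode") <- mode
  attr(calls, "co_label") <- co_label
  class(calls) <- c("modulation_calls", "data.frame")
  calls
}
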