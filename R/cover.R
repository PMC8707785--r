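#' Boolean induction matrix
#'
#' Stimuli-by-cytokines logical matrix marking which cytokines were
#' selected (top-k significant) for each stimulus; the combinatorial input
#' to reduced-panel design.
#'
#' @param m Logical matrix with stimulus rownames and cytokine colnames.
#' @param provenance `"from_grid"` (computed from data) or
#'   `"from_fixture"` (encoded reference).
#' @return The matrix, classed `"induction_matrix"` with a `provenance`
#'   attribute.
#' @export
induction_matrix <- function(m, provenance = c("from_grid", "from_fixture")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(m), is.logical(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("induction matrix needs stimulus rownames and cytokine colnames")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate row or column labels")
  }
  structure(m, provenance = provenance,
            class = c("induction_matrix", "matrix", "array"))
}

#' Build the induction matrix from top-k calls
#'
#' @param calls A list of `topk_call` objects (see [select_top_k()]), one
#'   per stimulus.
#' @param panel A [cytokine_panel()] fixing the column order.
#' @return An [induction_matrix()] with one row per call, `TRUE` where the
#'   cytokine was selected. An all-`FALSE` row (empty selection) raises a
#'   warning.
#' @export
matrix_from_topk <- function(calls, panel) {
  stopifnot(length(calls) > 0L)
  stim <- vapply(calls, function(cl) cl$stimulus, character(1))
  if (anyDuplicated(stim)) {
    stop("duplicate stimulus in calls: ", stim[duplicated(stim)][1])
  }
  if (!inherits(panel, "cytokine_panel")) panel <- cytokine_panel(panel)
  m <- matrix(FALSE, nrow = length(calls), ncol = nrow(panel),
              dimnames = list(stim, panel$name))
  for (cl in calls) {
    if (length(cl$selected) == 0L) {
      warning("empty selection for stimulus ", cl$stimulus,
              ": all-FALSE row")
      next
    }
    m[cl$stimulus, cl$selected] <- TRUE
  }
  induction_matrix(m, provenance = "from_grid")
}

#' Check whether a cytokine panel covers every stimulus
#'
#' A panel covers a stimulus when at least one of its cytokines is `TRUE`
#' in that stimulus's row — i.e. the reduced panel would give at least one
#' positive result for the stimulus.
#'
#' @param matrix An [induction_matrix()].
#' @param panel Character vector of cytokine names (subset of the matrix
#'   columns).
#' @return A list of class `"panel_cover"`: `cytokines`, `size`,
#'   `covered` (stimuli), `uncovered`, `is_cover`, `is_minimum` (`NA`
#'   unless filled by [minimal_covers()]).
#' @export
verify_panel <- function(matrix, panel) {
  stopifnot(inherits(matrix, "induction_matrix"))
  unk <- setdiff(panel, colnames(matrix))
  if (length(unk)) stop("unknown cytokine(s) in panel: ",
                        paste(unk, collapse = ", "))
  hit <- if (length(panel)) rowSums(matrix[, panel, drop = FALSE]) > 0
         else rep(FALSE, nrow(matrix))
  out <- list(cytokines = panel, size = length(panel),
              covered = rownames(matrix)[hit],
              uncovered = rownames(matrix)[!hit],
              is_cover = all(hit), is_minimum = NA)
  class(out) <- "panel_cover"
  out
}

#' @export
print.panel_cover <- function(x, ...) {
  cat(sprintf("panel {%s} (size %d): %s (%d/%d stimuli covered)\n",
              paste(x$cytokines, collapse = ", "), x$size,
              if (x$is_cover) "COVER" else "not a cover",
              length(x$covered), length(x$covered) + length(x$uncovered)))
  invisible(x)
}

#' Enumerate all minimum-size covering panels
#'
#' Exhaustive search by increasing panel cardinality: at the first
#' cardinality admitting at least one cover, the complete set of covers of
#' that size is returned in lexicographic column order. Exact search is
#' trivial at a 16-cytokine panel; the method reports every alternative
#' minimum panel rather than one greedy solution.
#'
#' @param matrix An [induction_matrix()]; every row must have at least one
#'   `TRUE`.
#' @param max_size Largest cardinality to search.
#' @param max_combinations Guard on the search-space size per cardinality.
#' @return A list of class `"cover_report"`: `min_size`, `covers` (list of
#'   character vectors), `n_covers`, plus the matrix dimensions.
#' @export
minimal_covers <- function(matrix, max_size = ncol(matrix),
                           max_combinations = 1e6) {
  stopifnot(inherits(matrix, "induction_matrix"), max_size >= 1L)
  empty <- rownames(matrix)[rowSums(matrix) == 0]
  if (length(empty)) {
    stop("no cover exists: stimulus with all-FALSE row: ",
         paste(empty, collapse = ", "))
  }
  p <- ncol(matrix)
  for (k in seq_len(min(max_size, p))) {
    if (choose(p, k) > max_combinations) {
      stop("search space at cardinality ", k,
           " exceeds max_combinations; refusing")
    }
    combos <- utils::combn(p, k)
    covers <- list()
    for (j in seq_len(ncol(combos))) {
      cols <- combos[, j]
      if (all(rowSums(matrix[, cols, drop = FALSE]) > 0)) {
        covers[[length(covers) + 1L]] <- colnames(matrix)[cols]
      }
    }
    if (length(covers)) {
      out <- list(min_size = k, covers = covers, n_covers = length(covers),
                  n_stimuli = nrow(matrix), n_cytokines = p)
      class(out) <- "cover_report"
      return(out)
    }
  }
  stop("no cover of size <= ", max_size, " exists")
}

#' @export
print.cover_report <- function(x, ...) {
  cat(sprintf("minimum covering panel size: %d (%d cover%s over %d stimuli)\n",
              x$min_size, x$n_covers, if (x$n_covers == 1) "" else "s",
              x$n_stimuli))
  for (cv in x$covers) cat("  {", paste(cv, collapse = ", "), "}\n")
  invisible(x)
}
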