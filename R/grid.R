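#' Significance grid of treatment arms against pooled negative control
#'
#' For every (stimulus, concentration, co-exposure, cytokine) cell of the
#' design, the treated replicate-averaged values across donors are compared
#' to the negative control by a two-sided Wilcoxon test. In paired mode
#' each donor's treated value is paired with that donor's own NC value
#' (signed-rank); in unpaired mode all NC values are pooled into one
#' reference sample (rank-sum). A cell is called significant only when the
#' p-value clears `alpha` *and* the treated median exceeds the NC median
#' (elevation gate: suppression never counts as induction). Cells with no
#' treated values are recorded as missing, never significant. Cohorts are
#' analysed separately.
#'
#' @param means A `cytokine_means` table (see [average_replicates()]),
#'   normalized or raw; rank tests are invariant to the per-cytokine
#'   scaling.
#' @param alpha Significance level.
#' @param mode `"paired"` (default, the signature-selection convention) or
#'   `"unpaired"` (the top-k/induction-matrix convention).
#' @param strict `TRUE` calls significance at `p < alpha`; `FALSE` at
#'   `p <= alpha`.
#' @param exact_cutoff Passed to [wilcoxon_test()].
#' @return A data.frame of class `"significance_grid"`: one row per cell
#'   with `cohort`, `stimulus`, `concentration`, `dose_rank`,
#'   `co_exposure`, `cytokine`, `p`, `elevated`, `significant`, `method`,
#'   `n`. Attributes record `alpha`, `mode`, `strict`, the panel and the
#'   design.
#' @export
significance_grid <- function(means, alpha = 0.05,
                              mode = c("paired", "unpaired"),
                              strict = TRUE, exact_cutoff = 12L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(means), nrow(means) > 0L)
  panel <- attr(means, "panel")
  design <- attr(means, "design")
  if (is.null(panel) || is.null(design)) {
    stop("means table lacks panel/design attributes; build it with average_replicates()")
  }
  out <- list()
  for (coh in unique(means$cohort)) {
    m <- means[means$cohort == coh, , drop = FALSE]
    nc <- m[m$role == "negative_control", , drop = FALSE]
    if (nrow(nc) == 0L) stop("cohort ", coh, " has no negative control")
    trt <- m[m$role == "treatment", , drop = FALSE]
    co_levels <- unique(trt$co_exposure)
    du <- unique(design[c("stimulus", "concentration", "dose_rank")])
    for (i in seq_len(nrow(du))) {
      s <- du$stimulus[i]; d <- du$concentration[i]; dr <- du$dose_rank[i]
      for (co in co_levels) {
        arm <- trt[trt$stimulus == s & trt$concentration == d &
                     trt$co_exposure == co, , drop = FALSE]
        for (k in panel$name) {
          xa <- arm[arm$cytokine == k, , drop = FALSE]
          nck <- nc[nc$cytokine == k, , drop = FALSE]
          if (nrow(xa) == 0L || nrow(nck) == 0L) {
            out[[length(out) + 1L]] <- data.frame(
              cohort = coh, stimulus = s, concentration = d, dose_rank = dr,
              co_exposure = co, cytokine = k, p = NA_real_,
              elevated = NA, significant = FALSE, method = NA_character_,
              n = 0L, stringsAsFactors = FALSE)
            next
          }
          if (mode == "paired") {
            dn <- intersect(xa$donor, nck$donor)
            x <- xa$value[match(dn, xa$donor)]
            y <- nck$value[match(dn, nck$donor)]
          } else {
            x <- xa$value
            y <- nck$value
          }
          res <- wilcoxon_test(x, y, mode, exact_cutoff = exact_cutoff)
          elev <- stats::median(x) > stats::median(y)
          p <- res$p_two_sided
          sig <- elev && (if (strict) p < alpha else p <= alpha)
          out[[length(out) + 1L]] <- data.frame(
            cohort = coh, stimulus = s, concentration = d, dose_rank = dr,
            co_exposure = co, cytokine = k, p = p, elevated = elev,
            significant = sig, method = res$method, n = length(x),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  attr(grid, "alpha") <- alpha
  attr(grid, "mode") <- mode
  attr(grid, "strict") <- strict
  attr(grid, "panel") <- panel
  attr(grid, "design") <- design
  class(grid) <- c("significance_grid", "data.frame")
  grid
}
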