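#' Condition-by-cytokine response matrix
#'
#' Mean normalized response per (treatment condition, cytokine), averaged
#' across donors (replicates were averaged upstream). Missing cells are
#' imputed as 0 — the post-censoring floor, where absence behaves like
#' non-detection — and flagged.
#'
#' @param means A `cytokine_means` table (see [average_replicates()]),
#'   normally on normalized values.
#' @param cohort Cohort to use; defaults to the first present.
#' @return A numeric matrix (conditions x cytokines) with condition labels
#'   like `"zymosan @1e+06 +TP"`; attributes `imputed` (logical matrix of
#'   imputed cells) and `conditions` (the arm metadata).
#' @export
build_response_matrix <- function(means, cohort = NULL) {
  stopifnot(is.data.frame(means), nrow(means) > 0L)
  if (is.null(cohort)) cohort <- means$cohort[1]
  m <- means[means$cohort == cohort, , drop = FALSE]
  if (nrow(m) == 0L) stop("no records for cohort ", cohort)
  panel <- attr(means, "panel")
  cyt <- if (!is.null(panel)) panel$name else unique(m$cytokine)
  lab <- .condition_label(m$stimulus, m$concentration, m$co_exposure)
  meta <- unique(data.frame(label = lab, stimulus = m$stimulus,
                            concentration = m$concentration,
                            co_exposure = m$co_exposure, role = m$role,
                            stringsAsFactors = FALSE))
  meta <- meta[order(meta$role, meta$stimulus, meta$concentration,
                     meta$co_exposure), , drop = FALSE]
  out <- matrix(NA_real_, nrow = nrow(meta), ncol = length(cyt),
                dimnames = list(meta$label, cyt))
  agg <- stats::aggregate(m$value, by = list(label = lab, cytokine = m$cytokine),
                          FUN = mean)
  out[cbind(match(agg$label, meta$label), match(agg$cytokine, cyt))] <- agg$x
  imputed <- is.na(out)
  out[imputed] <- 0
  attr(out, "imputed") <- imputed
  attr(out, "conditions") <- meta
  out
}

#' Agglomerative hierarchical clustering on Euclidean distances
#'
#' Clusters the rows or columns of a response matrix on pairwise Euclidean
#' distances with complete or Ward linkage (Ward on squared distances, the
#' `ward.D2` convention, so heights stay on the distance scale).
#'
#' @param matrix Numeric matrix, e.g. from [build_response_matrix()].
#' @param axis `"rows"` or `"columns"`.
#' @param linkage `"complete"` (default) or `"ward"`.
#' @return An object of class `"hclust"` (merge matrix, heights, leaf
#'   order), with the linkage and axis stored in `$method` and
#'   `$dist.method`.
#' @export
hier_cluster <- function(matrix, axis = c("rows", "columns"),
                         linkage = c("complete", "ward")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  m <- if (axis == "columns") t(matrix) else matrix
  if (nrow(m) < 2L) stop("need at least 2 items on the chosen axis")
  if (any(!is.finite(m))) stop("non-finite values in matrix")
  d <- stats::dist(m, method = "euclidean")
  stats::hclust(d, method = if (linkage == "ward") "ward.D2" else "complete")
}

#' Pearson-correlation clustering
#'
#' Computes the Pearson correlation between items (how well their values
#' co-vary across the other axis) and clusters on the dissimilarity
#' `1 - r`. Zero-variance items carry no correlation structure; they are
#' flagged and excluded.
#'
#' @inheritParams hier_cluster
#' @param linkage Linkage for the `1 - r` dissimilarity tree.
#' @return A list: `correlation` (the r matrix), `tree` (`hclust`),
#'   `excluded` (zero-variance item labels).
#' @export
correlation_cluster <- function(matrix, axis = c("rows", "columns"),
                                linkage = c("complete", "ward")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  m <- if (axis == "columns") t(matrix) else matrix
  v <- apply(m, 1L, stats::sd)
  excluded <- rownames(m)[v == 0]
  m <- m[v > 0, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 items with positive variance")
  r <- stats::cor(t(m))            # Pearson between items
  d <- stats::as.dist(1 - r)
  tree <- stats::hclust(d, method = if (linkage == "ward") "ward.D2"
                                    else "complete")
  list(correlation = r, tree = tree, excluded = excluded)
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths via the standard ultrametric
#' embedding of an `hclust` tree.
#'
#' @param tree An `"hclust"` object.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
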