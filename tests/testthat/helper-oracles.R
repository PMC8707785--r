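# Independent brute-force oracles, deliberately naive: enumeration and
# O(n^3) loops, sharing no code with the package's implementations.

# rank-sum test by full enumeration of all C(N, nx) group assignments
oracle_ranksum <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  d <- as.integer(round(2 * rank(pooled)))   # doubled mid-ranks
  s_obs <- sum(d[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  sums <- apply(combos, 2, function(idx) sum(d[idx]))
  tot <- ncol(combos)
  p_ge <- sum(sums >= s_obs) / tot
  p_le <- sum(sums <= s_obs) / tot
  list(p_two_sided = min(1, 2 * min(p_le, p_ge)), p_greater = p_ge)
}

# signed-rank test by full enumeration of all 2^n sign patterns
oracle_signrank <- function(x, y) {
  dd <- x - y
  dd <- dd[dd != 0]
  n <- length(dd)
  if (n == 0) return(list(p_two_sided = 1, p_greater = 1))
  d <- as.integer(round(2 * rank(abs(dd))))
  s_obs <- sum(d[dd > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% d)
  tot <- 2^n
  p_ge <- sum(sums >= s_obs) / tot
  p_le <- sum(sums <= s_obs) / tot
  list(p_two_sided = min(1, 2 * min(p_le, p_ge)), p_greater = p_ge)
}

# naive O(n^3) agglomerative clustering; returns the cophenetic matrix,
# which fully determines the dendrogram's merge heights
oracle_cophenetic <- function(X, linkage = c("complete", "ward")) {
  linkage <- match.arg(linkage)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  if (linkage == "ward") D <- D^2          # Lance-Williams on squared dist
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj) {
        a <- active[ii]; b <- active[jj]
        if (D[a, b] < bh) { bh <- D[a, b]; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    h <- if (linkage == "ward") sqrt(bh) else bh
    coph[clusters[[a]], clusters[[b]]] <- h
    coph[clusters[[b]], clusters[[a]]] <- h
    for (c_ in setdiff(active, c(a, b))) {
      D[a, c_] <- D[c_, a] <- if (linkage == "complete") {
        max(D[a, c_], D[b, c_])
      } else {
        ((sizes[a] + sizes[c_]) * D[a, c_] +
           (sizes[b] + sizes[c_]) * D[b, c_] -
           sizes[c_] * D[a, b]) / (sizes[a] + sizes[b] + sizes[c_])
      }
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  coph
}

# exact minimum set cover by enumerating every subset of columns
oracle_min_cover <- function(m) {
  p <- ncol(m)
  best <- Inf; covers <- list()
  for (mask in seq_len(2^p) - 1L) {
    cols <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    if (length(cols) > best) next
    if (all(rowSums(m[, cols, drop = FALSE]) > 0)) {
      if (length(cols) < best) { best <- length(cols); covers <- list() }
      covers[[length(covers) + 1L]] <- sort(colnames(m)[cols])
    }
  }
  list(min_size = best, covers = covers)
}

# hand-build a significance grid (for selection-rule tests)
make_grid_fixture <- function(rows, panel) {
  g <- do.call(rbind, lapply(rows, function(r) {
    data.frame(cohort = "fresh", stimulus = r$stimulus,
               concentration = r$concentration, dose_rank = r$dose_rank,
               co_exposure = "", cytokine = r$cytokine, p = r$p,
               elevated = r$elevated, significant = r$significant,
               method = "exact", n = 10L, stringsAsFactors = FALSE)
  }))
  attr(g, "alpha") <- 0.05
  attr(g, "mode") <- "paired"
  attr(g, "strict") <- TRUE
  attr(g, "panel") <- panel
  class(g) <- c("significance_grid", "data.frame")
  g
}

grid_cell <- function(stimulus, dose_rank, concentration, cytokine, p,
                      elevated = TRUE, significant = p < 0.05 && elevated) {
  list(stimulus = stimulus, dose_rank = dose_rank,
       concentration = concentration, cytokine = cytokine, p = p,
       elevated = elevated, significant = significant)
}

# a minimal 4-row well-formed study (1 donor, NC + one zymosan arm)
tiny_study_files <- function(dir, unit_mix = FALSE) {
  meas <- data.frame(
    donor = "G9L1", cohort = "fresh",
    stimulus = c("NC", "NC", "zymosan", "zymosan"),
    concentration = c(0, 0, if (unit_mix) 10 else 1e7, 1e7),
    unit = c("", "", if (unit_mix) "ug/mL" else "pg/mL", "pg/mL"),
    co_exposure = "", role = c("negative_control", "negative_control",
                               "treatment", "treatment"),
    cytokine = "IL-6", replicate = c(0, 1, 0, 1),
    value = c(10, 12, 100, 120), censor = "none",
    stringsAsFactors = FALSE)
  des <- iirmi_design()
  lim <- data.frame(cytokine = "IL-6", lloq = 1, uloq = 5e4)
  paths <- file.path(dir, c("meas.csv", "design.csv", "limits.csv"))
  write.csv(meas, paths[1], row.names = FALSE)
  write.csv(des, paths[2], row.names = FALSE)
  write.csv(lim, paths[3], row.names = FALSE)
  paths
}

# small fast generator config for property tests
small_config <- function(seed, n_donors = 5L, responses = NULL, ...) {
  panel <- cytokine_panel(c("IL-1a", "IL-6", "IL-8", "IP-10", "MCP-1",
                            "PGE-2"))
  design <- iirmi_design()
  design <- design[design$stimulus %in% c("zymosan", "LPS", "MDP"), ,
                   drop = FALSE]
  generator_config(n_donors = n_donors, panel = panel, design = design,
                   responses = responses, include_co_exposure = FALSE,
                   seed = seed, ...)
}
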