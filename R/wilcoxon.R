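# Exact, tie-aware Wilcoxon rank tests.
#
# Exactness is obtained by the generating-function (shift) algorithm on
# doubled mid-ranks: with ties broken as mid-ranks, every rank is a multiple
# of 1/2, so doubling makes all rank sums integers and the null distribution
# of the statistic is computed by exact integer counting, conditional on the
# observed tie pattern. All counts stay far below 2^53, so double arithmetic
# is exact. Beyond the exact cutoff a normal approximation with tie and
# continuity corrections is used.

.wx_cache <- new.env(parent = emptyenv())

# counts of k-subsets of the doubled-rank multiset `d` by doubled sum
.ranksum_counts <- function(d, k) {
  key <- paste(c(k, sort(d)), collapse = ",")
  hit <- .wx_cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- sum(d)
  f <- vector("list", k + 1L)
  f[[1L]] <- c(1, numeric(total))
  for (j in 2L:(k + 1L)) f[[j]] <- numeric(total + 1L)
  for (i in seq_along(d)) {
    for (kk in seq(min(i, k), 1L)) {
      prev <- f[[kk]]
      di <- d[i]
      f[[kk + 1L]] <- f[[kk + 1L]] +
        c(numeric(di), prev[seq_len(total + 1L - di)])
    }
  }
  out <- f[[k + 1L]]
  .wx_cache[[key]] <- out
  out
}

# counts of sign patterns of doubled ranks `d` by doubled positive-part sum
.signrank_counts <- function(d) {
  key <- paste(c("s", sort(d)), collapse = ",")
  hit <- .wx_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- 1
  for (di in d) {
    g <- c(f, numeric(di))
    g[(di + 1L):length(g)] <- g[(di + 1L):length(g)] + f
    f <- g
  }
  .wx_cache[[key]] <- f
  f
}

.two_sided <- function(p_le, p_ge) min(1, 2 * min(p_le, p_ge))

#' Wilcoxon rank test with an exact tie-aware small-sample path
#'
#' Unpaired mode is the rank-sum (Mann-Whitney) test on pooled mid-ranks;
#' paired mode is the signed-rank test on non-zero differences (zero
#' differences are dropped and counted). Small samples are tested exactly by
#' enumeration of the conditional null distribution, ties included; larger
#' samples use the normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples (equal length in paired mode).
#' @param mode `"unpaired"` or `"paired"`.
#' @param exact_cutoff Exact path is used when both groups have at most this
#'   many observations (unpaired), or when at most `2 * exact_cutoff`
#'   non-zero differences remain (paired).
#' @return A list of class `"wilcoxon_result"`: `statistic` (Mann-Whitney U,
#'   or the positive-rank sum W+), `p_two_sided`, `p_greater` (alternative:
#'   x tends larger), `method`, `n_x`, `n_y`, `tie_flag`, `n_zero`.
#' @examples
#' wilcoxon_test(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # exact 0.1
#' @export
wilcoxon_test <- function(x, y, mode = c("unpaired", "paired"),
                          exact_cutoff = 12L) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")

  if (mode == "unpaired") {
    nx <- length(x); ny <- length(y); n <- nx + ny
    pooled <- c(x, y)
    r <- rank(pooled)
    ties <- anyDuplicated(pooled) > 0L
    w <- sum(r[seq_len(nx)])                    # rank sum of x
    u <- w - nx * (nx + 1) / 2                  # Mann-Whitney U
    if (nx <= exact_cutoff && ny <= exact_cutoff) {
      d <- as.integer(round(2 * r))
      cnt <- .ranksum_counts(d, nx)
      tot <- choose(n, nx)
      s_obs <- as.integer(round(2 * w))
      s <- seq_along(cnt) - 1L
      p_ge <- sum(cnt[s >= s_obs]) / tot
      p_le <- sum(cnt[s <= s_obs]) / tot
      res <- list(statistic = u, p_two_sided = .two_sided(p_le, p_ge),
                  p_greater = p_ge, method = "exact")
    } else {
      mu <- nx * ny / 2
      tabs <- table(pooled)
      sigma <- sqrt((nx * ny / 12) *
                      ((n + 1) - sum(tabs^3 - tabs) / (n * (n - 1))))
      z <- u - mu
      p_two <- min(1, 2 * min(stats::pnorm((z - sign(z) * 0.5) / sigma),
                              stats::pnorm((z - sign(z) * 0.5) / sigma,
                                           lower.tail = FALSE)))
      p_gr <- stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE)
      res <- list(statistic = u, p_two_sided = p_two, p_greater = p_gr,
                  method = "normal_approx")
    }
    res$n_x <- nx; res$n_y <- ny; res$tie_flag <- ties; res$n_zero <- 0L
  } else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    dd <- x - y
    n_zero <- sum(dd == 0)
    dd <- dd[dd != 0]
    n <- length(dd)
    if (n == 0L) {
      res <- list(statistic = 0, p_two_sided = 1, p_greater = 1,
                  method = "exact", tie_flag = TRUE)
    } else {
      r <- rank(abs(dd))
      ties <- anyDuplicated(abs(dd)) > 0L
      w <- sum(r[dd > 0])                       # positive-rank sum W+
      if (n <= 2L * exact_cutoff) {
        d <- as.integer(round(2 * r))
        cnt <- .signrank_counts(d)
        tot <- 2^n
        s_obs <- as.integer(round(2 * w))
        s <- seq_along(cnt) - 1L
        p_ge <- sum(cnt[s >= s_obs]) / tot
        p_le <- sum(cnt[s <= s_obs]) / tot
        res <- list(statistic = w, p_two_sided = .two_sided(p_le, p_ge),
                    p_greater = p_ge, method = "exact")
      } else {
        mu <- n * (n + 1) / 4
        tabs <- table(abs(dd))
        sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                        sum(tabs^3 - tabs) / 48)
        z <- w - mu
        p_two <- min(1, 2 * min(stats::pnorm((z - sign(z) * 0.5) / sigma),
                                stats::pnorm((z - sign(z) * 0.5) / sigma,
                                             lower.tail = FALSE)))
        p_gr <- stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE)
        res <- list(statistic = w, p_two_sided = p_two, p_greater = p_gr,
                    method = "normal_approx")
      }
      res$tie_flag <- ties
    }
    res$n_x <- length(x); res$n_y <- length(y); res$n_zero <- n_zero
  }
  class(res) <- "wilcoxon_result"
  res
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon %s test: statistic = %g, p (two-sided) = %.4g, p (greater) = %.4g\n",
              x$method, x$statistic, x$p_two_sided, x$p_greater))
  cat(sprintf("  n = (%d, %d)%s%s\n", x$n_x, x$n_y,
              if (x$tie_flag) ", ties" else "",
              if (x$n_zero > 0) sprintf(", %d zero differences dropped",
                                        x$n_zero) else ""))
  invisible(x)
}
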