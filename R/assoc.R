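.assoc_result <- function(test, statistic, p, effect, n) {
  structure(list(test = test, statistic = statistic, p_two_sided = p,
                 effect = effect, n = n),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, two-sided p = %.4g\n",
              x$test, x$statistic, x$p_two_sided))
  if (length(x$effect))
    cat("  effect:", paste(sprintf("%s = %.4g", names(x$effect), x$effect),
                           collapse = ", "), "\n")
  cat("  n:", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2 x 2 table
#'
#' Exact p-value by the minimum-likelihood rule: the sum, over all tables
#' with the observed margins, of hypergeometric point probabilities no larger
#' than that of the observed table (with a small relative tolerance for
#' ties). The reported statistic is the sample odds ratio a*d / (b*c), with
#' Inf/0/NaN for zero cells as the arithmetic gives. A table with an empty
#' margin carries no information: p is defined as 1 with a warning.
#'
#' @param tab 2 x 2 integer matrix (rows = groups, columns =
#'   feature present / absent), or the count \code{a} if \code{b,c,d} given.
#' @param b,c,d Optional remaining counts (row-wise) when \code{tab} is the
#'   single count \code{a}.
#' @return An \code{assoc_result} with the odds ratio as statistic.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(0, 66, 8, 53), 2, byrow = TRUE))
fisher_exact_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) tab <- matrix(c(tab, b, c, d), 2, byrow = TRUE)
  if (!is.matrix(tab) || !all(dim(tab) == 2L))
    .stopf("fisher_exact_2x2: need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    .stopf("fisher_exact_2x2: counts must be nonnegative integers")
  if (sum(tab) < 1L) .stopf("fisher_exact_2x2: empty table")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("a margin of the 2x2 table is zero; p = 1 (no information)")
    p <- 1
  } else {
    p <- stats::fisher.test(tab)$p.value
  }
  .assoc_result("FISHER", statistic = or, p = p,
                effect = c(pct_row1 = 100 * tab[1, 1] / sum(tab[1, ]),
                           pct_row2 = 100 * tab[2, 1] / sum(tab[2, ])),
                n = rowSums(tab))
}

## all permutations of 1..n as an n! x n integer matrix (n small)
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

#' Mann-Whitney U test
#'
#' U statistic computed from midranks. For combined samples of at most 20
#' observations the two-sided p-value is exact, by enumeration of all
#' assignments of the pooled values to the two groups (valid under ties);
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples (titers).
#' @return An \code{assoc_result} with U (for \code{x}) as statistic and the
#'   rank-biserial correlation as effect.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 20, 30))  # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    .stopf("mann_whitney_u: both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= 20L) {
    cmb <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    dev <- abs(u - mu)
    p <- mean(abs(u_all - mu) >= dev - 1e-9)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  .assoc_result("MANNWHITNEY", statistic = u, p = p,
                effect = c(rank_biserial = 2 * u / (n1 * n2) - 1),
                n = c(n_x = n1, n_y = n2))
}

#' Two-sample t-test on log10 titers, with geometric mean titers
#'
#' Pooled-variance Student t-test on log10-transformed titers; the natural
#' comparison for lognormal-like LU data. Reports each group's geometric
#' mean titer GMT = 10^(mean log10 titer).
#'
#' @param x,y Strictly positive titer samples, each of size at least 2.
#' @return An \code{assoc_result} with the t statistic and GMTs as effect.
#' @export
#' @examples
#' ttest_log_titers(c(10, 1000), c(20, 2000))$effect  # GMT x = 100
ttest_log_titers <- function(x, y) {
  if (any(x <= 0) || any(y <= 0))
    .stopf("ttest_log_titers: titers must be strictly positive")
  if (length(x) < 2L || length(y) < 2L)
    .stopf("ttest_log_titers: each group needs n >= 2")
  tt <- stats::t.test(log10(x), log10(y), var.equal = TRUE)
  .assoc_result("TTEST_LOG", statistic = unname(tt$statistic),
                p = tt$p.value,
                effect = c(gmt_x = 10^mean(log10(x)),
                           gmt_y = 10^mean(log10(y))),
                n = c(n_x = length(x), n_y = length(y)))
}

## exact two-sided permutation p for Spearman, chunked over the first index
.spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  obs <- sum(rx * ry)
  ctr <- n * mean(rx) * mean(ry)
  dev <- abs(obs - ctr)
  sub <- .all_perms(n - 1L)
  count <- 0
  for (i in seq_len(n)) {
    rest <- ry[-i]
    s <- rx[1] * ry[i] +
      as.vector(matrix(rest[sub], nrow(sub)) %*% rx[-1])
    count <- count + sum(abs(s - ctr) >= dev - 1e-9)
  }
  count / (n * nrow(sub))
}

#' Spearman rank correlation
#'
#' Midrank Spearman correlation of paired samples. The two-sided p-value is
#' an exact permutation p for n <= 10 (enumeration of all pairings) and the
#' t-approximation with n - 2 degrees of freedom otherwise.
#'
#' @param x,y Paired numeric samples, n >= 3.
#' @return An \code{assoc_result} with rho as statistic.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) .stopf("spearman_rho: samples must be paired")
  n <- length(x)
  if (n < 3L) .stopf("spearman_rho: need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    .stopf("spearman_rho: constant input, correlation undefined")
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    p <- .spearman_perm_p(rx, ry)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  .assoc_result("SPEARMAN", statistic = rho, p = p,
                effect = c(rho = rho), n = n)
}

#' Reconstruct an integer count from a printed percentage
#'
#' Inverts display rounding: returns round(pct * n / 100), half away from
#' zero, and verifies that the reconstructed count re-rounds to the printed
#' percent. If it does not, the reconstruction is ambiguous and an error
#' lists every candidate count that does re-round (possibly none).
#'
#' @param pct Printed percentage in [0, 100].
#' @param n Group size.
#' @return Integer count.
#' @export
#' @examples
#' counts_from_percent(13, 61)  # 8, since 8/61 = 13.1% prints as 13
counts_from_percent <- function(pct, n) {
  if (pct < 0 || pct > 100) .stopf("counts_from_percent: pct outside [0,100]")
  if (n < 1L) .stopf("counts_from_percent: n must be >= 1")
  k <- round_half_away(pct * n / 100)
  if (round_half_away(100 * k / n) == pct) return(as.integer(k))
  cand <- which(vapply(0:n, function(i)
    round_half_away(100 * i / n) == pct, logical(1))) - 1L
  .stopf("ambiguous reconstruction: %.6g%% of %d has no consistent count via rounding; candidates re-rounding to %.6g%%: %s",
         pct, n, pct,
         if (length(cand)) paste(cand, collapse = ", ") else "(none)")
}

#' Fisher's exact test from printed percentages
#'
#' Convenience wrapper: reconstructs both counts with
#' [counts_from_percent()] and runs [fisher_exact_2x2()] on the resulting
#' table (rows = the two groups, columns = feature present / absent).
#'
#' @param pct1,n1 Printed percent and size of group 1.
#' @param pct2,n2 Printed percent and size of group 2.
#' @return An \code{assoc_result}; the reconstructed table is attached as
#'   attribute \code{"table"}.
#' @export
fisher_from_percents <- function(pct1, n1, pct2, n2) {
  k1 <- counts_from_percent(pct1, n1)
  k2 <- counts_from_percent(pct2, n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  res <- fisher_exact_2x2(tab)
  attr(res, "table") <- tab
  res
}

#' Screen binary features for association with a two-level grouping
#'
#' For every requested feature, builds the 2 x 2 table of feature presence
#' against the grouping and runs the two-sided Fisher's exact test. Raw
#' p-values are the headline output; Benjamini-Hochberg adjusted values are
#' appended as a clearly supplementary column. Rows with missing feature
#' values are dropped per feature; a feature leaving an empty stratum is
#' skipped with a message.
#'
#' @param features Data frame (or matrix) of binary 0/1 or logical columns.
#' @param group Factor or vector with exactly two used levels, parallel to
#'   the rows of \code{features}.
#' @param which Feature columns to test (default: all).
#' @return Data frame: feature, counts a/b/c/d (group1 feature+/-, group2
#'   feature+/-), odds_ratio, p, p_adj_bh.
#' @export
association_screen <- function(features, group, which = colnames(features)) {
  features <- as.data.frame(features)
  g <- factor(group)
  lev <- levels(droplevels(g))
  if (length(lev) != 2L)
    .stopf("association_screen: group must have exactly two used levels")
  rows <- lapply(which, function(f) {
    v <- features[[f]]
    keep <- !is.na(v) & !is.na(g)
    v <- as.logical(v[keep]); gk <- g[keep]
    if (sum(gk == lev[1]) == 0L || sum(gk == lev[2]) == 0L) {
      message("association_screen: empty stratum for '", f, "', skipped")
      return(NULL)
    }
    tab <- matrix(c(sum(v & gk == lev[1]), sum(!v & gk == lev[1]),
                    sum(v & gk == lev[2]), sum(!v & gk == lev[2])),
                  2, byrow = TRUE)
    res <- suppressWarnings(fisher_exact_2x2(tab))
    data.frame(feature = f, a = tab[1, 1], b = tab[1, 2],
               c = tab[2, 1], d = tab[2, 2],
               odds_ratio = res$statistic, p = res$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("association_screen: no testable features")
  out$p_adj_bh <- stats::p.adjust(out$p, method = "BH")
  attr(out, "group_levels") <- lev
  out
}
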