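## Independent brute-force oracles used to check the exact tests and the ROC
## scan. Deliberately written as direct enumerations, sharing no code with
## the package internals.

## Fisher two-sided p by explicit hypergeometric enumeration over all tables
## with the observed margins (minimum-likelihood rule).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- vapply(a_range, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), numeric(1))
  p_obs <- pr[match(tab[1, 1], a_range)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

## Mann-Whitney exact two-sided p by enumerating every assignment of the
## pooled values to group 1 and counting tie-aware pairwise wins directly.
oracle_mwu_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(x, y) - mu)
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, function(i) u_of(pool[i], pool[-i]))
  mean(abs(u_all - mu) >= obs - 1e-9)
}

## Spearman exact two-sided p by full permutation of one margin
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- abs(stats::cor(rx, ry))
  perm_mat <- function(v) {
    if (length(v) == 1L) return(matrix(v))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perm_mat(v[-i]))))
  }
  pm <- perm_mat(seq_len(n))
  rhos <- apply(pm, 1, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rhos) >= rho_obs - 1e-9)
}

## best achievable Youden J over all thresholds, by direct scan of every
## classification the data admits
oracle_best_j <- function(x_sle, x_hc) {
  cand <- c(-Inf, sort(unique(c(x_sle, x_hc))), Inf)
  j <- vapply(cand, function(ct)
    100 * mean(x_sle > ct) + 100 * mean(x_hc <= ct) - 100, numeric(1))
  max(j)
}
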