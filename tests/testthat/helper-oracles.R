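# Independent brute-force oracles used to check the implementations.
# These are deliberately literal (two nested loops, full enumeration);
# they never share code with the package.

# SNIP recurrence, written as two explicit loops over the definition
snip_oracle <- function(y, iterations, use_lls = FALSE) {
  n <- length(y)
  v <- if (use_lls) log(log(sqrt(y + 1) + 1) + 1) else y
  for (i in seq(iterations, 1L)) {
    w <- v
    for (m in (i + 1):(n - i)) {
      avg <- (v[m - i] + v[m + i]) / 2
      if (avg < v[m]) w[m] <- avg
    }
    v <- w
  }
  b <- if (use_lls) (exp(exp(v) - 1) - 1)^2 - 1 else v
  pmin(pmax(b, 0), y)
}

# AUROC as an explicit double loop over all (a, b) pairs
auroc_oracle <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    if (y > x) wins <- wins + 1
    else if (y == x) wins <- wins + 0.5
  }
  wins / (length(a) * length(b))
}

# exact two-sided WMW p by full enumeration of label assignments
wmw_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher p by enumeration over the hypergeometric support
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# product-limit estimator computed directly from its definition
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(times = ut, survival = surv)
}
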