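# Independent brute-force oracles used to check package computations.
# These deliberately avoid the code paths (and, where feasible, the base
# helpers) used by the implementation.

# average ranks from the definition: #smaller + (#equal + 1)/2
bruteRank <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, 0)
}

# product-moment correlation from the direct sum formula
brutePearson <- function(x, y) {
  sx <- x - sum(x) / length(x)
  sy <- y - sum(y) / length(y)
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

bruteSpearman <- function(x, y) brutePearson(bruteRank(x), bruteRank(y))

# BH step-up from the definition: sort ascending, q_(i) = min_{j>=i} p_(j)*m/j
# capped at 1, returned in the original order
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(po[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- q
  out
}

# AUROC as the normalized Mann-Whitney statistic on score ranks
bruteAuroc <- function(score, positive) {
  rk <- bruteRank(score)
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  (sum(rk[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Kruskal-Wallis H from the textbook rank-sum formula (no-tie form)
bruteKruskalH <- function(values, groups) {
  rk <- bruteRank(values)
  n <- length(values)
  groups <- as.character(groups)
  h <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    h <- h + sum(idx) * (mean(rk[idx]) - (n + 1) / 2)^2
  }
  12 / (n * (n + 1)) * h
}

# Welch two-sample t statistic and df from the textbook formulas
bruteWelch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  sa <- va / length(a)
  sb <- vb / length(b)
  list(t = (mean(a) - mean(b)) / sqrt(sa + sb),
       df = (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1)))
}
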