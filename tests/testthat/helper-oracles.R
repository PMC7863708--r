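# Independent statistical oracles used to cross-check the package's test
# wrappers. These deliberately re-derive everything from first principles
# (rank formulas, exhaustive enumeration) rather than calling the same
# routines the implementation wraps.

# Tie-corrected Kruskal-Wallis H from the rank-sum formula.
oracleKruskalH <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- rank(x)  # mid-ranks
  sizes <- vapply(groups, length, 1L)
  idx <- rep(seq_along(groups), sizes)
  rsum <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact two-sided rank-sum p-value by full enumeration of all C(N, na)
# group assignments (tie-free data only).
oracleExactRankSumP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(sel) sum(rank(pooled)[sel]) - na * (na + 1) / 2
  uObs <- u_of(seq_len(na))
  sels <- utils::combn(length(pooled), na, simplify = FALSE)
  us <- vapply(sels, u_of, 0)
  cdfLo <- mean(us <= uObs)
  cdfHi <- mean(us >= uObs)
  min(1, 2 * min(cdfLo, cdfHi))
}

# Normal-approximation rank-sum p with mid-rank tie correction and
# continuity correction, from the textbook formulas.
oracleNormalRankSumP <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- w - na * nb / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), 1 - stats::pnorm(z)))
}

# Shoelace polygon area.
shoelaceArea <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
}

polygonPerimeter <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(sqrt((v[j, 1L] - v[, 1L])^2 + (v[j, 2L] - v[, 2L])^2))
}
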