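# Independent brute-force oracles, deliberately implemented with different
# algorithms than the package (Floyd-Warshall instead of BFS, matrix-power
# path counting instead of Brandes accumulation, permutation enumeration
# instead of the normal approximation).

# All-pairs shortest path lengths by Floyd-Warshall.
oracleDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# DC / Ne / BC by direct definitions. Shortest-path counts use the fact that
# every length-d(s,t) walk is a shortest path: sigma_st = (A^d)[s,t].
oracleNodalMetrics <- function(A) {
  n <- nrow(A)
  D <- oracleDistances(A)
  dc <- colSums(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  ne <- rowSums(inv) / (n - 1)
  P <- vector("list", n)
  P[[1]] <- A
  if (n >= 2) for (l in 2:n) P[[l]] <- P[[l - 1]] %*% A
  sigma <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d) || d == 0) return(0)
    P[[d]][s, t]
  }
  bc <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == i || t == i) next
      dst <- D[s, t]
      if (!is.finite(dst)) next
      if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
          D[s, i] + D[i, t] == dst)
        acc <- acc + sigma(s, i) * sigma(i, t) / sigma(s, t)
    }
    bc[i] <- acc
  }
  list(DC = dc, Ne = ne, BC = bc)
}

# Dense adjacency of the graph whose upper-triangle edges are the set bits
# of `code` (exhaustive enumeration of labeled graphs).
graphFromCode <- function(n, code) {
  A <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  bits <- as.integer(intToBits(code))[seq_len(m)]
  A[upper.tri(A)] <- bits
  A + t(A)
}

randomAdjacency <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# Exact Mann-Whitney by full enumeration of group assignments: U statistic
# (pairwise count definition) and exact two-sided permutation p-value.
oracleMannWhitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  Ustat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U <- Ustat(x, y)
  pool <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  mu <- n1 * n2 / 2
  Us <- apply(idx, 2, function(ii) Ustat(pool[ii], pool[-ii]))
  pExact <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  list(U = U, pExact = pExact)
}

# Partial correlation of ranks via the precision matrix (a route that never
# touches regression residuals).
oraclePartialSpearman <- function(x, y, covs) {
  covs <- as.matrix(covs)
  R <- cbind(rank(x), rank(y), apply(covs, 2, rank))
  Om <- solve(cor(R))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

smallConfig <- function(...) {
  defaults <- list(nPatients = 4L, nControls = 4L, nRegions = 12L,
                   nTimepoints = 40L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohortConfig, args)
}
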