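# FC construction, Fisher z, sparsity binarization, small-world check.

test_that("pearsonFC matches the textbook formula and flags bad input", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5), c = c(4, 3, 2, 1))
  C <- pearsonFC(m)
  textbook <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  expect_equal(C["a", "b"], textbook(m[, 1], m[, 2]))
  expect_equal(C["a", "c"], textbook(m[, 1], m[, 3]))
  expect_equal(C["b", "c"], textbook(m[, 2], m[, 3]))
  expect_equal(diag(C), setNames(rep(1, 3), colnames(m)))

  # identical and negated columns
  m2 <- cbind(x = c(1, 3, 2, 5), y = c(1, 3, 2, 5), z = -c(1, 3, 2, 5))
  C2 <- pearsonFC(m2)
  expect_equal(C2["x", "y"], 1)
  expect_equal(C2["x", "z"], -1)

  expect_error(pearsonFC(cbind(a = c(1, 1, 1), b = c(1, 2, 3))), "a")
  expect_error(pearsonFC(matrix(rnorm(4), 2, 2)), "3 timepoints")
})

test_that("fisherZ is atanh off-diagonal with zero diagonal and clamping", {
  r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0, -0.5, 0, 1), 3)
  z <- fisherZ(r)
  expect_equal(z[1, 2], atanh(0.5))
  expect_equal(z[1, 2], 0.5493, tolerance = 1e-3)
  expect_equal(z[1, 3], -z[1, 2])  # odd symmetry
  expect_equal(z[2, 3], 0)
  expect_equal(diag(z), rep(0, 3))
  rBad <- matrix(c(1, 1, 1, 1), 2)
  expect_warning(zB <- fisherZ(rBad), "clamped")
  expect_equal(zB[1, 2], atanh(1 - 1e-7))
})

test_that("binarization keeps exactly round(s*N(N-1)/2) edges with the tie rule", {
  # all-equal z: lexicographically smallest pairs win
  z <- matrix(1, 4, 4); diag(z) <- 0
  A <- binarizeAtSparsity(z, 0.5)  # k = round(3) = 3
  expect_equal(sum(A) / 2, 3)
  expect_equal(A[1, 2], 1); expect_equal(A[1, 3], 1); expect_equal(A[1, 4], 1)
  expect_equal(A[2, 3], 0)

  # distinct ranks: exactly the top-k pairs (sort oracle)
  set.seed(1)
  N <- 9
  z2 <- matrix(0, N, N)
  z2[upper.tri(z2)] <- rnorm(N * (N - 1) / 2)
  z2 <- z2 + t(z2)
  for (s in c(0.15, 0.3, 0.5)) {
    k <- round(s * N * (N - 1) / 2)
    A2 <- binarizeAtSparsity(z2, s)
    expect_equal(sum(A2) / 2, k)
    cutoff <- sort(z2[upper.tri(z2)], decreasing = TRUE)[k]
    expect_true(all(z2[A2 == 1] >= cutoff))
  }

  # saturation and degenerate cases
  expect_warning(Afull <- binarizeAtSparsity(z2, 0.999), "saturates")
  expect_equal(sum(Afull) / 2, N * (N - 1) / 2)
  expect_error(binarizeAtSparsity(z2, 0.001), "zero edges")
})

test_that("edge sets are nested across the sweep and invariant to the r/z scale", {
  set.seed(2)
  ts <- matrix(rnorm(50 * 12), 50, 12)
  r <- pearsonFC(ts); z <- fisherZ(r)
  prev <- NULL
  for (s in sparsityThresholds(0.1, 0.5, 0.1)) {
    A <- binarizeAtSparsity(z, s)
    if (!is.null(prev)) expect_true(all(A[prev == 1] == 1))
    prev <- A
    # monotone transform: binarizing r or z gives the same network
    expect_identical(A, binarizeAtSparsity(r - diag(diag(r)), s))
  }
})

test_that("relabeling regions permutes the network identically", {
  set.seed(3)
  ts <- matrix(rnorm(60 * 10), 60, 10)
  z <- fisherZ(pearsonFC(ts))
  perm <- sample(10)
  A <- binarizeAtSparsity(z, 0.3)
  Ap <- binarizeAtSparsity(z[perm, perm], 0.3)
  expect_equal(Ap, A[perm, perm])
})

test_that("small-world statistics behave on reference topologies", {
  # complete graph: rewiring is a no-op, all ratios 1
  K10 <- matrix(1, 10, 10); diag(K10) <- 0
  swK <- smallWorldness(K10, nRandom = 5, seed = 1)
  expect_equal(swK$gamma, 1)
  expect_equal(swK$lambda, 1)
  expect_equal(swK$sigma, 1)

  # ring lattice N=20, k=4 neighbors: classic small-world precursor,
  # high clustering relative to rewired references
  N <- 20
  ring <- matrix(0, N, N)
  for (i in seq_len(N)) for (d in 1:2) {
    j <- ((i - 1 + d) %% N) + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  sw <- smallWorldness(ring, nRandom = 20, seed = 4)
  expect_gt(sw$gamma, 1)
  expect_gt(sw$sigma, 1)

  # determinism
  sw2 <- smallWorldness(ring, nRandom = 20, seed = 4)
  expect_identical(sw, sw2)
})
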