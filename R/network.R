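# Functional network construction: Pearson FC, Fisher z, sparsity-threshold
# binarization with deterministic tie-breaking, small-world verification.

#' Sparsity sweep thresholds
#'
#' The default sweep binarizes each connectivity matrix at edge densities
#' 0.10, 0.11, ..., 0.50 (41 thresholds).
#'
#' @param sMin,sMax,step sweep bounds and step.
#' @return increasing numeric vector of densities in (0, 1).
#' @export
sparsityThresholds <- function(sMin = 0.10, sMax = 0.50, step = 0.01) {
  if (sMin <= 0 || sMax >= 1 || sMin > sMax || step <= 0)
    stop("invalid sweep: need 0 < sMin <= sMax < 1 and step > 0")
  seq(sMin, sMax, by = step)
}

#' Pearson functional connectivity
#'
#' Region-by-region Pearson correlation of a timepoints-by-regions BOLD
#' matrix (edge construction).
#'
#' @param ts numeric T x N matrix, T >= 3, no constant columns.
#' @return symmetric N x N correlation matrix, unit diagonal.
#' @export
pearsonFC <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts) || anyNA(ts))
    stop("time series must be numeric with no missing values")
  if (nrow(ts) < 3L)
    stop("need at least 3 timepoints to correlate (got ", nrow(ts), ")")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant time series in region(s): ", paste(bad, collapse = ", "))
  }
  C <- cor(ts)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies `atanh` elementwise off the diagonal; the diagonal is forced to
#' zero. Off-diagonal correlations of magnitude 1 (degenerate but possible
#' with duplicated regressors) are clamped to +/-(1 - 1e-7) with a warning.
#'
#' @param r symmetric correlation matrix.
#' @return Z-matrix of the same dimension, zero diagonal.
#' @export
fisherZ <- function(r) {
  r <- as.matrix(r)
  off <- upper.tri(r) | lower.tri(r)
  v <- r[off]
  if (any(abs(v) >= 1)) {
    warning(sum(abs(v) >= 1) / 2, " off-diagonal correlation(s) at |r| = 1 ",
            "clamped to 1 - 1e-7 before the z-transform")
    v <- pmin(pmax(v, -(1 - 1e-7)), 1 - 1e-7)
    r[off] <- v
  }
  z <- r
  z[off] <- atanh(r[off])
  diag(z) <- 0
  z
}

# Upper-triangle pairs ordered by decreasing edge weight, ties broken by
# ascending (i, j); shared by binarization and the fast metric-curve path.
.edgeRanking <- function(z, absolute = FALSE) {
  N <- nrow(z)
  ut <- upper.tri(z)
  idx <- which(ut, arr.ind = TRUE)
  w <- z[ut]
  if (absolute) w <- abs(w)
  o <- order(-w, idx[, 1L], idx[, 2L])
  list(pairs = idx[o, , drop = FALSE], nPairs = length(w))
}

.edgeCountAt <- function(sparsity, nRegions) {
  # round() is round-half-even, the documented rounding rule
  as.integer(round(sparsity * nRegions * (nRegions - 1) / 2))
}

#' Binarize a Z-matrix at a target sparsity
#'
#' Retains the `k = round(s * N(N-1)/2)` strongest edges (signed z by
#' default: the strongest positive correlations; set `absolute = TRUE` to
#' rank on `|z|`). Ties at the cutoff are broken deterministically by
#' ascending region-index pair.
#'
#' @param z symmetric Z (or correlation) matrix, zero/ignored diagonal.
#' @param sparsity target edge density in (0, 1).
#' @param absolute rank edges on absolute value instead of signed value.
#' @return symmetric 0/1 adjacency matrix with zero diagonal and exactly
#'   `k` undirected edges.
#' @export
binarizeAtSparsity <- function(z, sparsity, absolute = FALSE) {
  z <- as.matrix(z)
  N <- nrow(z)
  if (N != ncol(z)) stop("z must be square")
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must lie in (0, 1)")
  k <- .edgeCountAt(sparsity, N)
  M <- N * (N - 1) / 2
  if (k == 0L)
    stop("sparsity ", sparsity, " yields zero edges for N = ", N)
  if (k >= M) {
    warning("sparsity ", sparsity, " saturates the graph (complete network)")
    k <- as.integer(M)
  }
  er <- .edgeRanking(z, absolute)
  keep <- er$pairs[seq_len(k), , drop = FALSE]
  A <- matrix(0, N, N, dimnames = dimnames(z))
  A[keep] <- 1
  A + t(A)
}

.checkAdjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) || any(adj != t(adj)) ||
      any(diag(adj) != 0) || !all(adj %in% c(0, 1)))
    stop("adjacency must be a symmetric 0/1 matrix with zero diagonal")
  adj
}

.asGraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Small-world verification of a binary network
#'
#' Computes the clustering ratio gamma = C/C_rand, path-length ratio
#' lambda = L/L_rand and sigma = gamma/lambda against degree-preserving
#' randomized references (edge-swap rewiring with `10 |E|` swap attempts
#' each), on the largest connected component. `sigma > 1` flags a
#' small-world topology.
#'
#' @param adj binary adjacency matrix.
#' @param nRandom number of rewired reference networks.
#' @param seed RNG seed (results are reproducible for fixed inputs).
#' @return list with `gamma`, `lambda`, `sigma`, the raw `C`, `L`,
#'   `Crand`, `Lrand`, the component size used, `nRandom` and `seed`.
#' @export
smallWorldness <- function(adj, nRandom = 100L, seed = 1L) {
  adj <- .checkAdjacency(adj)
  g <- .asGraph(adj)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 3L)
    stop("largest connected component has fewer than 3 nodes")
  if (length(keep) < igraph::vcount(g))
    message("small-world metrics computed on the largest component (",
            length(keep), "/", igraph::vcount(g), " nodes)")
  gc <- igraph::induced_subgraph(g, keep)
  localC <- function(gr) {
    tr <- igraph::transitivity(gr, type = "local", isolates = "zero")
    mean(tr)
  }
  C <- localC(gc)
  L <- igraph::mean_distance(gc, directed = FALSE)
  nswap <- max(1L, 10L * igraph::ecount(gc))
  Crand <- Lrand <- numeric(nRandom)
  set.seed(seed)
  for (b in seq_len(nRandom)) {
    gr <- igraph::rewire(gc, igraph::keeping_degseq(niter = nswap))
    Crand[b] <- localC(gr)
    Lrand[b] <- igraph::mean_distance(gr, directed = FALSE)
  }
  gamma <- C / mean(Crand)
  lambda <- L / mean(Lrand)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       C = C, L = L, Crand = mean(Crand), Lrand = mean(Lrand),
       componentSize = length(keep), nRandom = nRandom, seed = seed)
}
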