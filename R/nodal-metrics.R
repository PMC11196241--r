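# Nodal graph metrics (degree, efficiency, betweenness) per threshold and
# their integration over the sparsity sweep. Metrics are computed on the full
# node set (isolated nodes keep a value), so vectors always have length N.

#' Degree centrality
#'
#' Number of edges incident to each node.
#'
#' @param adj binary adjacency matrix.
#' @return integer-valued length-N vector; `sum` equals twice the edge count.
#' @export
degreeCentrality <- function(adj) {
  adj <- .checkAdjacency(adj)
  rowSums(adj)
}

#' Nodal efficiency
#'
#' `Ne_i = mean_{j != i} 1 / d(i, j)` with unweighted shortest-path
#' distances; unreachable pairs contribute 0, so an isolated node has
#' efficiency 0.
#'
#' @param adj binary adjacency matrix.
#' @return length-N vector in `[0, 1]`.
#' @export
nodalEfficiency <- function(adj) {
  adj <- .checkAdjacency(adj)
  N <- nrow(adj)
  if (N < 2L) return(rep(0, N))
  d <- igraph::distances(.asGraph(adj), algorithm = "unweighted")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (N - 1)
}

#' Betweenness centrality
#'
#' Unnormalized undirected betweenness (Brandes accumulation):
#' `BC_i = sum_{s < t, s,t != i} sigma_st(i) / sigma_st`, where `sigma_st`
#' counts shortest s-t paths.
#'
#' @param adj binary adjacency matrix.
#' @return nonnegative length-N vector.
#' @export
betweennessCentrality <- function(adj) {
  adj <- .checkAdjacency(adj)
  as.numeric(igraph::betweenness(.asGraph(adj), directed = FALSE,
                                 weights = NA, normalized = FALSE))
}

#' Nodal metric curves across the sparsity sweep
#'
#' Binarizes a Z-matrix at every threshold of the sweep and evaluates the
#' requested nodal metrics, exploiting the nestedness of the edge sets
#' (degree curves are accumulated incrementally without constructing
#' graphs).
#'
#' @param z symmetric Z-matrix.
#' @param sparsities thresholds, default [sparsityThresholds()].
#' @param metrics subset of `c("DC", "Ne", "BC")`.
#' @param absolute rank edges on `|z|` (see [binarizeAtSparsity()]).
#' @return named list of N x length(sparsities) matrices, one per metric,
#'   with attribute `"thresholds"`.
#' @export
nodalMetricCurves <- function(z, sparsities = sparsityThresholds(),
                              metrics = c("DC", "Ne", "BC"),
                              absolute = FALSE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  z <- as.matrix(z)
  N <- nrow(z)
  K <- length(sparsities)
  if (K < 1L) stop("empty sparsity sweep")
  ks <- vapply(sparsities, .edgeCountAt, integer(1), nRegions = N)
  if (any(ks == 0L))
    stop("sweep contains thresholds with zero edges for N = ", N)
  M <- N * (N - 1) / 2
  ks <- pmin(ks, as.integer(M))
  er <- .edgeRanking(z, absolute)
  out <- lapply(metrics, function(m) matrix(0, N, K))
  names(out) <- metrics
  needGraph <- any(c("Ne", "BC") %in% metrics)
  for (k in seq_len(K)) {
    pairs <- er$pairs[seq_len(ks[k]), , drop = FALSE]
    if ("DC" %in% metrics)
      out$DC[, k] <- tabulate(c(pairs), nbins = N)
    if (needGraph) {
      g <- igraph::make_graph(t(pairs), n = N, directed = FALSE)
      if ("Ne" %in% metrics) {
        d <- igraph::distances(g, algorithm = "unweighted")
        inv <- 1 / d
        inv[!is.finite(inv)] <- 0
        diag(inv) <- 0
        out$Ne[, k] <- rowSums(inv) / (N - 1)
      }
      if ("BC" %in% metrics)
        out$BC[, k] <- igraph::betweenness(g, directed = FALSE, weights = NA,
                                           normalized = FALSE)
    }
  }
  for (m in metrics) attr(out[[m]], "thresholds") <- sparsities
  attr(out, "thresholds") <- sparsities
  out
}

#' Integrate a metric curve over the sweep (AUC)
#'
#' Trapezoidal (default) or left-rectangle integration of node-by-threshold
#' curves over a uniformly spaced sparsity sweep, yielding one
#' threshold-independent scalar per node.
#'
#' @param values N x K matrix (or length-K vector) of metric values.
#' @param thresholds the K sweep densities (uniform spacing required); taken
#'   from the `"thresholds"` attribute when absent.
#' @param rule `"trapezoid"` or `"rectangle"`.
#' @return length-N vector of AUCs.
#' @export
aucOverSweep <- function(values, thresholds = attr(values, "thresholds"),
                         rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  K <- ncol(values)
  if (is.null(thresholds) || length(thresholds) != K)
    stop("thresholds must match the number of curve columns")
  if (K < 2L)
    stop("AUC needs at least two thresholds")
  steps <- diff(thresholds)
  if (max(steps) - min(steps) > 1e-8 * mean(steps))
    stop("thresholds must be uniformly spaced")
  h <- mean(steps)
  if (rule == "trapezoid")
    h * (rowSums(values) - (values[, 1L] + values[, K]) / 2)
  else
    h * rowSums(values[, -K, drop = FALSE])
}

#' Per-subject nodal AUC table
#'
#' Full single-subject chain: Pearson FC, Fisher z, sparsity sweep, nodal
#' metric curves, AUC integration.
#'
#' @param ts timepoints-by-regions matrix.
#' @param sparsities sweep thresholds.
#' @param metrics metrics to compute.
#' @param absolute,rule passed to [nodalMetricCurves()] / [aucOverSweep()].
#' @return N x length(metrics) matrix of AUCs (columns named by metric).
#' @export
subjectNodalAUC <- function(ts, sparsities = sparsityThresholds(),
                            metrics = c("DC", "Ne", "BC"),
                            absolute = FALSE,
                            rule = c("trapezoid", "rectangle")) {
  z <- fisherZ(pearsonFC(ts))
  curves <- nodalMetricCurves(z, sparsities, metrics, absolute)
  out <- vapply(metrics, function(m)
    aucOverSweep(curves[[m]], sparsities, rule), numeric(nrow(z)))
  colnames(out) <- metrics
  rownames(out) <- colnames(ts)
  out
}
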