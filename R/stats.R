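# Statistical primitives used by the group analysis: Mann-Whitney U with the
# z (normal) approximation, Student/Welch t, 2x2 chi-square, BH-FDR,
# Spearman and partial Spearman correlation.

#' Mann-Whitney U test (normal approximation)
#'
#' Rank-sum test with mid-ranks for ties. `U` is the count of (x, y) pairs
#' with x above y (ties count 1/2); the reported `z` uses the tie-corrected
#' variance and a 0.5 continuity correction, so the sign encodes direction:
#' x stochastically below y gives negative z.
#'
#' @param x,y numeric samples (each nonempty).
#' @return list with `U`, `z`, `p` (two-sided normal approximation) and the
#'   sample sizes.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))$U  # complete separation: 0
#' @export
mannWhitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie <- table(r)
  tieTerm <- sum(tie^3 - tie)
  sig2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
  if (sig2 <= 0) {
    # every observation tied across both samples
    return(list(U = U, z = 0, p = 1, n1 = n1, n2 = n2))
  }
  sigma <- sqrt(sig2)
  cc <- 0.5 * sign(U - mu)
  z <- (U - mu - cc) / sigma
  if (U == mu) z <- 0
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = U, z = z, p = p, n1 = n1, n2 = n2)
}

#' Two-sample t test
#'
#' Pooled-variance Student t by default; `welch = TRUE` for unequal
#' variances.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param welch use the Welch-Satterthwaite form.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
twoSampleT <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 observations")
  if (var(x) + var(y) == 0) stop("zero variance in both samples")
  ht <- t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Two-sample Student t from summary statistics
#'
#' Pooled-variance t computed from printed means, SDs and group sizes (for
#' checking published tables).
#'
#' @param m1,s1,n1,m2,s2,n2 group means, SDs and sizes.
#' @return list with `t`, `df`, `p`.
#' @export
tFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square on a 2x2 table
#'
#' Without continuity correction (df = 1), as used for the sex contingency.
#'
#' @param tab 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return list with `chi2`, `df`, `p`.
#' @examples
#' chiSquare2x2(matrix(c(22, 23, 19, 21), 2))  # sex-by-group contingency
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the contingency table")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values and the significance mask at q < alpha.
#' Benjamini-Yekutieli is available for dependence-robust correction.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha significance level on the adjusted scale.
#' @param method `"BH"` (default) or `"BY"`.
#' @return list with `q` and logical `significant` (both empty for empty
#'   input); `NA` p-values propagate.
#' @export
bhFdr <- function(p, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(list(q = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = method)
  list(q = q, significant = !is.na(q) & q < alpha)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-rank Spearman rho; p from `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 4 complete pairs.
#' @return list with `rho`, `p`, `n`.
#' @export
spearmanRho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), n - 2), n = n)
}

#' Partial Spearman correlation
#'
#' Rank-transforms x, y and every covariate, residualizes the x- and y-ranks
#' on the covariate ranks (with intercept), and correlates the residuals;
#' p-value from t on `n - 2 - k` degrees of freedom for k covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector or matrix of adjustment variables.
#' @return list with `rho`, `p`, `n`, `nCovariates`.
#' @export
partialSpearman <- function(x, y, covariates) {
  covariates <- as.matrix(covariates)
  ok <- complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(covariates)
  if (n <= k + 2L) stop("need n > #covariates + 2")
  rx <- rank(x); ry <- rank(y)
  rc <- apply(covariates, 2, rank)
  constant <- apply(rc, 2, sd) == 0
  if (any(constant)) {
    # a constant covariate adjusts nothing; drop it rather than fail
    rc <- rc[, !constant, drop = FALSE]
    k <- ncol(rc)
  }
  X <- cbind(1, rc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    nm <- colnames(covariates)
    if (is.null(nm)) nm <- paste0("V", seq_len(k))
    stop("collinear covariates (after rank transform): ",
         paste(nm, collapse = ", "))
  }
  ex <- qr.resid(qrX, rx)
  ey <- qr.resid(qrX, ry)
  # a variable fully absorbed by the covariates has no partial association
  tol <- 1e-10 * n
  if (sd(ex) < tol || sd(ey) < tol)
    return(list(rho = 0, p = 1, n = n, nCovariates = k))
  rho <- cor(ex, ey)
  df <- n - 2 - k
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n, nCovariates = k))
  tt <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), df), n = n, nCovariates = k)
}
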