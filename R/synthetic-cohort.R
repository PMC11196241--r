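# Generative model: modular Gaussian covariance with a graded connectivity
# factor, CBF linearly coupled to standardized hubness, truncated phenotype
# distributions. Everything is deterministic given (config, seed).

.moduleAssignment <- function(nRegions, nModules) {
  ceiling(seq_len(nRegions) * nModules / nRegions)
}

# Correlation/covariance matrix for one group. Kept outside buildCovariance()
# so class validity can call it on a partially checked object.
.covarianceMatrix <- function(cfg, group) {
  N <- cfg@nRegions
  mod <- .moduleAssignment(N, cfg@nModules)
  S <- matrix(cfg@betweenModuleCorr, N, N)
  same <- outer(mod, mod, "==")
  S[same] <- cfg@withinModuleCorr
  if (length(cfg@hubRegions)) {
    g <- cfg@baseLoading +
      cfg@loadingGradient * (seq_len(N) - 1) / max(1L, N - 1L)
    g[cfg@hubRegions] <- cfg@hubLoading
    S <- S + outer(g, g)
  }
  diag(S) <- 1
  if (group == "patient" && length(cfg@disconnectionRegions) &&
      cfg@disconnectionAttenuation != 1) {
    d <- cfg@disconnectionRegions
    incident <- matrix(FALSE, N, N)
    incident[d, ] <- TRUE
    incident[, d] <- TRUE
    diag(incident) <- FALSE
    S[incident] <- S[incident] * cfg@disconnectionAttenuation
  }
  off <- S[upper.tri(S)]
  if (any(abs(off) >= 1))
    stop("correlation parameters exceed 1 in magnitude: reduce ",
         "withinModuleCorr/betweenModuleCorr or hubLoading/baseLoading")
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("configured covariance for group '", group,
         "' is not positive definite; adjust withinModuleCorr, ",
         "betweenModuleCorr, hubLoading/baseLoading/loadingGradient or ",
         "disconnectionAttenuation")
  S
}

#' Region-by-region covariance of a synthetic group
#'
#' Builds the (correlation-scaled) covariance used to draw ROI time series:
#' a block-modular base (`withinModuleCorr` inside contiguous modules,
#' `betweenModuleCorr` across), plus, when hub regions are configured, a
#' rank-one shared-connectivity term `g g'` with graded loadings so hub rows
#' carry more off-diagonal mass than non-hubs. For the patient group, entries
#' incident to `disconnectionRegions` are multiplied by
#' `disconnectionAttenuation`.
#'
#' @param config a [CohortConfig-class].
#' @param group `"control"` or `"patient"`.
#' @return symmetric positive-definite `nRegions` x `nRegions` matrix with
#'   unit diagonal.
#' @examples
#' cfg <- cohortConfig(nRegions = 20, nTimepoints = 50,
#'                     hubRegions = integer(0),
#'                     hyperperfusionRegions = 1L,
#'                     disconnectionRegions = 2L, seed = 1)
#' S <- buildCovariance(cfg, "control")
#' @export
buildCovariance <- function(config, group = c("control", "patient")) {
  group <- match.arg(group)
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  .covarianceMatrix(config, group)
}

# Inverse-CDF truncated normal: one uniform draw per value, so generation
# stays deterministic under a fixed seed (no rejection loops).
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

# Hubness = total off-diagonal connectivity of a region, standardized.
.standardizedHubness <- function(S) {
  h <- rowSums(S) - diag(S)
  as.numeric(scale(h))
}

.drawSeries <- function(nT, R, ar1) {
  N <- ncol(R)
  E <- matrix(rnorm(nT * N), nT, N)
  if (ar1 != 0) {
    E <- apply(E, 2, function(e) stats::filter(e, ar1, method = "recursive"))
    E <- E * sqrt(1 - ar1^2)  # restore unit marginal variance
  }
  E %*% R
}

#' Generate a synthetic cohort
#'
#' Draws, per subject, a zero-mean Gaussian ROI time series with the group
#' covariance from [buildCovariance()], a regional CBF vector
#' `baseline + slope_group * hubness + noise` (patients additionally get
#' `cbfOffset` in the hyperperfusion regions; negative draws are resampled so
#' CBF stays strictly positive), and a phenotype record with truncated-normal
#' MoCA (patients < 26, controls in \[26, 30\]), patient hemoglobin and
#' hematocrit, age, sex and education. Identical `(config, seed)` give a
#' bit-identical cohort.
#'
#' @param config a [CohortConfig-class].
#' @return an [NvcCohort-class]; `truthInfo()` records the injected effects.
#' @examples
#' coh <- generateCohort(cohortConfig(nPatients = 4, nControls = 4,
#'                                    nRegions = 12, nTimepoints = 40,
#'                                    seed = 3))
#' table(groupLabels(coh))
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  if (config@nTimepoints <= config@nRegions)
    warning("nTimepoints <= nRegions: correlation matrices will be ",
            "rank-deficient; consider a longer series")
  set.seed(config@seed)
  N <- config@nRegions
  Sg <- list(control = .covarianceMatrix(config, "control"),
             patient = .covarianceMatrix(config, "patient"))
  Rg <- lapply(Sg, chol)
  # CBF follows the architectural (control) hubness in both groups: the
  # patient effect on coupling is the reduced slope, not a shifted target
  hubness <- .standardizedHubness(Sg$control)
  slope <- c(control = config@couplingSlopeControl,
             patient = config@couplingSlopePatient)

  nTot <- config@nPatients + config@nControls
  groups <- rep(c("patient", "control"),
                c(config@nPatients, config@nControls))
  ids <- c(sprintf("P%03d", seq_len(config@nPatients)),
           sprintf("C%03d", seq_len(config@nControls)))

  ts <- vector("list", nTot)
  names(ts) <- ids
  cbf <- matrix(NA_real_, N, nTot, dimnames = list(NULL, ids))
  moca <- hb <- hct <- age <- edu <- numeric(nTot)
  sex <- character(nTot)

  mp <- config@mocaParams
  cp <- config@clinicalParams
  dp <- config@demoParams

  for (i in seq_len(nTot)) {
    grp <- groups[i]
    ts[[i]] <- .drawSeries(config@nTimepoints, Rg[[grp]], config@ar1)
    mu <- config@cbfBaselineMean + slope[[grp]] * hubness
    if (grp == "patient" && length(config@hyperperfusionRegions))
      mu[config@hyperperfusionRegions] <-
        mu[config@hyperperfusionRegions] + config@cbfOffset
    v <- mu + rnorm(N, 0, config@cbfNoiseSd)
    while (any(bad <- v <= 0))  # resample, not clip: no point mass at zero
      v[bad] <- mu[bad] + rnorm(sum(bad), 0, config@cbfNoiseSd)
    cbf[, i] <- v
    if (grp == "patient") {
      m <- mp$patient
      moca[i] <- .rtruncnorm(1, m[["mean"]], m[["sd"]], lower = 0, upper = 26)
      hb[i] <- rnorm(1, cp$hemoglobin[["mean"]], cp$hemoglobin[["sd"]])
      hct[i] <- rnorm(1, cp$hematocrit[["mean"]], cp$hematocrit[["sd"]])
      age[i] <- round(.rtruncnorm(1, dp$agePatient[["mean"]],
                                  dp$agePatient[["sd"]], 30, 65))
      sex[i] <- if (runif(1) < dp$maleProbPatient) "M" else "F"
      edu[i] <- round(.rtruncnorm(1, dp$educationPatient[["mean"]],
                                  dp$educationPatient[["sd"]], 0, 22))
    } else {
      m <- mp$control
      moca[i] <- .rtruncnorm(1, m[["mean"]], m[["sd"]], lower = 26, upper = 30)
      hb[i] <- NA_real_
      hct[i] <- NA_real_
      age[i] <- round(.rtruncnorm(1, dp$ageControl[["mean"]],
                                  dp$ageControl[["sd"]], 30, 65))
      sex[i] <- if (runif(1) < dp$maleProbControl) "M" else "F"
      edu[i] <- round(.rtruncnorm(1, dp$educationControl[["mean"]],
                                  dp$educationControl[["sd"]], 0, 22))
    }
  }

  labels <- if (N == 90L) aalLabels()$label else sprintf("R%02d", seq_len(N))
  for (i in seq_len(nTot)) colnames(ts[[i]]) <- labels
  rownames(cbf) <- labels

  pheno <- S4Vectors::DataFrame(
    subject_id = ids, group = groups, moca = moca,
    hemoglobin = hb, hematocrit = hct,
    age = age, sex = sex, education = edu, row.names = ids)

  truth <- list(
    couplingSlope = slope,
    hubRegions = config@hubRegions,
    hyperperfusionRegions = config@hyperperfusionRegions,
    disconnectionRegions = config@disconnectionRegions,
    hubness = hubness)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cbf = cbf),
    rowData = S4Vectors::DataFrame(index = seq_len(N), label = labels),
    colData = pheno,
    metadata = list(timeSeries = ts, config = config, truth = truth))
  new("NvcCohort", se)
}

#' Write a cohort to disk
#'
#' Serializes one time-series TSV per subject (`ts_<id>.tsv`, T rows x N
#' labelled columns), a cohort CBF table (`cbf.csv`, subjects x regions) and
#' a phenotype table (`phenotype.csv`). Floating-point values are written
#' with 17 significant digits so a write/read round trip is exact.
#'
#' @param cohort an [NvcCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "NvcCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- colnames(cohort)
  paths <- character(0)
  for (id in ids) {
    p <- file.path(dir, paste0("ts_", id, ".tsv"))
    .writeTable(as.data.frame(roiSeries(cohort, id)), p, sep = "\t")
    paths <- c(paths, p)
  }
  cbf <- t(cbfMatrix(cohort))
  cbfDf <- data.frame(subject_id = ids, cbf, check.names = FALSE)
  pCbf <- file.path(dir, "cbf.csv")
  .writeTable(cbfDf, pCbf, sep = ",")
  pPh <- file.path(dir, "phenotype.csv")
  .writeTable(phenotype(cohort), pPh, sep = ",")
  invisible(c(paths, pCbf, pPh))
}
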