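#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Configuration of a synthetic NVC cohort
#'
#' An S4 parameter object describing the generative model for a synthetic
#' cohort of hemodialysis patients and healthy controls: modular Gaussian
#' ROI time series with designated hub regions, regional CBF coupled to
#' network hubness, and the clinical/phenotype distributions of the study
#' population. Construct with [cohortConfig()]; all downstream randomness is
#' fully determined by the `seed` slot.
#'
#' @slot nPatients,nControls number of subjects per group.
#' @slot nRegions number of atlas regions (network nodes).
#' @slot nTimepoints BOLD series length per subject.
#' @slot nModules number of contiguous covariance modules.
#' @slot withinModuleCorr,betweenModuleCorr baseline correlations inside and
#'   across modules, each in `[0, 1)`.
#' @slot hubRegions indices of regions with elevated connectivity.
#' @slot hubLoading,baseLoading,loadingGradient parameters of the shared
#'   connectivity factor: every region gets loading
#'   `baseLoading + loadingGradient * (i-1)/(N-1)`, hub regions get
#'   `hubLoading`; the rank-one term `g g'` (diagonal reset to 1) is added to
#'   the modular base, keeping the matrix positive definite while giving each
#'   region a distinct "hubness". Set `hubRegions = integer(0)` for a purely
#'   modular covariance.
#' @slot couplingSlopeControl,couplingSlopePatient CBF increase
#'   (mL/100 g/min) per standard deviation of regional hubness.
#' @slot hyperperfusionRegions,cbfOffset regions whose patient CBF is shifted
#'   upward by `cbfOffset` mL/100 g/min.
#' @slot disconnectionRegions,disconnectionAttenuation regions whose incident
#'   covariance entries are multiplied by the attenuation factor in patients.
#' @slot cbfBaselineMean,cbfNoiseSd regional CBF baseline and noise
#'   (mL/100 g/min).
#' @slot mocaParams,clinicalParams,demoParams lists of group means/SDs for
#'   MoCA, hemoglobin/hematocrit, and age/sex/education.
#' @slot ar1 lag-1 autocorrelation of the time series (0 = i.i.d. timepoints,
#'   the default).
#' @slot seed integer RNG seed.
#' @seealso [cohortConfig()], [generateCohort()], [buildCovariance()]
#' @exportClass CohortConfig
setClass("CohortConfig",
  slots = c(
    nPatients = "integer",
    nControls = "integer",
    nRegions = "integer",
    nTimepoints = "integer",
    nModules = "integer",
    withinModuleCorr = "numeric",
    betweenModuleCorr = "numeric",
    hubRegions = "integer",
    hubLoading = "numeric",
    baseLoading = "numeric",
    loadingGradient = "numeric",
    couplingSlopeControl = "numeric",
    couplingSlopePatient = "numeric",
    hyperperfusionRegions = "integer",
    cbfOffset = "numeric",
    disconnectionRegions = "integer",
    disconnectionAttenuation = "numeric",
    cbfBaselineMean = "numeric",
    cbfNoiseSd = "numeric",
    mocaParams = "list",
    clinicalParams = "list",
    demoParams = "list",
    ar1 = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  scalarPos <- function(x, name, minOne = TRUE) {
    if (length(x) != 1L || is.na(x) || (minOne && x < 1L))
      msg <<- c(msg, sprintf("'%s' must be a single value >= 1", name))
  }
  scalarPos(object@nPatients, "nPatients")
  scalarPos(object@nControls, "nControls")
  scalarPos(object@nRegions, "nRegions")
  scalarPos(object@nTimepoints, "nTimepoints")
  scalarPos(object@nModules, "nModules")
  if (length(object@nTimepoints) == 1L && !is.na(object@nTimepoints) &&
      object@nTimepoints < 2L)
    msg <- c(msg, "nTimepoints must be >= 2")
  for (nm in c("withinModuleCorr", "betweenModuleCorr")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v >= 1)
      msg <- c(msg, sprintf("'%s' must lie in [0, 1)", nm))
  }
  N <- object@nRegions
  for (nm in c("hubRegions", "hyperperfusionRegions", "disconnectionRegions")) {
    v <- slot(object, nm)
    if (length(v) && (any(v < 1) || any(v > N) || anyDuplicated(v)))
      msg <- c(msg, sprintf(
        "'%s' must be distinct region indices in 1..%d", nm, N))
  }
  if (object@disconnectionAttenuation < 0 || object@disconnectionAttenuation > 1)
    msg <- c(msg, "disconnectionAttenuation must lie in [0, 1]")
  if (object@cbfNoiseSd < 0 || object@cbfBaselineMean <= 0)
    msg <- c(msg, "cbfBaselineMean must be > 0 and cbfNoiseSd >= 0")
  if (abs(object@ar1) >= 1)
    msg <- c(msg, "ar1 must lie in (-1, 1)")
  if (length(msg)) return(msg)
  # positive definiteness of both group covariances, checked at build time
  for (grp in c("control", "patient")) {
    chk <- tryCatch({
      .covarianceMatrix(object, grp)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(chk)) return(chk)
  }
  TRUE
})

#' Synthetic NVC cohort container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with rows = atlas
#' regions and columns = subjects. The `"cbf"` assay holds regional CBF
#' (mL/100 g/min), `colData` the phenotype table (group, MoCA, hemoglobin,
#' hematocrit, age, sex, education), and `metadata()` carries the per-subject
#' ROI time-series matrices (`timeSeries`), the generating [CohortConfig]
#' (`config`), and the injected ground truth (`truth`).
#'
#' Use the accessors [cbfMatrix()], [roiSeries()], [phenotype()],
#' [groupLabels()] and [truthInfo()] rather than reaching into slots.
#'
#' @seealso [generateCohort()]
#' @exportClass NvcCohort
setClass("NvcCohort", contains = "SummarizedExperiment")

setValidity("NvcCohort", function(object) {
  md <- S4Vectors::metadata(object)
  if (!"cbf" %in% SummarizedExperiment::assayNames(object))
    return("assay 'cbf' is required")
  ts <- md$timeSeries
  if (is.null(ts) || length(ts) != ncol(object))
    return("metadata()$timeSeries must hold one matrix per subject")
  N <- nrow(object)
  ok <- vapply(ts, function(m) is.matrix(m) && ncol(m) == N, logical(1))
  if (!all(ok))
    return("every time-series matrix must have one column per region")
  cbf <- SummarizedExperiment::assay(object, "cbf")
  if (any(!is.finite(cbf)) || any(cbf <= 0))
    return("CBF values must be finite and strictly positive")
  TRUE
})
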