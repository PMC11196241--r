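#' @include AllClasses.R
NULL

#' Accessors for NvcCohort objects
#'
#' `cbfMatrix()` returns the regions-by-subjects CBF assay; `roiSeries()` one
#' subject's timepoints-by-regions BOLD matrix (or the full list);
#' `phenotype()` the phenotype table as a data.frame; `groupLabels()` the
#' patient/control factor; `truthInfo()` the injected ground-truth record of
#' a synthetic cohort.
#'
#' @param x an [NvcCohort-class] object.
#' @param subject subject identifier or index; if missing, the full list of
#'   time-series matrices is returned.
#' @return See the individual descriptions above.
#' @examples
#' cfg <- cohortConfig(nPatients = 3, nControls = 3, nRegions = 10,
#'                     nTimepoints = 40, seed = 1)
#' coh <- generateCohort(cfg)
#' dim(cbfMatrix(coh))
#' head(phenotype(coh))
#' @name cohort-accessors
#' @aliases cbfMatrix roiSeries phenotype groupLabels truthInfo
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("cbfMatrix", function(x) standardGeneric("cbfMatrix"))

#' @rdname cohort-accessors
#' @export
setGeneric("roiSeries", function(x, subject) standardGeneric("roiSeries"))

#' @rdname cohort-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname cohort-accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname cohort-accessors
#' @export
setGeneric("truthInfo", function(x) standardGeneric("truthInfo"))

#' @rdname cohort-accessors
setMethod("cbfMatrix", "NvcCohort", function(x)
  SummarizedExperiment::assay(x, "cbf"))

#' @rdname cohort-accessors
setMethod("roiSeries", "NvcCohort", function(x, subject) {
  ts <- S4Vectors::metadata(x)$timeSeries
  if (missing(subject)) return(ts)
  ts[[subject]]
})

#' @rdname cohort-accessors
setMethod("phenotype", "NvcCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname cohort-accessors
setMethod("groupLabels", "NvcCohort", function(x)
  factor(SummarizedExperiment::colData(x)$group,
         levels = c("patient", "control")))

#' @rdname cohort-accessors
setMethod("truthInfo", "NvcCohort", function(x)
  S4Vectors::metadata(x)$truth)

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig\n")
  cat(sprintf("  subjects : %d patients / %d controls\n",
              object@nPatients, object@nControls))
  cat(sprintf("  series   : %d timepoints x %d regions (%d modules, ar1 = %g)\n",
              object@nTimepoints, object@nRegions, object@nModules, object@ar1))
  cat(sprintf("  coupling : slope %g (control) / %g (patient) mL/100g/min per SD\n",
              object@couplingSlopeControl, object@couplingSlopePatient))
  cat(sprintf("  effects  : %d hub, %d hyperperfusion (+%g), %d disconnection (x%g)\n",
              length(object@hubRegions), length(object@hyperperfusionRegions),
              object@cbfOffset, length(object@disconnectionRegions),
              object@disconnectionAttenuation))
  cat(sprintf("  seed     : %d\n", object@seed))
  invisible(object)
})

setMethod("show", "NvcCohort", function(object) {
  grp <- table(SummarizedExperiment::colData(object)$group)
  cat(sprintf("NvcCohort: %d regions x %d subjects (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%d %s", grp, names(grp)), collapse = ", ")))
  ts <- S4Vectors::metadata(object)$timeSeries
  if (length(ts))
    cat(sprintf("  time series: %d timepoints per subject\n", nrow(ts[[1]])))
  callNextMethod()
})
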