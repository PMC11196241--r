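#' Default region sets for injected effects
#'
#' Returns the three region sets the generator perturbs: connectivity hubs,
#' patient hyperperfusion regions, and patient disconnection regions. For the
#' 90-region AAL parcellation the sets follow the anatomy the study
#' implicates (default-mode/limbic hubs; hyperperfusion in the median
#' cingulate, parahippocampal, lingual and superior parietal gyri;
#' disconnection in the middle frontal gyri, Heschl's gyrus, the temporal
#' pole and the right parahippocampal gyrus, with PHG.R carrying both
#' effects). The disconnection set deliberately avoids the hub regions:
#' hub CBF shifts with the reduced patient coupling slope, and stacking the
#' two effects on the same regions would leave no clean NODE_only ground
#' truth to recover. For other region
#' counts the sets are placed deterministically in the first, second and last
#' thirds of the index range, with one region shared between the
#' hyperperfusion and disconnection sets so every driving category is
#' represented.
#'
#' @param nRegions number of regions.
#' @return list with integer vectors `hubs`, `hyperperfusion`,
#'   `disconnection`.
#' @export
defaultRegionSets <- function(nRegions) {
  nRegions <- as.integer(nRegions)
  if (nRegions == 90L) {
    return(list(
      hubs = c(23L, 24L, 35L, 36L, 37L, 38L, 65L, 66L, 67L, 68L),
      hyperperfusion = c(33L, 34L, 40L, 47L, 48L, 59L, 60L),
      disconnection = c(7L, 8L, 40L, 79L, 83L)
    ))
  }
  if (nRegions < 9L)
    stop("defaultRegionSets() needs nRegions >= 9; supply region sets directly")
  k <- max(2L, nRegions %/% 10L)
  third <- nRegions %/% 3L
  hubs <- unique(as.integer(round(seq(1L, third, length.out = k))))
  hyper <- unique(as.integer(round(seq(third + 1L, 2L * third, length.out = k))))
  disc <- unique(as.integer(round(seq(2L * third + 1L, nRegions - 1L,
                                      length.out = max(1L, k - 1L)))))
  # share one region between hyperperfusion and disconnection ("BOTH" truth)
  disc <- sort(unique(c(disc, hyper[length(hyper)])))
  list(hubs = hubs, hyperperfusion = hyper, disconnection = disc)
}

#' Build a synthetic cohort configuration
#'
#' Constructor for [CohortConfig-class]. Defaults reproduce the study
#' conditions: 45 patients / 40 controls, 90 AAL regions, 230 timepoints,
#' patient coupling slope at 50% of the control slope, hyperperfusion offset
#' +22 mL/100 g/min, disconnection attenuation 0.5, MoCA 22.6 +/- 3.6
#' (patients, truncated below 26) vs 28.1 +/- 2.2 (controls, truncated to
#' \[26, 30\]), hemoglobin 95.36 +/- 4.12 g/L and hematocrit 27.17 +/- 1.79%
#' for patients.
#'
#' @param nPatients,nControls group sizes.
#' @param nRegions,nTimepoints series dimensions.
#' @param nModules number of contiguous covariance modules.
#' @param withinModuleCorr,betweenModuleCorr base correlations.
#' @param hubRegions,hyperperfusionRegions,disconnectionRegions integer
#'   region sets; `NULL` selects [defaultRegionSets()].
#' @param hubLoading,baseLoading,loadingGradient shared-factor loadings (see
#'   [CohortConfig-class]).
#' @param couplingSlopeControl,couplingSlopePatient CBF per SD of hubness.
#' @param cbfOffset patient CBF shift in hyperperfusion regions.
#' @param disconnectionAttenuation multiplier on patient covariance entries
#'   incident to disconnection regions.
#' @param cbfBaselineMean,cbfNoiseSd CBF baseline and noise (mL/100 g/min).
#' @param mocaParams,clinicalParams,demoParams named lists of distribution
#'   parameters; see defaults.
#' @param ar1 optional lag-1 autocorrelation of timepoints (default 0).
#' @param seed RNG seed.
#' @return a validated [CohortConfig-class] object.
#' @examples
#' cohortConfig(nPatients = 5, nControls = 5, nRegions = 20,
#'              nTimepoints = 60, seed = 7)
#' @export
cohortConfig <- function(nPatients = 45L,
                         nControls = 40L,
                         nRegions = 90L,
                         nTimepoints = 230L,
                         nModules = 6L,
                         withinModuleCorr = 0.30,
                         betweenModuleCorr = 0.05,
                         hubRegions = NULL,
                         hubLoading = 0.55,
                         baseLoading = 0.15,
                         loadingGradient = 0.25,
                         couplingSlopeControl = 7.5,
                         couplingSlopePatient = couplingSlopeControl / 2,
                         hyperperfusionRegions = NULL,
                         cbfOffset = 22,
                         disconnectionRegions = NULL,
                         disconnectionAttenuation = 0.5,
                         cbfBaselineMean = 60,
                         cbfNoiseSd = 10,
                         mocaParams = list(
                           patient = c(mean = 22.6, sd = 3.6),
                           control = c(mean = 28.1, sd = 2.2)),
                         clinicalParams = list(
                           hemoglobin = c(mean = 95.36, sd = 4.12),
                           hematocrit = c(mean = 27.17, sd = 1.79)),
                         demoParams = list(
                           agePatient = c(mean = 49, sd = 11),
                           ageControl = c(mean = 46, sd = 10),
                           educationPatient = c(mean = 9.5, sd = 2.7),
                           educationControl = c(mean = 9.8, sd = 2.5),
                           maleProbPatient = 22 / 45,
                           maleProbControl = 19 / 40),
                         ar1 = 0,
                         seed = 1L) {
  sets <- NULL
  if (is.null(hubRegions) || is.null(hyperperfusionRegions) ||
      is.null(disconnectionRegions))
    sets <- defaultRegionSets(nRegions)
  if (is.null(hubRegions)) hubRegions <- sets$hubs
  if (is.null(hyperperfusionRegions)) hyperperfusionRegions <- sets$hyperperfusion
  if (is.null(disconnectionRegions)) disconnectionRegions <- sets$disconnection
  new("CohortConfig",
      nPatients = as.integer(nPatients),
      nControls = as.integer(nControls),
      nRegions = as.integer(nRegions),
      nTimepoints = as.integer(nTimepoints),
      nModules = as.integer(nModules),
      withinModuleCorr = withinModuleCorr,
      betweenModuleCorr = betweenModuleCorr,
      hubRegions = as.integer(hubRegions),
      hubLoading = hubLoading,
      baseLoading = baseLoading,
      loadingGradient = loadingGradient,
      couplingSlopeControl = couplingSlopeControl,
      couplingSlopePatient = couplingSlopePatient,
      hyperperfusionRegions = as.integer(hyperperfusionRegions),
      cbfOffset = cbfOffset,
      disconnectionRegions = as.integer(disconnectionRegions),
      disconnectionAttenuation = disconnectionAttenuation,
      cbfBaselineMean = cbfBaselineMean,
      cbfNoiseSd = cbfNoiseSd,
      mocaParams = mocaParams,
      clinicalParams = clinicalParams,
      demoParams = demoParams,
      ar1 = ar1,
      seed = as.integer(seed))
}

#' Null (exchangeable-groups) version of a configuration
#'
#' Sets every patient-specific effect to its control value: equal coupling
#' slopes, no hyperperfusion offset, no disconnection attenuation. Under the
#' resulting configuration the group label is exchangeable for all
#' network/CBF statistics, which is what type-I-error calibration requires.
#'
#' @param config a [CohortConfig-class].
#' @param seed optional replacement seed.
#' @return a [CohortConfig-class] with patient effects neutralized.
#' @export
nullConfig <- function(config, seed = config@seed) {
  config@couplingSlopePatient <- config@couplingSlopeControl
  config@cbfOffset <- 0
  config@disconnectionAttenuation <- 1
  config@seed <- as.integer(seed)
  validObject(config)
  config
}
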