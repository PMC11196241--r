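# NVC biomarkers: per-subject global CBF-topology Spearman coupling
# coefficients and per-region CBF/topology coupling ratios.

#' Global CBF-topology coupling coefficient
#'
#' Spearman correlation (mid-ranks) across regions between one subject's
#' regional CBF vector and a nodal-metric AUC vector. This is the
#' whole-brain NVC coefficient; higher values mean blood supply tracks
#' connectivity more tightly.
#'
#' @param cbf length-N CBF vector (mL/100 g/min).
#' @param auc length-N nodal AUC vector.
#' @return Spearman rho in `[-1, 1]`, or `NA` (with a warning) when either
#'   vector is constant.
#' @export
globalCoupling <- function(cbf, auc) {
  if (length(cbf) != length(auc))
    stop("cbf and auc must have equal length")
  if (length(cbf) < 3L)
    stop("need at least 3 regions")
  if (sd(cbf) == 0 || sd(auc) == 0) {
    warning("constant input: coupling coefficient undefined, returning NA")
    return(NA_real_)
  }
  cor(rank(cbf), rank(auc))
}

#' Regional CBF/topology coupling ratios
#'
#' `ratio[i, m] = CBF_i / AUC_{i, m}` for each region i and nodal metric m:
#' the regional NVC index, "blood supply per unit of connectivity". Regions
#' whose AUC denominator falls below `1e-9 * max(|AUC_m|)` are returned as
#' `NA` and listed in a message (no exception: downstream tests skip missing
#' regions).
#'
#' @param cbf length-N CBF vector.
#' @param auc N x M matrix of nodal AUCs (one column per metric, e.g. from
#'   [subjectNodalAUC()]).
#' @return N x M matrix of ratios.
#' @export
regionalRatios <- function(cbf, auc) {
  auc <- as.matrix(auc)
  if (length(cbf) != nrow(auc))
    stop("cbf length must match rows of auc")
  out <- matrix(NA_real_, nrow(auc), ncol(auc), dimnames = dimnames(auc))
  flagged <- integer(0)
  for (m in seq_len(ncol(auc))) {
    tol <- 1e-9 * max(abs(auc[, m]))
    small <- !is.finite(auc[, m]) | abs(auc[, m]) <= tol
    out[!small, m] <- cbf[!small] / auc[!small, m]
    flagged <- union(flagged, which(small))
  }
  if (length(flagged))
    message("coupling ratio undefined (near-zero denominator) in region(s): ",
            paste(sort(flagged), collapse = ", "))
  out
}

#' Cohort-wide coupling profiles
#'
#' Runs the per-subject chain (FC, Fisher z, sparsity sweep, nodal AUCs) for
#' every subject of a cohort and assembles the NVC biomarkers.
#'
#' @param cohort an [NvcCohort-class].
#' @param sparsities sweep thresholds.
#' @param metrics subset of `c("DC", "Ne", "BC")`.
#' @param absolute,rule network/AUC options (see [binarizeAtSparsity()],
#'   [aucOverSweep()]).
#' @return list with
#'   `coefficients`: data.frame (subject_id, group, one `rho_<metric>`
#'   column per metric);
#'   `auc`: regions x metrics x subjects array;
#'   `ratios`: regions x metrics x subjects array.
#' @examples
#' coh <- generateCohort(cohortConfig(nPatients = 3, nControls = 3,
#'                                    nRegions = 12, nTimepoints = 40,
#'                                    seed = 2))
#' prof <- couplingProfiles(coh, sparsities = sparsityThresholds(0.2, 0.4, 0.05),
#'                          metrics = "DC")
#' head(prof$coefficients)
#' @export
couplingProfiles <- function(cohort, sparsities = sparsityThresholds(),
                             metrics = c("DC", "Ne", "BC"),
                             absolute = FALSE,
                             rule = c("trapezoid", "rectangle")) {
  stopifnot(is(cohort, "NvcCohort"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  rule <- match.arg(rule)
  ids <- colnames(cohort)
  N <- nrow(cohort)
  cbf <- cbfMatrix(cohort)
  auc <- array(NA_real_, c(N, length(metrics), length(ids)),
               dimnames = list(rownames(cohort), metrics, ids))
  ratios <- auc
  rhos <- matrix(NA_real_, length(ids), length(metrics),
                 dimnames = list(ids, paste0("rho_", tolower(metrics))))
  for (i in seq_along(ids)) {
    a <- subjectNodalAUC(roiSeries(cohort, ids[i]), sparsities, metrics,
                         absolute, rule)
    auc[, , i] <- a
    ratios[, , i] <- suppressMessages(regionalRatios(cbf[, i], a))
    for (m in seq_along(metrics))
      rhos[i, m] <- globalCoupling(cbf[, i], a[, m])
  }
  coefficients <- data.frame(
    subject_id = ids,
    group = as.character(groupLabels(cohort)),
    rhos,
    row.names = NULL)
  list(coefficients = coefficients, auc = auc, ratios = ratios)
}
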