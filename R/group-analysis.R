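# Group-level statistics over regions: test routing follows the study design
# (Mann-Whitney for CBF and NVC indices, Student t for nodal parameters),
# with BH-FDR applied per index family (each index's 90 regions form one
# correction family).

#' Region-wise group comparison
#'
#' Tests every region for a patient-control difference in one index
#' (CBF, a nodal AUC, or a coupling ratio) and applies FDR correction across
#' regions within the index family. Regions with missing values in more than
#' `maxMissing` of subjects are dropped with a message; remaining missing
#' values are omitted pairwise.
#'
#' @param values subjects x regions matrix of the index.
#' @param group factor/character with levels `patient`, `control`.
#' @param indexName label stored in the output (e.g. `"CBF"`, `"DC"`,
#'   `"CBF/DC"`).
#' @param test `"mannwhitney"` (z statistic) or `"ttest"`.
#' @param alpha FDR significance level.
#' @param fdrMethod `"BH"` or `"BY"`.
#' @param maxMissing maximal tolerated fraction of missing subjects per
#'   region.
#' @return data.frame with columns `region`, `index`, `statistic`, `p`, `q`,
#'   `direction` (`patients_higher`/`patients_lower`), `significant`
#'   (q < alpha). Dropped regions appear with `NA` statistics.
#' @export
regionComparisons <- function(values, group, indexName,
                              test = c("mannwhitney", "ttest"),
                              alpha = 0.05, fdrMethod = c("BH", "BY"),
                              maxMissing = 0.2) {
  test <- match.arg(test)
  fdrMethod <- match.arg(fdrMethod)
  values <- as.matrix(values)
  group <- as.character(group)
  if (length(group) != nrow(values))
    stop("group length must match rows of values")
  if (!all(group %in% c("patient", "control")))
    stop("group labels must be 'patient' or 'control'")
  pat <- group == "patient"
  N <- ncol(values)
  regions <- colnames(values)
  if (is.null(regions)) regions <- as.character(seq_len(N))
  stat <- p <- rep(NA_real_, N)
  dir <- rep(NA_character_, N)
  missFrac <- colMeans(is.na(values))
  drop <- missFrac > maxMissing
  if (any(drop))
    message("excluding ", sum(drop), " region(s) missing in > ",
            round(100 * maxMissing), "% of subjects: ",
            paste(regions[drop], collapse = ", "))
  for (j in which(!drop)) {
    xp <- values[pat, j]; xc <- values[!pat, j]
    xp <- xp[!is.na(xp)]; xc <- xc[!is.na(xc)]
    if (test == "mannwhitney") {
      mw <- mannWhitney(xp, xc)
      stat[j] <- mw$z; p[j] <- mw$p
      dir[j] <- if (median(xp) >= median(xc)) "patients_higher" else
        "patients_lower"
    } else {
      tt <- twoSampleT(xp, xc)
      stat[j] <- tt$t; p[j] <- tt$p
      dir[j] <- if (mean(xp) >= mean(xc)) "patients_higher" else
        "patients_lower"
    }
  }
  fdr <- bhFdr(p, alpha, fdrMethod)
  data.frame(region = regions, index = indexName, statistic = stat,
             p = p, q = fdr$q,
             direction = dir,
             significant = fdr$significant,
             row.names = NULL)
}

#' Group tests on the global coupling coefficients
#'
#' Mann-Whitney comparison of the per-subject CBF-topology coupling
#' coefficients between patients and controls, one test per nodal metric,
#' with group medians and quartiles.
#'
#' @param coefficients the `coefficients` data.frame from
#'   [couplingProfiles()].
#' @param alternative `"two.sided"` or `"less"` (patients below controls,
#'   the study's directional hypothesis).
#' @return data.frame with one row per metric: medians/IQR per group, `z`,
#'   `p`.
#' @export
couplingGroupTests <- function(coefficients,
                               alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  rhoCols <- grep("^rho_", names(coefficients), value = TRUE)
  pat <- coefficients$group == "patient"
  out <- lapply(rhoCols, function(cl) {
    xp <- coefficients[[cl]][pat]
    xc <- coefficients[[cl]][!pat]
    mw <- mannWhitney(xp, xc)
    p <- if (alternative == "less") pnorm(mw$z) else mw$p
    qp <- quantile(xp, c(0.5, 0.25, 0.75), na.rm = TRUE)
    qc <- quantile(xc, c(0.5, 0.25, 0.75), na.rm = TRUE)
    data.frame(metric = sub("^rho_", "", cl),
               median_patient = qp[1], q1_patient = qp[2], q3_patient = qp[3],
               median_control = qc[1], q1_control = qc[2], q3_control = qc[3],
               z = mw$z, p = p, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Brain-behavior correlations in patients
#'
#' Spearman correlation between each regional coupling ratio and the MoCA
#' score within the patient group, uncorrected, plus the partial Spearman
#' correlation adjusting hemoglobin and hematocrit.
#'
#' @param ratios regions x metrics x subjects array from
#'   [couplingProfiles()].
#' @param pheno phenotype data.frame (needs `group`, `moca`, `hemoglobin`,
#'   `hematocrit`; subjects in array order).
#' @return data.frame with `region`, `metric`, `rho`, `p`, `rho_adjusted`,
#'   `p_adjusted`, `covariates`.
#' @export
behaviorCorrelations <- function(ratios, pheno) {
  if (dim(ratios)[3] != nrow(pheno))
    stop("subject dimension of ratios must match phenotype rows")
  pat <- pheno$group == "patient"
  moca <- pheno$moca[pat]
  covs <- cbind(hemoglobin = pheno$hemoglobin[pat],
                hematocrit = pheno$hematocrit[pat])
  regions <- dimnames(ratios)[[1]]
  if (is.null(regions)) regions <- as.character(seq_len(dim(ratios)[1]))
  metrics <- dimnames(ratios)[[2]]
  rows <- list()
  for (m in seq_along(metrics)) {
    for (j in seq_len(dim(ratios)[1])) {
      v <- ratios[j, m, pat]
      if (sum(complete.cases(v, moca)) < 4L) next
      sp <- spearmanRho(v, moca)
      ps <- if (sum(complete.cases(v, moca, covs)) > ncol(covs) + 3L)
        partialSpearman(v, moca, covs)
      else
        list(rho = NA_real_, p = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        region = regions[j], metric = metrics[m],
        rho = sp$rho, p = sp$p,
        rho_adjusted = ps$rho, p_adjusted = ps$p,
        covariates = "hemoglobin+hematocrit", row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
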