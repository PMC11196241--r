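# End-to-end orchestration: simulate (or load) -> networks -> nodal AUCs ->
# coupling -> group statistics -> driving classification, with a manifest
# sufficient to reproduce every table.

.cohortFromTables <- function(tsList, cbf, pheno) {
  ids <- pheno$subject_id
  stopifnot(length(tsList) == length(ids), nrow(cbf) == length(ids))
  tsList <- tsList[ids]
  N <- ncol(tsList[[1]])
  labels <- colnames(tsList[[1]])
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(N))
  cbfM <- t(cbf[ids, , drop = FALSE])
  rownames(cbfM) <- labels
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cbf = cbfM),
    rowData = S4Vectors::DataFrame(index = seq_len(N), label = labels),
    colData = S4Vectors::DataFrame(pheno, row.names = ids),
    metadata = list(timeSeries = tsList, config = NULL, truth = NULL))
  new("NvcCohort", se)
}

#' Load a cohort from on-disk tables
#'
#' Reads the per-subject time-series TSVs, the cohort CBF table and the
#' phenotype table written by [writeCohort()] (or prepared externally in the
#' same layout) back into an [NvcCohort-class].
#'
#' @param dir directory containing `ts_<id>.tsv`, `cbf.csv`,
#'   `phenotype.csv`.
#' @return an [NvcCohort-class].
#' @export
readCohort <- function(dir) {
  pheno <- readPhenotype(file.path(dir, "phenotype.csv"))
  cbf <- readCbfTable(file.path(dir, "cbf.csv"))
  tsList <- lapply(pheno$subject_id, function(id)
    readTimeSeries(file.path(dir, paste0("ts_", id, ".tsv")),
                   expectedRegions = ncol(cbf)))
  names(tsList) <- pheno$subject_id
  .cohortFromTables(tsList, cbf, pheno)
}

#' Run the full NVC analysis pipeline
#'
#' Generates (or loads) a cohort, computes per-subject networks, nodal AUCs
#' and coupling profiles, runs the region-wise and coupling group statistics
#' with per-family FDR, the MoCA correlations, and the driving
#' classification, and writes all result tables plus a manifest. Reruns with
#' identical configuration and seed produce byte-identical files.
#'
#' Test routing follows the study design: Mann-Whitney for CBF and coupling
#' ratios, Student t for nodal AUCs; FDR correction is applied across
#' regions within each index family.
#'
#' @param config a [CohortConfig-class] (ignored when `inputDir` is given).
#' @param outDir output directory.
#' @param inputDir optional directory with a pre-existing cohort in
#'   [writeCohort()] layout; when supplied, no simulation is run.
#' @param sparsities sweep thresholds (validated before any computation).
#' @param metrics nodal metrics to analyze.
#' @param absolute,rule network and AUC options.
#' @param fdrMethod,alpha FDR settings.
#' @param writeSubjectTables also write the simulated cohort tables under
#'   `outDir/cohort/`.
#' @return invisibly, a list with every result table, the overlap counts,
#'   the cohort, and the written file paths.
#' @examples
#' \donttest{
#' res <- runPipeline(cohortConfig(nPatients = 5, nControls = 5,
#'                                 nRegions = 12, nTimepoints = 40,
#'                                 seed = 11),
#'                    outDir = tempfile(), metrics = "DC",
#'                    sparsities = sparsityThresholds(0.2, 0.4, 0.05))
#' res$couplingTests
#' }
#' @export
runPipeline <- function(config = cohortConfig(),
                        outDir,
                        inputDir = NULL,
                        sparsities = sparsityThresholds(),
                        metrics = c("DC", "Ne", "BC"),
                        absolute = FALSE,
                        rule = c("trapezoid", "rectangle"),
                        fdrMethod = c("BH", "BY"),
                        alpha = 0.05,
                        writeSubjectTables = FALSE) {
  rule <- match.arg(rule)
  fdrMethod <- match.arg(fdrMethod)
  metrics <- match.arg(metrics, c("DC", "Ne", "BC"), several.ok = TRUE)
  if (!is.numeric(sparsities) || length(sparsities) < 2L ||
      any(diff(sparsities) <= 0) || min(sparsities) <= 0 ||
      max(sparsities) >= 1)
    stop("invalid sparsity sweep: need >= 2 strictly increasing densities in (0, 1)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (is.null(inputDir)) generateCohort(config) else
    readCohort(inputDir)
  message("pipeline: ", ncol(cohort), " subjects (",
          sum(groupLabels(cohort) == "patient"), " patients), ",
          nrow(cohort), " regions, ", length(sparsities), " thresholds")
  if (writeSubjectTables && is.null(inputDir))
    writeCohort(cohort, file.path(outDir, "cohort"))

  prof <- couplingProfiles(cohort, sparsities, metrics, absolute, rule)
  grp <- groupLabels(cohort)
  regions <- rownames(cohort)

  # region-wise comparisons: CBF family + one family per nodal metric and
  # per ratio index
  comparisons <- list(
    regionComparisons(t(cbfMatrix(cohort)), grp, "CBF",
                      test = "mannwhitney", alpha = alpha,
                      fdrMethod = fdrMethod))
  for (m in metrics) {
    comparisons[[length(comparisons) + 1L]] <-
      regionComparisons(t(prof$auc[, m, ]), grp, m,
                        test = "ttest", alpha = alpha, fdrMethod = fdrMethod)
    comparisons[[length(comparisons) + 1L]] <-
      regionComparisons(t(prof$ratios[, m, ]), grp, paste0("CBF/", m),
                        test = "mannwhitney", alpha = alpha,
                        fdrMethod = fdrMethod)
  }
  comparisons <- do.call(rbind, comparisons)

  sigOf <- function(idx) {
    sub <- comparisons[comparisons$index %in% idx, , drop = FALSE]
    vapply(regions, function(r)
      any(sub$significant[sub$region == r], na.rm = TRUE), logical(1))
  }
  cbfSig <- sigOf("CBF")
  nodalSig <- sigOf(metrics)
  ratioSig <- sigOf(paste0("CBF/", metrics))

  driving <- classifyDriving(ratioSig, cbfSig, nodalSig, regions)
  overlap <- overlapCounts(cbfSig, nodalSig, ratioSig)
  couplingTests <- couplingGroupTests(prof$coefficients)
  behavior <- behaviorCorrelations(prof$ratios, phenotype(cohort))

  paths <- c(
    region_comparisons = file.path(outDir, "region_comparisons.tsv"),
    coupling_coefficients = file.path(outDir, "coupling_coefficients.tsv"),
    coupling_group_tests = file.path(outDir, "coupling_group_tests.tsv"),
    behavior_correlations = file.path(outDir, "behavior_correlations.tsv"),
    driving_categories = file.path(outDir, "driving_categories.tsv"),
    overlap_counts = file.path(outDir, "overlap_counts.json"),
    manifest = file.path(outDir, "manifest.json"))
  .writeTable(comparisons, paths["region_comparisons"])
  .writeTable(prof$coefficients, paths["coupling_coefficients"])
  .writeTable(couplingTests, paths["coupling_group_tests"])
  .writeTable(behavior, paths["behavior_correlations"])
  .writeTable(transform(driving, category = as.character(category)),
              paths["driving_categories"])
  jsonlite::write_json(overlap, paths["overlap_counts"], auto_unbox = TRUE)

  manifest <- list(
    package = "nvcoupler",
    version = as.character(utils::packageVersion("nvcoupler")),
    config = if (is.null(inputDir)) .configAsList(config) else NULL,
    configHash = if (is.null(inputDir)) .configHash(config) else NULL,
    inputDir = inputDir,
    sparsities = sparsities,
    metrics = metrics,
    absolute = absolute,
    aucRule = rule,
    fdrMethod = fdrMethod,
    alpha = alpha,
    nSubjects = ncol(cohort),
    nRegions = nrow(cohort))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(cohort = cohort, profiles = prof,
                 comparisons = comparisons,
                 couplingTests = couplingTests,
                 behavior = behavior,
                 driving = driving, overlap = overlap,
                 masks = list(cbf = cbfSig, nodal = nodalSig,
                              ratio = ratioSig),
                 paths = paths))
}
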