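# Tabular readers/writers and the optional NIfTI ROI-mean extraction.
# ROI-level tables (TSV/CSV) are the canonical interchange format.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' AAL-90 region labels
#'
#' The ordered 90-region AAL parcellation used as network nodes, with the
#' abbreviations conventional in the connectomics literature (index 1 =
#' PreCG.L, ..., 90 = ITG.R).
#'
#' @return data.frame with columns `index`, `label`.
#' @export
aalLabels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "nvcoupler",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read an ROI time-series table
#'
#' TSV or CSV (auto-detected), header row of region labels, one row per
#' timepoint. CRLF and LF files parse identically.
#'
#' @param path file path.
#' @param expectedRegions optional required region count.
#' @return numeric T x N matrix with region labels as column names.
#' @export
readTimeSeries <- function(path, expectedRegions = NULL) {
  sep <- .detectSep(path)
  fields <- utils::count.fields(path, sep = sep, quote = "")
  if (length(unique(fields)) != 1L)
    stop("failed to parse '", basename(path), "': ragged rows (",
         min(fields), "-", max(fields), " fields; first bad row ",
         which(fields != fields[1])[1], ")")
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               colClasses = "numeric"),
    error = function(e)
      stop("failed to parse '", basename(path), "': ", conditionMessage(e)))
  labels <- colnames(df)
  if (anyDuplicated(labels))
    stop("duplicate region labels in '", basename(path), "': ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric or missing cells in '", basename(path), "'")
  if (!is.null(expectedRegions) && ncol(m) != expectedRegions)
    stop("'", basename(path), "' has ", ncol(m),
         " regions; expected ", expectedRegions)
  m
}

#' Read a cohort CBF table
#'
#' Subjects-by-regions table with a leading `subject_id` column.
#'
#' @param path CSV/TSV path.
#' @return numeric subjects x regions matrix with subject ids as row names.
#' @export
readCbfTable <- function(path) {
  sep <- .detectSep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("CBF table needs a 'subject_id' column")
  ids <- as.character(df$subject_id)
  m <- as.matrix(df[setdiff(names(df), "subject_id")])
  if (!is.numeric(m) || anyNA(m) || any(m <= 0))
    stop("CBF values must be numeric and strictly positive")
  rownames(m) <- ids
  m
}

#' Read a phenotype table
#'
#' Validates subject uniqueness, group labels and the MoCA range.
#'
#' @param path CSV/TSV path with columns `subject_id`, `group`, `moca`,
#'   `hemoglobin`, `hematocrit`, `age`, `sex`, `education`.
#' @return data.frame.
#' @export
readPhenotype <- function(path) {
  sep <- .detectSep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id values in phenotype table")
  if (!all(df$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  if ("moca" %in% names(df) &&
      any(df$moca < 0 | df$moca > 30, na.rm = TRUE))
    stop("MoCA scores must lie in [0, 30]")
  df
}

#' ROI mean extraction from NIfTI volumes
#'
#' Averages a CBF volume over the voxels of each integer atlas label
#' (1..nRegions; 0 = background). The two volumes must share grid and
#' affine (within 1e-4). Labels absent from the atlas yield `NA` with a
#' warning.
#'
#' @param cbfVolume path to the CBF NIfTI (.nii/.nii.gz).
#' @param atlasVolume path to the integer-labelled atlas NIfTI on the same
#'   grid.
#' @param nRegions number of atlas labels expected.
#' @return length-`nRegions` vector of mean CBF per region.
#' @export
extractRoiMeans <- function(cbfVolume, atlasVolume, nRegions = 90L) {
  cbf <- RNifti::readNifti(cbfVolume)
  atlas <- RNifti::readNifti(atlasVolume)
  if (!identical(dim(cbf), dim(atlas)))
    stop("CBF and atlas volumes have different grids: ",
         paste(dim(cbf), collapse = "x"), " vs ",
         paste(dim(atlas), collapse = "x"))
  if (max(abs(RNifti::xform(cbf) - RNifti::xform(atlas))) > 1e-4)
    stop("CBF and atlas affines differ by more than 1e-4")
  a <- as.array(atlas)
  if (any(abs(a - round(a)) > 1e-6))
    stop("atlas volume contains non-integer labels")
  a <- round(a)
  v <- as.array(cbf)
  out <- vapply(seq_len(nRegions), function(lab) {
    sel <- a == lab
    if (!any(sel)) return(NA_real_)
    mean(v[sel])
  }, numeric(1))
  if (anyNA(out))
    warning("atlas label(s) with no voxels: ",
            paste(which(is.na(out)), collapse = ", "))
  out
}

#' Participant exclusion bookkeeping
#'
#' Applies an itemized exclusion table to enrolled group counts and returns
#' the final sample sizes, mirroring the study's enrollment accounting.
#'
#' @param enrolled named vector `c(patients = ..., controls = ...)`.
#' @param exclusions data.frame with columns `group`
#'   (`patient`/`control`), `n`, `reason`.
#' @return list with `final` (named vector), `excludedTotal`, and the
#'   bookkeeping table.
#' @examples
#' applyExclusions()  # the study's enrollment: 52/51 -> 45/40, 18 excluded
#' @export
applyExclusions <- function(enrolled = c(patients = 52L, controls = 51L),
                            exclusions = studyExclusions()) {
  stopifnot(all(c("patients", "controls") %in% names(enrolled)),
            all(c("group", "n", "reason") %in% names(exclusions)))
  if (any(exclusions$n < 0)) stop("exclusion counts must be nonnegative")
  exP <- sum(exclusions$n[exclusions$group == "patient"])
  exC <- sum(exclusions$n[exclusions$group == "control"])
  if (exP > enrolled[["patients"]] || exC > enrolled[["controls"]])
    stop("more exclusions than enrolled subjects")
  final <- c(patients = enrolled[["patients"]] - exP,
             controls = enrolled[["controls"]] - exC)
  list(final = final, excludedTotal = exP + exC, bookkeeping = exclusions)
}

#' Itemized exclusion reasons of the study enrollment
#'
#' One patient with an encephalomalacia focus, one control with middle
#' cerebral artery occlusion, six patients and one control with head motion
#' > 3 mm, nine controls with MoCA < 26.
#'
#' @return data.frame with `group`, `n`, `reason`.
#' @export
studyExclusions <- function() {
  data.frame(
    group = c("patient", "control", "patient", "control", "control"),
    n = c(1L, 1L, 6L, 1L, 9L),
    reason = c("encephalomalacia focus", "MCA occlusion",
               "head motion > 3 mm", "head motion > 3 mm", "MoCA < 26"),
    stringsAsFactors = FALSE)
}
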