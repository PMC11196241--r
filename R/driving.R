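# Four-way "driving" classification of regions with significant coupling
# ratio changes, and the Venn overlap counts behind the sensitivity diagram.

#' Classify what drives regional coupling-ratio changes
#'
#' Every region with a significant ratio change is assigned one of four
#' categories according to which underlying indices also changed:
#' `CBF_only` (CBF significant, nodal not), `NODE_only` (nodal significant,
#' CBF not), `BOTH`, or `RATIO_only` (neither). Regions without a
#' significant ratio are unclassified (absent from the output).
#'
#' @param ratioSig,cbfSig,nodalSig logical region masks of equal length;
#'   `nodalSig` is typically the union of DC/Ne/BC significance and
#'   `ratioSig` the union over the three ratio indices (per-metric masks may
#'   be supplied instead).
#' @param regions optional region labels.
#' @return data.frame with `region`, `category` (factor with the four
#'   levels), and logical `cbf`, `nodal` columns recording the drivers.
#' @export
classifyDriving <- function(ratioSig, cbfSig, nodalSig, regions = NULL) {
  n <- length(ratioSig)
  if (length(cbfSig) != n || length(nodalSig) != n)
    stop("mask lengths differ")
  if (is.null(regions)) regions <- as.character(seq_len(n))
  keep <- which(as.logical(ratioSig))
  cat <- ifelse(cbfSig[keep] & nodalSig[keep], "BOTH",
         ifelse(cbfSig[keep] & !nodalSig[keep], "CBF_only",
         ifelse(!cbfSig[keep] & nodalSig[keep], "NODE_only", "RATIO_only")))
  data.frame(region = regions[keep],
             category = factor(cat, levels = c("CBF_only", "NODE_only",
                                               "BOTH", "RATIO_only")),
             cbf = as.logical(cbfSig[keep]),
             nodal = as.logical(nodalSig[keep]),
             row.names = NULL)
}

#' Venn overlap counts of significant regions
#'
#' Counts regions in each of the seven cells of the CBF / nodal / ratio
#' significance Venn diagram, plus each index's total (the "sensitivity" of
#' the index).
#'
#' @param cbfSig,nodalSig,ratioSig logical region masks of equal length.
#' @return named list of counts: `cbf_only`, `nodal_only`, `ratio_only`,
#'   `cbf_nodal`, `cbf_ratio`, `nodal_ratio`, `all_three`, and totals
#'   `total_cbf`, `total_nodal`, `total_ratio`.
#' @export
overlapCounts <- function(cbfSig, nodalSig, ratioSig) {
  n <- length(cbfSig)
  if (length(nodalSig) != n || length(ratioSig) != n)
    stop("mask lengths differ")
  c <- as.logical(cbfSig); d <- as.logical(nodalSig); r <- as.logical(ratioSig)
  list(
    cbf_only = sum(c & !d & !r),
    nodal_only = sum(!c & d & !r),
    ratio_only = sum(!c & !d & r),
    cbf_nodal = sum(c & d & !r),
    cbf_ratio = sum(c & !d & r),
    nodal_ratio = sum(!c & d & r),
    all_three = sum(c & d & r),
    total_cbf = sum(c),
    total_nodal = sum(d),
    total_ratio = sum(r))
}
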