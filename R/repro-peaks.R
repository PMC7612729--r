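#' Retain pooled peaks supported by replicates or pseudoreplicates
#'
#' ENCODE-style reproducibility filter applied after relaxed peak calling.
#' A pooled-replicate peak is retained when it is covered to at least
#' \code{min_overlap_frac} of its own length by peaks from both biological
#' replicates, or by peaks from both pooled pseudoreplicates. Coverage by
#' several supporting peaks is unioned, never double-counted. The default
#' fraction is 0.20 for ATAC and 0.30 for histone ChIP assays.
#'
#' @param pooled \code{GRanges} of peaks called on the pooled replicates.
#' @param rep1,rep2 peaks called on each biological replicate.
#' @param pseudo1,pseudo2 peaks called on each pooled pseudoreplicate.
#' @param assay "ATAC" or "histone"; sets the default overlap fraction.
#' @param min_overlap_frac override of the assay default, in (0, 1].
#' @param reciprocal additionally require, for the supporting set that
#'   rescues a pooled peak, that at least one supporting peak is itself
#'   covered to the same fraction by that pooled peak. Off by default: the
#'   test is anchored on the pooled peak.
#' @return the retained subset of \code{pooled}, records unmodified.
#' @export
retain_reproducible <- function(pooled, rep1, rep2, pseudo1, pseudo2,
                                assay = c("ATAC", "histone"),
                                min_overlap_frac = NULL,
                                reciprocal = FALSE) {
  assay <- match.arg(assay)
  f <- min_overlap_frac %||% if (assay == "ATAC") 0.20 else 0.30
  stopifnot(f > 0, f <= 1)
  if (length(pooled) == 0) {
    warning("empty pooled peak set; nothing to retain")
    return(pooled)
  }
  support <- function(reps) {
    ok <- Reduce(`&`, lapply(reps, function(r)
      overlap_fraction(pooled, r) >= f))
    if (reciprocal) {
      for (r in reps) {
        rev_ok <- logical(length(pooled))
        if (length(r) > 0) {
          frac_r <- overlap_fraction(r, pooled)
          h <- GenomicRanges::findOverlaps(pooled, r, ignore.strand = TRUE)
          good <- frac_r[S4Vectors::subjectHits(h)] >= f
          rev_ok[unique(S4Vectors::queryHits(h)[good])] <- TRUE
        }
        ok <- ok & rev_ok
      }
    }
    ok
  }
  keep <- support(list(rep1, rep2)) | support(list(pseudo1, pseudo2))
  pooled[keep]
}

#' Filter peaks on the MACS2 q-value score
#'
#' Keeps peaks whose -log10(q) score strictly exceeds the threshold, i.e.
#' FDR strictly below 10^-threshold. Conventional thresholds: 4 for ATAC
#' (FDR < 1e-4) and 3 for histone marks (FDR < 1e-3).
#'
#' @param peaks \code{GRanges} with a \code{qValue} metadata column.
#' @param min_q_score -log10(q) cutoff, exclusive.
#' @return the passing subset, order preserved.
#' @export
filter_by_qscore <- function(peaks, min_q_score) {
  .assert_granges(peaks, "peaks")
  if (!"qValue" %in% colnames(S4Vectors::mcols(peaks)))
    stop("peaks lack a qValue column", call. = FALSE)
  peaks[peaks$qValue > min_q_score]
}
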