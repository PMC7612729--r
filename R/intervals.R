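#' Merge overlapping or abutting intervals
#'
#' Thin wrapper around \link[GenomicRanges]{reduce} that validates input,
#' merges book-ended intervals (the bedtools-merge default) and returns the
#' result sorted by (chromosome, start). Strand is ignored.
#'
#' @param gr a \code{GRanges}.
#' @return sorted, disjoint \code{GRanges} covering the same bases.
#' @export
merge_intervals <- function(gr) {
  .assert_granges(gr)
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr),
                            ignore.strand = TRUE)
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Fraction of each subject interval covered by a query set
#'
#' Computes, for every subject interval, the fraction of its bases covered
#' by the union of the query intervals (overlapping query intervals are
#' counted once). This is the "overlap by peak/element length" statistic
#' used in reproducibility filtering and chromatin-state calling.
#'
#' @param subject \code{GRanges} of intervals whose coverage is measured.
#' @param query \code{GRanges} of covering intervals.
#' @return numeric vector in [0, 1], one value per subject interval.
#' @export
overlap_fraction <- function(subject, query) {
  .assert_granges(subject, "subject")
  .assert_granges(query, "query")
  covered <- numeric(length(subject))
  if (length(query) > 0 && length(subject) > 0) {
    q <- GenomicRanges::reduce(query, ignore.strand = TRUE)
    h <- GenomicRanges::findOverlaps(subject, q, ignore.strand = TRUE)
    if (length(h) > 0) {
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(subject)[S4Vectors::queryHits(h)],
        GenomicRanges::ranges(q)[S4Vectors::subjectHits(h)]))
      agg <- tapply(w, S4Vectors::queryHits(h), sum)
      covered[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  covered / GenomicRanges::width(subject)
}

#' Signed distance from points to the nearest TSS
#'
#' For each point, finds the annotation row whose TSS is closest in absolute
#' distance. The signed distance is negative when the point lies 5' of the
#' TSS on the gene's strand and positive 3' of it; thresholds elsewhere in
#' the package use the magnitude only. Ties (equal absolute distance) are
#' broken in favour of the lexicographically smallest gene_id. Points on a
#' chromosome absent from the annotation get an \code{NA} distance and gene.
#'
#' @param chrom,pos character / numeric vectors of point coordinates
#'   (1-based positions).
#' @param annotation data.frame as from [read_gene_annotation()].
#' @return data.frame with columns \code{chrom}, \code{pos},
#'   \code{distance} (signed), \code{gene_id}.
#' @export
nearest_tss_distance <- function(chrom, pos, annotation) {
  stopifnot(length(chrom) == length(pos))
  out <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    distance = NA_real_, gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  ann <- annotation[order(annotation$chrom, annotation$tss,
                          annotation$gene_id), , drop = FALSE]
  for (ch in unique(out$chrom)) {
    a <- ann[ann$chrom == ch, , drop = FALSE]
    idx <- which(out$chrom == ch)
    if (nrow(a) == 0) next
    for (i in idx) {
      d <- abs(a$tss - out$pos[i])
      j <- which(d == min(d))
      j <- j[order(a$gene_id[j])][1]
      signed <- if (a$strand[j] == "-") a$tss[j] - out$pos[i]
                else out$pos[i] - a$tss[j]
      out$distance[i] <- signed
      out$gene_id[i] <- a$gene_id[j]
    }
  }
  out
}

#' Extract a representative point from each peak
#'
#' ATAC peaks carry a called summit; histone peaks are conventionally
#' represented by their centre. Both conventions are exposed.
#'
#' @param peaks \code{GRanges} with narrowPeak metadata (see
#'   [read_narrowpeak()]).
#' @param mode "summit" uses the summit offset (falling back to the centre
#'   for peaks without one); "centre" always uses the midpoint.
#' @return data.frame with columns \code{chrom} and \code{pos} (1-based).
#' @export
peak_points <- function(peaks, mode = c("summit", "centre")) {
  mode <- match.arg(mode)
  .assert_granges(peaks, "peaks")
  centre <- floor((GenomicRanges::start(peaks) +
                   GenomicRanges::end(peaks)) / 2)
  pos <- centre
  if (mode == "summit" && "peak" %in% colnames(S4Vectors::mcols(peaks))) {
    off <- peaks$peak
    has <- !is.na(off) & off >= 0
    pos[has] <- GenomicRanges::start(peaks)[has] + off[has]
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
             pos = pos, stringsAsFactors = FALSE)
}
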