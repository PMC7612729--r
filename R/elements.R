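#' Build the promoter element set
#'
#' Promoters are defined as TSS +/- \code{flank} for every transcript of the
#' configured biotypes; transcripts sharing an identical promoter interval
#' are collapsed to one non-redundant element. Intervals extending past the
#' chromosome start are clipped with a warning.
#'
#' @param annotation data.frame as from [read_gene_annotation()], one row
#'   per transcript TSS.
#' @param flank half-width in bp (default 1000, i.e. TSS +/- 1 kb).
#' @return \code{GRanges} with metadata columns \code{element_id},
#'   \code{kind} ("promoter"), \code{associated_gene} (lexicographically
#'   first gene at the interval), \code{gene_ids} (comma-joined, all genes
#'   collapsed into the element) and \code{tss}.
#' @export
build_promoter_set <- function(annotation, flank = 1000) {
  stopifnot(nrow(annotation) > 0, flank > 0)
  start <- annotation$tss - flank
  if (any(start < 1)) {
    warning(sum(start < 1), " promoter interval(s) clipped at chromosome start")
    start <- pmax(start, 1)
  }
  end <- annotation$tss + flank - 1   # width 2*flank (half-open on disk)
  key <- paste(annotation$chrom, start, end)
  ord <- order(annotation$chrom, start, annotation$gene_id)
  keep <- ord[!duplicated(key[ord])]
  genes_by_key <- split(annotation$gene_id, key)
  gr <- GenomicRanges::GRanges(annotation$chrom[keep],
          IRanges::IRanges(start[keep], end[keep]))
  gr$element_id <- sprintf("prom_%05d", seq_along(gr))
  gr$kind <- "promoter"
  gr$associated_gene <- annotation$gene_id[keep]
  gr$gene_ids <- unname(vapply(genes_by_key[key[keep]],
                        function(g) paste(sort(unique(g)), collapse = ","),
                        character(1)))
  gr$tss <- annotation$tss[keep]
  gr
}

#' Build the putative enhancer element set from ATAC peaks
#'
#' Pipeline: (1) per-cell-type ATAC peaks are filtered on the q-value score
#' (-log10 q strictly greater than \code{min_q_score}); (2) peaks of all
#' cell types are merged into combined open-chromatin regions; (3) each
#' combined region is assigned the single constituent summit with the best
#' q score (ties: leftmost); (4) combined regions overlapping any promoter
#' by >= 1 bp are removed; (5) the remaining distal summits are extended by
#' +/- \code{flank} bp; (6) overlapping extended windows are merged, the
#' merged element keeping its best-q constituent summit.
#'
#' @param atac_peaks_by_celltype named list of \code{GRanges} narrowPeak
#'   sets, one per cell type.
#' @param promoters \code{GRanges} from [build_promoter_set()].
#' @param min_q_score -log10(q) cutoff, exclusive (default 4).
#' @param flank summit extension half-width in bp (default 500).
#' @param missing_summit what to do with peaks lacking a summit offset:
#'   "reject" errors, "use-centre" substitutes the peak midpoint.
#' @return \code{GRanges} with metadata columns \code{element_id},
#'   \code{kind} ("enhancer"), \code{summit} (1-based position) and
#'   \code{summit_q}.
#' @export
build_enhancer_set <- function(atac_peaks_by_celltype, promoters,
                               min_q_score = 4, flank = 500,
                               missing_summit = c("reject", "use-centre")) {
  missing_summit <- match.arg(missing_summit)
  stopifnot(is.list(atac_peaks_by_celltype),
            length(atac_peaks_by_celltype) > 0)
  filtered <- lapply(atac_peaks_by_celltype, filter_by_qscore, min_q_score)
  all_peaks <- suppressWarnings(do.call(c, unname(filtered)))
  if (length(all_peaks) == 0)
    stop("no ATAC peak passes the q-score filter", call. = FALSE)
  no_summit <- is.na(all_peaks$peak) | all_peaks$peak < 0
  if (any(no_summit)) {
    if (missing_summit == "reject")
      stop(sum(no_summit), " peak(s) lack a summit offset", call. = FALSE)
    mid <- floor((GenomicRanges::start(all_peaks) +
                  GenomicRanges::end(all_peaks)) / 2)
    all_peaks$peak[no_summit] <-
      (mid - GenomicRanges::start(all_peaks))[no_summit]
  }
  combined <- merge_intervals(all_peaks)

  summit_pos <- GenomicRanges::start(all_peaks) + all_peaks$peak
  summits <- GenomicRanges::GRanges(GenomicRanges::seqnames(all_peaks),
               IRanges::IRanges(summit_pos, width = 1),
               q = all_peaks$qValue)
  h <- GenomicRanges::findOverlaps(summits, combined, ignore.strand = TRUE)
  if (length(h) == 0) stop("no summit maps into a combined peak")
  sdf <- data.frame(region = S4Vectors::subjectHits(h),
                    pos = GenomicRanges::start(summits)[S4Vectors::queryHits(h)],
                    q = summits$q[S4Vectors::queryHits(h)])
  sdf <- sdf[order(sdf$region, -sdf$q, sdf$pos), ]
  best <- sdf[!duplicated(sdf$region), ]

  distal <- !(best$region %in% S4Vectors::queryHits(
    GenomicRanges::findOverlaps(combined, promoters, ignore.strand = TRUE)))
  best <- best[distal, , drop = FALSE]
  if (nrow(best) == 0) {
    warning("all combined ATAC peaks overlap promoters; no enhancers")
    return(GenomicRanges::GRanges())
  }

  chrom <- as.character(GenomicRanges::seqnames(combined))[best$region]
  win <- GenomicRanges::GRanges(chrom,
           IRanges::IRanges(pmax(best$pos - flank, 1),
                            best$pos + flank - 1))
  win$summit <- best$pos
  win$summit_q <- best$q
  merged <- merge_intervals(win)
  h2 <- GenomicRanges::findOverlaps(win, merged, ignore.strand = TRUE)
  wdf <- data.frame(el = S4Vectors::subjectHits(h2),
                    summit = win$summit[S4Vectors::queryHits(h2)],
                    q = win$summit_q[S4Vectors::queryHits(h2)])
  wdf <- wdf[order(wdf$el, -wdf$q, wdf$summit), ]
  top <- wdf[!duplicated(wdf$el), ]
  merged$element_id <- sprintf("enh_%06d", seq_along(merged))
  merged$kind <- "enhancer"
  merged$summit <- NA_integer_
  merged$summit_q <- NA_real_
  merged$summit[top$el] <- top$summit
  merged$summit_q[top$el] <- top$q
  merged
}
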