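suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(SummarizedExperiment)
})

## GRanges shorthand from BED-style 0-based half-open coordinates
gr_bed <- function(chrom, start, end, ...) {
  g <- GRanges(chrom, IRanges(start + 1L, end))
  extra <- list(...)
  for (nm in names(extra)) mcols(g)[[nm]] <- extra[[nm]]
  g
}

## narrowPeak-flavoured GRanges (BED-style inputs; summit = offset)
np <- function(chrom, start, end, q = 10, summit = NULL) {
  g <- gr_bed(chrom, start, end)
  n <- length(g)
  g$name <- sprintf("pk%d", seq_len(n))
  g$score <- rep(0L, n)
  g$signalValue <- rep(1, n)
  g$pValue <- rep_len(q + 2, n)
  g$qValue <- rep_len(q, n)
  g$peak <- if (is.null(summit)) as.integer(floor((end - start) / 2))
            else rep_len(as.integer(summit), n)
  g
}

## random BED-style intervals on a couple of chromosomes
random_intervals <- function(n, max_pos = 10000, max_len = 500,
                            chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  gr_bed(sample(chroms, n, replace = TRUE), start, start + len)
}

## per-base boolean-array union oracle: covered base count per chromosome
base_coverage_oracle <- function(gr, max_pos = 20000) {
  out <- list()
  for (ch in unique(as.character(seqnames(gr)))) {
    v <- logical(max_pos)
    g <- gr[seqnames(gr) == ch]
    for (i in seq_along(g)) v[start(g)[i]:end(g)[i]] <- TRUE
    out[[ch]] <- v
  }
  out
}

## brute-force tau-b by pair enumeration
tau_oracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

## tiny annotation table
toy_annotation <- function(tss, chrom = "chr1", strand = "+",
                           ids = NULL) {
  n <- length(tss)
  data.frame(gene_id = ids %||% sprintf("G%03d", seq_len(n)),
             gene_name = ids %||% sprintf("G%03d", seq_len(n)),
             chrom = rep_len(chrom, n), tss = tss,
             strand = rep_len(strand, n),
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small simulated study shared by several tests (noise-free peaks)
small_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_chromosomes = 1, chrom_length = 4e6,
             n_genes = 60, n_enhancers = 250,
             peak_noise = list(drop_prob = 0, shift_sd = 0), ...)
}
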