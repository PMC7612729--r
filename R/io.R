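#' Read a MACS2 narrowPeak (BED6+4) file
#'
#' narrowPeak is a 10-column tab-separated format: chrom, start, end, name,
#' score, strand, signalValue, pValue, qValue, peak. Coordinates on disk are
#' 0-based half-open; they are converted to the 1-based closed convention of
#' \link[GenomicRanges]{GRanges} on read. \code{pValue} and \code{qValue} are
#' -log10 transformed significance scores; \code{peak} is the summit offset
#' from \code{start} (-1 when absent). Lines starting with \code{#} are
#' skipped.
#'
#' @param path file path.
#' @return a \code{GRanges} with metadata columns \code{name}, \code{score},
#'   \code{signalValue}, \code{pValue}, \code{qValue}, \code{peak}.
#' @seealso [write_narrowpeak()], [read_bed()]
#' @export
read_narrowpeak <- function(path) {
  cols <- c("character", "integer", "integer", "character", "integer",
            "character", "numeric", "numeric", "numeric", "integer")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          quote = "", colClasses = cols,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "signalValue",
                                        "pValue", "qValue", "peak"))
  .validate_bed_coords(df, path)
  bad <- df$peak != -1L & (df$peak < 0L | df$peak >= df$end - df$start)
  if (any(bad))
    stop(sprintf("summit offset outside peak in record %d of %s",
                 which(bad)[1], path), call. = FALSE)
  if (any(df$pValue < 0) || any(df$qValue < 0))
    stop("negative -log10 p/q score in ", path, call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = df$name, score = df$score, signalValue = df$signalValue,
    pValue = df$pValue, qValue = df$qValue, peak = df$peak)
  gr
}

.validate_bed_coords <- function(df, path) {
  bad <- df$start >= df$end | df$start < 0L
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("malformed interval %s:%d-%d at record %d of %s",
                 df$chrom[i], df$start[i], df$end[i], i, path), call. = FALSE)
  }
  if (any(!nzchar(df$chrom)))
    stop("empty chromosome name in ", path, call. = FALSE)
  invisible(df)
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_narrowpeak()]: coordinates are converted back to 0-based
#' half-open. Missing metadata columns are filled with narrowPeak
#' conventions (score 0, signalValue 0, p/q 0, peak -1).
#'
#' @param gr a \code{GRanges}, typically from [read_narrowpeak()].
#' @param path output file path.
#' @export
write_narrowpeak <- function(gr, path) {
  .assert_granges(gr, "peaks")
  m <- S4Vectors::mcols(gr)
  n <- length(gr)
  get <- function(col, default) if (col %in% colnames(m)) m[[col]] else
    rep(default, n)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = get("name", "."),
    score = get("score", 0L),
    strand = strand,
    signalValue = get("signalValue", 0),
    pValue = get("pValue", 0),
    qValue = get("qValue", 0),
    peak = get("peak", -1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' @param path file path. Lines starting with \code{#} are skipped.
#' @return \code{GRanges}; columns 4-6 (name, score, strand) kept when
#'   present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns: ", path, call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  .validate_bed_coords(df, path)
  strand <- if (ncol(df) >= 6) ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*")
            else "*"
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start + 1L, df$end), strand = strand)
  if (ncol(df) >= 4) gr$name <- as.character(df[[4]])
  if (ncol(df) >= 5) gr$score <- df[[5]]
  gr
}

#' Write a GRanges as BED6 (or BED3 plus any extra metadata columns)
#'
#' @param gr a \code{GRanges}.
#' @param path output file path.
#' @param extra_cols character vector of metadata columns to append after
#'   the first six fields (BED6+ output).
#' @export
write_bed <- function(gr, path, extra_cols = character()) {
  .assert_granges(gr)
  m <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% colnames(m)) m$name else ".",
    score = if ("score" %in% colnames(m)) m$score else 0L,
    strand = strand)
  for (col in extra_cols) df[[col]] <- m[[col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a tab-separated table with a header naming at least
#' \code{gene_id}, \code{chrom}, \code{tss}, \code{strand}; optional
#' \code{gene_name} and \code{biotype} (e.g. protein_coding, lincRNA).
#' One row per transcript TSS; \code{tss} is a 1-based position.
#'
#' @param path file path. \code{#} comment lines tolerated.
#' @param biotypes if non-NULL, keep only these biotypes.
#' @return a data.frame with columns gene_id, gene_name, chrom, tss, strand,
#'   biotype.
#' @export
read_gene_annotation <- function(path,
                                 biotypes = c("protein_coding", "lincRNA")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
  if (!"biotype" %in% names(df)) df$biotype <- "protein_coding"
  if (any(df$tss < 0)) stop("negative TSS position in ", path, call. = FALSE)
  if (!is.null(biotypes)) df <- df[df$biotype %in% biotypes, , drop = FALSE]
  df[, c("gene_id", "gene_name", "chrom", "tss", "strand", "biotype")]
}

#' Write a gene annotation table
#' @param annotation data.frame as returned by [read_gene_annotation()].
#' @param path output file path.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
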