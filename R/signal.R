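#' Tile the genome into fixed-size analysis bins over peaks
#'
#' Produces 1-kb (by default) tiling bins and keeps those overlapping any
#' combined peak by at least 1 bp. Signal quantification for histone marks
#' is done on these bins rather than on the variable-width peaks.
#'
#' @param combined_peaks \code{GRanges} of merged peaks.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp (default 1000).
#' @return \code{GRanges} of retained bins with a \code{bin_id} column.
#' @export
make_analysis_bins <- function(combined_peaks, chrom_sizes,
                               bin_size = 1000) {
  .assert_granges(combined_peaks, "combined peaks")
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  tiles <- GenomicRanges::tileGenome(chrom_sizes, tilewidth = bin_size,
                                     cut.last.tile.in.chrom = TRUE)
  keep <- IRanges::overlapsAny(tiles, combined_peaks, ignore.strand = TRUE)
  bins <- tiles[keep]
  bins$bin_id <- sprintf("bin_%s_%d",
                         as.character(GenomicRanges::seqnames(bins)),
                         GenomicRanges::start(bins) - 1L)
  bins
}

#' Count fragments overlapping regions
#'
#' featureCounts '-O'-style counting: every fragment increments every region
#' it overlaps by at least 1 bp, so a fragment spanning two abutting regions
#' counts once in each.
#'
#' @param fragments named list of \code{GRanges}, one per sample, in the
#'   order of \code{samples}.
#' @param regions \code{GRanges} of elements or bins, carrying an
#'   \code{element_id} or \code{bin_id} column.
#' @param samples data.frame of sample metadata with at least
#'   \code{sample_id}; rows match \code{fragments}. Optional columns
#'   \code{cell_type}, \code{replicate}, \code{mark},
#'   \code{library_depth} (defaults to the fragment count).
#' @return a \link[SummarizedExperiment]{RangedSummarizedExperiment} with a
#'   \code{counts} assay.
#' @export
count_fragments <- function(fragments, regions, samples) {
  stopifnot(length(fragments) == nrow(samples))
  counts <- vapply(fragments, function(fr)
    GenomicRanges::countOverlaps(regions, fr, ignore.strand = TRUE),
    integer(length(regions)))
  counts <- matrix(counts, nrow = length(regions),
                   dimnames = list(.region_ids(regions), samples$sample_id))
  if (is.null(samples$library_depth))
    samples$library_depth <- vapply(fragments, length, integer(1))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = regions,
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
}

.region_ids <- function(regions) {
  m <- S4Vectors::mcols(regions)
  if ("element_id" %in% colnames(m)) return(m$element_id)
  if ("bin_id" %in% colnames(m)) return(m$bin_id)
  sprintf("region_%06d", seq_along(regions))
}

#' Build a count experiment from a precomputed matrix
#'
#' Convenience constructor for workflows starting from a counts table
#' rather than fragment files.
#'
#' @param counts integer matrix, regions x samples.
#' @param regions \code{GRanges} matching the rows (optional).
#' @param samples data.frame matching the columns; needs
#'   \code{sample_id}; \code{library_depth} defaults to column sums.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
count_experiment <- function(counts, samples, regions = NULL) {
  stopifnot(ncol(counts) == nrow(samples))
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (is.null(samples$library_depth))
    samples$library_depth <- colSums(counts)
  colnames(counts) <- samples$sample_id
  if (is.null(rownames(counts)))
    rownames(counts) <- if (!is.null(regions)) .region_ids(regions)
                        else sprintf("region_%06d", seq_len(nrow(counts)))
  cd <- S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  if (is.null(regions))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts), colData = cd)
  else
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts), rowRanges = regions, colData = cd)
}

#' Size factors and log2 normalization
#'
#' Default size factors are relative library depths,
#' s_j = depth_j / geometric-mean(depths); "median_ratio" selects the
#' median-of-ratios estimator instead. Adds a \code{normalized} assay
#' holding log2(count / s_j + 1) and a \code{size_factor} column to the
#' sample metadata. Normalization is monotone in counts within a sample.
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay.
#' @param method "depth" (default) or "median_ratio".
#' @return the experiment with assay \code{normalized} added.
#' @export
normalize_counts <- function(se, method = c("depth", "median_ratio")) {
  method <- match.arg(method)
  counts <- SummarizedExperiment::assay(se, "counts")
  if (method == "depth") {
    depth <- SummarizedExperiment::colData(se)$library_depth
    if (is.null(depth)) depth <- colSums(counts)
    if (any(depth <= 0)) stop("zero-depth sample", call. = FALSE)
    sf <- depth / geometric_mean(depth)
  } else {
    logg <- rowMeans(log(counts))
    use <- is.finite(logg)
    if (!any(use)) stop("no region with all-positive counts", call. = FALSE)
    sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
      exp(stats::median(log(cnt) - logg[use])))
  }
  norm <- log2(sweep(counts, 2, sf, "/") + 1)
  SummarizedExperiment::assays(se)$normalized <- norm
  SummarizedExperiment::colData(se)$size_factor <- sf
  se
}

#' Differential signal between two cell types
#'
#' Negative-binomial Wald test on size-factor-normalized counts. Per region
#' the fold change is the ratio of group means of normalized counts (with a
#' 0.5 pseudocount), and the Wald statistic uses the delta-method variance
#' of the log mean under an NB model,
#' Var(K) = s*mu + alpha*(s*mu)^2. The dispersion alpha is estimated by
#' method of moments per region and, by default, pooled into a single
#' common value across all regions ("common"), which keeps the test
#' calibrated with two replicates per condition; "genewise" uses the
#' per-region estimates. P-values are BH-adjusted and regions are flagged
#' dynamic when |log2FC| > \code{lfc_min} and adjusted p < \code{alpha}.
#' This is a deliberately simple, documented test, not a DESeq2 replica
#' (no shrinkage, no outlier handling); it is antisymmetric in the
#' contrast order.
#'
#' @param se normalized \code{SummarizedExperiment} (run
#'   [normalize_counts()] first) whose colData has \code{cell_type}.
#' @param contrast length-2 character vector (A, B); fold change is B vs A.
#' @param dispersion "common" or "genewise".
#' @param lfc_min,alpha dynamic-flag gates (defaults 1 and 0.05).
#' @return data.frame with region_id, base_mean, log2_fc, p_value,
#'   adj_p_value, dynamic.
#' @export
differential_signal <- function(se, contrast,
                                dispersion = c("common", "genewise"),
                                lfc_min = 1, alpha = 0.05) {
  dispersion <- match.arg(dispersion)
  stopifnot(length(contrast) == 2)
  cd <- SummarizedExperiment::colData(se)
  if (is.null(cd$size_factor))
    stop("run normalize_counts() before differential_signal()",
         call. = FALSE)
  ja <- which(cd$cell_type == contrast[1])
  jb <- which(cd$cell_type == contrast[2])
  if (length(ja) < 2 || length(jb) < 2)
    stop("need >= 2 replicates per condition for a dispersion estimate",
         call. = FALSE)
  counts <- SummarizedExperiment::assay(se, "counts")
  sf <- cd$size_factor
  q <- sweep(counts, 2, sf, "/")
  mA <- rowMeans(q[, ja, drop = FALSE])
  mB <- rowMeans(q[, jb, drop = FALSE])
  vA <- apply(q[, ja, drop = FALSE], 1, stats::var)
  vB <- apply(q[, jb, drop = FALSE], 1, stats::var)
  cA <- mean(1 / sf[ja]); cB <- mean(1 / sf[jb])
  ## MoM: Var(q) = mu/s + alpha mu^2, averaged over the two groups
  denom <- (mA^2 + mB^2) / 2
  a_hat <- ((vA + vB) / 2 - (mA * cA + mB * cB) / 2) / denom
  a_hat[!is.finite(a_hat)] <- NA
  a_hat <- pmax(a_hat, 0)
  a_use <- if (dispersion == "common") {
    rep(max(mean(a_hat, na.rm = TRUE), 1e-8), length(mA))
  } else ifelse(is.na(a_hat), 0, a_hat)

  pc <- 0.5
  lfc <- log2(mB + pc) - log2(mA + pc)
  varA <- (mA * sum(1 / sf[ja]) + length(ja) * a_use * mA^2) / length(ja)^2
  varB <- (mB * sum(1 / sf[jb]) + length(jb) * a_use * mB^2) / length(jb)^2
  se_log <- sqrt(varA / (mA + pc)^2 + varB / (mB + pc)^2)
  z <- ifelse(se_log > 0, (log(mB + pc) - log(mA + pc)) / se_log, 0)
  p <- 2 * stats::pnorm(-abs(z))
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(region_id = rownames(counts), base_mean = (mA + mB) / 2,
             log2_fc = lfc, p_value = p, adj_p_value = adj,
             dynamic = abs(lfc) > lfc_min & adj < alpha,
             stringsAsFactors = FALSE)
}

#' Select dynamically active (or repressed) elements
#'
#' An element qualifies when its state is in \code{states} in at least one
#' cell type and it is flagged dynamic in at least one of the supplied
#' contrasts; elements in a qualifying state in every cell type
#' (constitutive) are excluded when \code{exclude_constitutive} is TRUE,
#' as in the dynamically-active-enhancer definition.
#'
#' @param assignments data.frame from [classify_elements()].
#' @param diffs list of data.frames from [differential_signal()], one per
#'   contrast pair.
#' @param states qualifying states (e.g. "active", or
#'   c("mixed", "poised", "repressed") for the repression variant).
#' @param cell_types the cell types over which "any"/"all" are evaluated.
#' @param exclude_constitutive drop elements qualifying in every cell type.
#' @return character vector of element ids.
#' @export
select_dynamic_elements <- function(assignments, diffs, states,
                                    cell_types,
                                    exclude_constitutive = TRUE) {
  sub <- assignments[assignments$cell_type %in% cell_types, , drop = FALSE]
  hit <- sub$state %in% states
  n_hit <- tapply(hit, sub$element_id, sum)
  any_state <- names(n_hit)[n_hit >= 1]
  all_state <- names(n_hit)[n_hit == length(cell_types)]
  dyn <- unique(unlist(lapply(diffs, function(d)
    d$region_id[d$dynamic])))
  out <- intersect(any_state, dyn)
  if (exclude_constitutive) out <- setdiff(out, all_state)
  sort(out)
}

#' K-means clustering of dynamic elements on z-scored profiles
#'
#' Rows (elements) are z-scored across all samples of the normalized
#' matrix, then clustered with \link[stats]{kmeans} (Hartigan-Wong,
#' \code{nstart} random starts under the given seed, so runs are
#' reproducible). Zero-variance rows get an all-zero profile.
#'
#' @param se normalized \code{SummarizedExperiment}.
#' @param element_ids rows to cluster (e.g. from
#'   [select_dynamic_elements()]).
#' @param k number of clusters.
#' @param seed RNG seed; recorded in the result.
#' @param nstart random restarts (default 25).
#' @return list with \code{labels} (named integer vector, 1..k),
#'   \code{centers} (k x samples matrix), \code{seed}, \code{k}.
#' @export
cluster_dynamic <- function(se, element_ids, k, seed = 1, nstart = 25) {
  norm <- SummarizedExperiment::assay(se, "normalized")
  if (is.null(norm)) stop("run normalize_counts() first", call. = FALSE)
  x <- norm[element_ids, , drop = FALSE]
  if (k > nrow(x))
    stop("k exceeds the number of elements", call. = FALSE)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(labels = stats::setNames(km$cluster, element_ids),
       centers = km$centers, seed = seed, k = k)
}

#' Area under the ROC curve by rank statistics
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive scores above a random negative (ties counting 1/2).
#' Invariant under any strictly monotone transform of the score.
#'
#' @param score numeric predictor.
#' @param positive logical labels.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes", call. = FALSE)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Chromatin marks as classifiers of promoter expression
#'
#' Ranks non-neutral promoters by the expression of their associated gene,
#' labels the \code{top_n} most (or least) expressed as positives, and
#' reports the AUC of each mark's promoter signal as a classifier of that
#' label.
#'
#' @param signal numeric matrix, promoters x marks (normalized signal).
#' @param expression numeric vector per promoter.
#' @param states state per promoter (neutral promoters are excluded).
#' @param top_n positives taken from the extreme of the ranking
#'   (default 1000); capped at half the promoters with a warning.
#' @param tail "top" or "bottom" of the expression ranking.
#' @return named numeric vector: AUC per mark.
#' @export
mark_expression_auc <- function(signal, expression, states,
                                top_n = 1000, tail = c("top", "bottom")) {
  tail <- match.arg(tail)
  stopifnot(nrow(signal) == length(expression),
            length(expression) == length(states))
  keep <- states != "neutral"
  signal <- signal[keep, , drop = FALSE]
  expression <- expression[keep]
  n <- length(expression)
  if (top_n >= n) {
    warning("fewer promoters than top_n; using floor(n/2)")
    top_n <- floor(n / 2)
  }
  ord <- order(expression, decreasing = (tail == "top"))
  positive <- logical(n)
  positive[ord[seq_len(top_n)]] <- TRUE
  apply(signal, 2, rank_auc, positive = positive)
}
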