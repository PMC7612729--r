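#' Assign each enhancer to its nearest gene within a window
#'
#' Distance is measured from the enhancer summit to the TSS; enhancers with
#' no TSS within \code{max_distance} (exclusive) stay unassigned and are
#' dropped from the result.
#'
#' @param enhancers \code{GRanges} from [build_enhancer_set()] (needs
#'   \code{element_id} and \code{summit}).
#' @param annotation data.frame as from [read_gene_annotation()] with one
#'   row per gene TSS.
#' @param max_distance window in bp (default 1e5, i.e. < 100 kb).
#' @return data.frame with enhancer_id, gene_id, distance (signed; see
#'   [nearest_tss_distance()]).
#' @export
assign_nearest_gene <- function(enhancers, annotation,
                                max_distance = 1e5) {
  nd <- nearest_tss_distance(
    as.character(GenomicRanges::seqnames(enhancers)),
    enhancers$summit, annotation)
  keep <- !is.na(nd$distance) & abs(nd$distance) < max_distance
  data.frame(enhancer_id = enhancers$element_id[keep],
             gene_id = nd$gene_id[keep],
             distance = nd$distance[keep],
             stringsAsFactors = FALSE)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between an enhancer's signal and a
#' gene's expression across samples. Returns NA with a warning when either
#' vector has zero variance (tau undefined).
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return tau-b in [-1, 1], or NA.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector; tau undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "kendall")
}

#' Empirical p-value of an enhancer-gene correlation
#'
#' The null distribution is the set of Kendall taus between the enhancer's
#' signal and every (expressed) gene on the same chromosome; the empirical
#' p-value is the fraction of null taus greater than or equal to the
#' observed one. With \code{add_one}, the conventional (k+1)/(N+1) estimate
#' is returned instead of the literal count/N.
#'
#' @param enhancer_signal numeric vector across samples.
#' @param null_expression numeric matrix, genes x samples, of
#'   same-chromosome gene expression (rownames are gene ids).
#' @param observed_tau the candidate pair's tau.
#' @param exclude_gene gene id to drop from the null (the focal gene;
#'   NULL keeps all).
#' @param add_one use (k+1)/(N+1) smoothing.
#' @return empirical p in [0, 1].
#' @export
empirical_link_pvalue <- function(enhancer_signal, null_expression,
                                  observed_tau, exclude_gene = NULL,
                                  add_one = FALSE) {
  if (!is.null(exclude_gene))
    null_expression <- null_expression[
      setdiff(rownames(null_expression), exclude_gene), , drop = FALSE]
  if (nrow(null_expression) == 0)
    stop("empty null gene set", call. = FALSE)
  taus <- apply(null_expression, 1, function(y)
    suppressWarnings(kendall_tau(enhancer_signal, y)))
  taus <- taus[!is.na(taus)]
  if (length(taus) == 0) stop("no defined null tau", call. = FALSE)
  k <- sum(taus >= observed_tau)
  if (add_one) (k + 1) / (length(taus) + 1) else k / length(taus)
}

#' Flag high-confidence enhancer-gene links
#'
#' Boundary values pass: tau >= tau_min and p <= p_max.
#'
#' @param links data.frame with \code{tau} and \code{empirical_p}.
#' @param tau_min,p_max thresholds (defaults 0.3 and 0.05).
#' @return the data.frame with a logical \code{high_confidence} column.
#' @export
call_high_confidence <- function(links, tau_min = 0.3, p_max = 0.05) {
  links$high_confidence <- !is.na(links$tau) & !is.na(links$empirical_p) &
    links$tau >= tau_min & links$empirical_p <= p_max
  links
}

#' Link enhancers to genes by correlation against an empirical null
#'
#' Full linking pipeline: each enhancer is assigned to its nearest gene
#' within \code{max_distance} of the summit; the Kendall tau between the
#' enhancer's signal (typically H3K27ac) and the gene's expression across
#' all samples is computed; its significance is assessed against the
#' empirical null of taus with all other expressed genes on the same
#' chromosome; and pairs with tau >= tau_min and empirical p <= p_max are
#' flagged high-confidence.
#'
#' @param enhancer_signal numeric matrix, enhancers x samples, rownames =
#'   element ids (normalized signal at enhancers).
#' @param expression numeric matrix, genes x samples, rownames = gene ids,
#'   same sample order.
#' @param enhancers \code{GRanges} from [build_enhancer_set()].
#' @param annotation gene annotation data.frame.
#' @param max_distance summit-to-TSS assignment window (default 1e5).
#' @param tau_min,p_max high-confidence gates (defaults 0.3, 0.05).
#' @param min_expression genes enter the null only when their mean signal
#'   exceeds this (default 0; zero-variance genes are dropped regardless).
#' @param exclude_focal drop the focal gene from its own null (default
#'   TRUE).
#' @param add_one (k+1)/(N+1) smoothing for the empirical p.
#' @return a link table: enhancer_id, gene_id, distance, tau, empirical_p,
#'   high_confidence. Pairs with undefined tau are dropped with a warning.
#' @export
link_enhancers_to_genes <- function(enhancer_signal, expression,
                                    enhancers, annotation,
                                    max_distance = 1e5,
                                    tau_min = 0.3, p_max = 0.05,
                                    min_expression = 0,
                                    exclude_focal = TRUE,
                                    add_one = FALSE) {
  stopifnot(ncol(enhancer_signal) == ncol(expression))
  pairs <- assign_nearest_gene(enhancers, annotation, max_distance)
  pairs <- pairs[pairs$enhancer_id %in% rownames(enhancer_signal) &
                 pairs$gene_id %in% rownames(expression), , drop = FALSE]
  expressed <- rowMeans(expression) > min_expression
  chrom_of <- stats::setNames(annotation$chrom, annotation$gene_id)
  enh_chrom <- stats::setNames(
    as.character(GenomicRanges::seqnames(enhancers)), enhancers$element_id)
  tau <- rep(NA_real_, nrow(pairs))
  emp <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- enhancer_signal[pairs$enhancer_id[i], ]
    y <- expression[pairs$gene_id[i], ]
    t_i <- suppressWarnings(kendall_tau(x, y))
    if (is.na(t_i)) next
    tau[i] <- t_i
    null_genes <- annotation$gene_id[
      annotation$chrom == enh_chrom[[pairs$enhancer_id[i]]]]
    null_genes <- intersect(null_genes,
                            rownames(expression)[expressed])
    null_expr <- expression[null_genes, , drop = FALSE]
    emp[i] <- empirical_link_pvalue(
      x, null_expr, t_i,
      exclude_gene = if (exclude_focal) pairs$gene_id[i] else NULL,
      add_one = add_one)
  }
  drop <- is.na(tau)
  if (any(drop))
    warning(sum(drop), " pair(s) dropped: undefined tau")
  out <- data.frame(pairs[!drop, , drop = FALSE],
                    tau = tau[!drop], empirical_p = emp[!drop],
                    stringsAsFactors = FALSE)
  call_high_confidence(out, tau_min = tau_min, p_max = p_max)
}
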