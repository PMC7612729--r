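#' Cooperativity classes of a set of TF peak collections
#'
#' Merges all TF peaks into a combined binding universe, marks each
#' combined region as bound by a TF when it overlaps >= 1 bp of that TF's
#' peaks, and labels it with its cooperativity class (the non-empty subset
#' of TFs binding it, e.g. "SOX17", "SOX17+TFAP2C"). Pairwise co-binding
#' significance is an upper-tail hypergeometric test on the universe
#' (observed count included, the phyper(k-1, ..., lower.tail = FALSE)
#' convention).
#'
#' @param collections named list of \code{GRanges}, one per TF (typically
#'   three).
#' @return list with \code{universe} (combined \code{GRanges} with a
#'   \code{class} column and one logical column per TF),
#'   \code{class_counts} (named counts over the non-empty subsets) and
#'   \code{pairwise} (data.frame tf1, tf2, n1, n2, overlap, p_value).
#' @export
intersect_tf_peaks <- function(collections) {
  stopifnot(is.list(collections), length(collections) >= 2,
            !is.null(names(collections)))
  tfs <- names(collections)
  empty <- vapply(collections, length, integer(1)) == 0
  if (any(empty))
    warning("empty peak collection(s): ", paste(tfs[empty], collapse = ", "))
  universe <- merge_intervals(
    suppressWarnings(do.call(c, lapply(unname(collections), function(g)
      GenomicRanges::granges(g)))))
  bound <- vapply(collections, function(p)
    IRanges::overlapsAny(universe, p, ignore.strand = TRUE),
    logical(length(universe)))
  bound <- matrix(bound, ncol = length(tfs), dimnames = list(NULL, tfs))
  lab <- apply(bound, 1, function(b) paste(tfs[b], collapse = "+"))
  universe$class <- lab
  for (tf in tfs) S4Vectors::mcols(universe)[[tf]] <- bound[, tf]

  subsets <- unlist(lapply(seq_along(tfs), function(k)
    apply(utils::combn(tfs, k), 2, paste, collapse = "+")))
  class_counts <- stats::setNames(
    vapply(subsets, function(s) sum(lab == s), numeric(1)), subsets)

  prs <- utils::combn(tfs, 2)
  pairwise <- data.frame(tf1 = prs[1, ], tf2 = prs[2, ],
                         n1 = NA_real_, n2 = NA_real_,
                         overlap = NA_real_, p_value = NA_real_)
  N <- length(universe)
  for (i in seq_len(ncol(prs))) {
    b1 <- bound[, prs[1, i]]; b2 <- bound[, prs[2, i]]
    k <- sum(b1 & b2)
    pairwise$n1[i] <- sum(b1); pairwise$n2[i] <- sum(b2)
    pairwise$overlap[i] <- k
    pairwise$p_value[i] <- stats::phyper(k - 1, sum(b1), N - sum(b1),
                                         sum(b2), lower.tail = FALSE)
  }
  list(universe = universe, class_counts = class_counts,
       pairwise = pairwise)
}

#' BETA-style distance-decayed weight
#'
#' Default regulatory-potential decay: w(d) = exp(-(0.5 + 4 d/window)),
#' maximal at the TSS and monotone decreasing with distance.
#'
#' @param delta |summit - TSS| / window in [0, 1].
#' @return weight in (0, exp(-0.5)].
#' @export
beta_decay <- function(delta) exp(-(0.5 + 4 * delta))

#' Regulatory potential of each gene for one TF
#'
#' Sums a monotone-decreasing distance weight over all peak points within
#' \code{window} bp of the gene's TSS (inclusive); genes with no nearby
#' peak score 0. Additive over peaks. Merged peak regions without a summit
#' annotation are represented by their midpoint.
#'
#' @param peaks \code{GRanges} of the TF's peaks (summit used if present).
#' @param annotation gene annotation data.frame (one TSS per gene).
#' @param window distance cutoff in bp (default 1e5).
#' @param decay weight function of delta = distance/window.
#' @return data.frame gene_id, score, n_peaks.
#' @export
regulatory_potential <- function(peaks, annotation, window = 1e5,
                                 decay = beta_decay) {
  pts <- peak_points(peaks, mode = "summit")
  score <- numeric(nrow(annotation))
  npk <- integer(nrow(annotation))
  for (ch in unique(annotation$chrom)) {
    gi <- which(annotation$chrom == ch)
    pp <- pts$pos[pts$chrom == ch]
    if (length(pp) == 0) next
    for (g in gi) {
      d <- abs(pp - annotation$tss[g])
      d <- d[d <= window]
      npk[g] <- length(d)
      if (length(d)) score[g] <- sum(decay(d / window))
    }
  }
  data.frame(gene_id = annotation$gene_id, score = score, n_peaks = npk,
             stringsAsFactors = FALSE)
}

#' Activator/repressor prediction by one-tailed KS tests
#'
#' Compares the regulatory-potential distribution of up- and down-regulated
#' gene groups against the unchanged group with one-sided
#' Kolmogorov-Smirnov tests, testing whether the group is stochastically
#' enriched for high potential (its CDF lies below the unchanged CDF). A
#' significant up group marks the TF as an activator, a significant down
#' group as a repressor.
#'
#' @param potentials data.frame from [regulatory_potential()].
#' @param up_genes,down_genes,unchanged_genes disjoint gene-id vectors.
#' @return data.frame with one row per group (up, down): n, D statistic,
#'   p_value (asymptotic), unreliable flag for groups smaller than 5.
#' @export
predict_tf_function <- function(potentials, up_genes, down_genes,
                                unchanged_genes) {
  if (length(intersect(up_genes, down_genes)) ||
      length(intersect(up_genes, unchanged_genes)) ||
      length(intersect(down_genes, unchanged_genes)))
    stop("gene groups must be disjoint", call. = FALSE)
  sc <- stats::setNames(potentials$score, potentials$gene_id)
  ref <- sc[intersect(unchanged_genes, names(sc))]
  one <- function(genes) {
    g <- sc[intersect(genes, names(sc))]
    if (length(g) == 0 || length(ref) == 0)
      return(c(n = length(g), D = NA, p = NA))
    ## alternative = "less": CDF of x below CDF of y, i.e. x
    ## stochastically larger
    kt <- suppressWarnings(stats::ks.test(g, ref, alternative = "less",
                                          exact = FALSE))
    c(n = length(g), D = unname(kt$statistic), p = kt$p.value)
  }
  res <- rbind(up = one(up_genes), down = one(down_genes))
  data.frame(group = rownames(res), n = res[, "n"], D = res[, "D"],
             p_value = res[, "p"],
             unreliable = res[, "n"] < 5,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call direct up/down target genes of TF cooperativity classes
#'
#' A gene is a direct up target of a class (a subset of the TF trio) when:
#' (1) it is downregulated (log2FC < -lfc_min, adjusted p < alpha) in the
#' knockout of every member TF; (2) a peak of that class lies within
#' \code{window} bp of its TSS (class-peak midpoint to TSS); and (3) at
#' least one of those nearby class peaks overlaps an element that is
#' active or mixed in the context cell type. Direct down targets mirror
#' this: upregulated in every member knockout, a nearby class peak, and
#' none of the nearby class peaks overlapping an active element.
#'
#' @param tf_classes result of [intersect_tf_peaks()].
#' @param ko_tables named list (by TF) of data.frames with gene_id,
#'   log2_fc, adj_p. Classes with a missing member table are skipped with
#'   a warning.
#' @param elements \code{GRanges} of enhancers and/or promoters with
#'   \code{element_id}.
#' @param assignments state assignments (from [classify_elements()]) for
#'   the context cell type.
#' @param context cell type in which element states gate the calls.
#' @param annotation gene annotation data.frame.
#' @param window summit-to-TSS distance cutoff (default 1e5, inclusive).
#' @param lfc_min,alpha knockout differential-expression gates.
#' @return data.frame gene_id, class, direction ("up"/"down"), n_peaks.
#' @export
call_direct_targets <- function(tf_classes, ko_tables, elements,
                                assignments, context, annotation,
                                window = 1e5, lfc_min = 1, alpha = 0.05) {
  universe <- tf_classes$universe
  st <- assignments[assignments$cell_type == context, , drop = FALSE]
  state_of <- stats::setNames(st$state, st$element_id)
  el_state <- state_of[elements$element_id]
  active_mixed <- elements[!is.na(el_state) &
                           el_state %in% c("active", "mixed")]
  active_only <- elements[!is.na(el_state) & el_state == "active"]
  pk_active_mixed <- IRanges::overlapsAny(universe, active_mixed,
                                          ignore.strand = TRUE)
  pk_active <- IRanges::overlapsAny(universe, active_only,
                                    ignore.strand = TRUE)
  pts <- peak_points(universe, mode = "centre")

  classes <- names(tf_classes$class_counts)
  out <- list()
  for (cl in classes) {
    members <- strsplit(cl, "+", fixed = TRUE)[[1]]
    miss <- setdiff(members, names(ko_tables))
    if (length(miss)) {
      warning("no knockout table for ", paste(miss, collapse = ", "),
              "; skipping class ", cl)
      next
    }
    in_class <- which(universe$class == cl)
    if (length(in_class) == 0) next
    down_all <- up_all <- NULL
    for (tf in members) {
      kt <- ko_tables[[tf]]
      dn <- kt$gene_id[kt$log2_fc < -lfc_min & kt$adj_p < alpha]
      up <- kt$gene_id[kt$log2_fc > lfc_min & kt$adj_p < alpha]
      down_all <- if (is.null(down_all)) dn else intersect(down_all, dn)
      up_all <- if (is.null(up_all)) up else intersect(up_all, up)
    }
    cand <- annotation[annotation$gene_id %in% c(down_all, up_all), ,
                       drop = FALSE]
    for (g in seq_len(nrow(cand))) {
      near <- in_class[pts$chrom[in_class] == cand$chrom[g] &
                       abs(pts$pos[in_class] - cand$tss[g]) <= window]
      if (length(near) == 0) next
      gid <- cand$gene_id[g]
      if (gid %in% down_all && any(pk_active_mixed[near]))
        out[[length(out) + 1]] <- data.frame(
          gene_id = gid, class = cl, direction = "up",
          n_peaks = length(near), stringsAsFactors = FALSE)
      if (gid %in% up_all && !any(pk_active[near]))
        out[[length(out) + 1]] <- data.frame(
          gene_id = gid, class = cl, direction = "down",
          n_peaks = length(near), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), class = character(),
                      direction = character(), n_peaks = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Overlap enrichment of a query region set against references
#'
#' For each named reference set, reports the fraction of query regions
#' overlapping it (>= 1 bp) and an upper-tail hypergeometric enrichment
#' p-value on the supplied universe (e.g. all promoters, all elements).
#' The query must be drawn from the universe.
#'
#' @param query \code{GRanges} subset of the universe.
#' @param reference_sets named list of \code{GRanges}.
#' @param universe \code{GRanges} background region set.
#' @return data.frame reference, query_hits, fraction, universe_hits,
#'   p_value.
#' @export
region_set_enrichment <- function(query, reference_sets, universe) {
  in_universe <- suppressWarnings(IRanges::overlapsAny(
    query, universe, type = "equal", ignore.strand = TRUE))
  if (!all(in_universe))
    stop(sum(!in_universe), " query region(s) not in the universe",
         call. = FALSE)
  N <- length(universe); n <- length(query)
  res <- lapply(names(reference_sets), function(nm) {
    ref <- reference_sets[[nm]]
    K <- sum(suppressWarnings(
      IRanges::overlapsAny(universe, ref, ignore.strand = TRUE)))
    k <- sum(suppressWarnings(
      IRanges::overlapsAny(query, ref, ignore.strand = TRUE)))
    data.frame(reference = nm, query_hits = k, fraction = k / n,
               universe_hits = K,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
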