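#' Configuration of a synthetic regulatory-genomics study
#'
#' Defines an in-silico study emulating the statistical structure of a
#' multi-stage differentiation experiment: 6 cell types x 2 replicates,
#' ATAC and histone-mark peak sets with replicate/pseudoreplicate
#' concordance, negative-binomial fragment counts at elements with
#' state-dependent means, gene expression coupled to linked-enhancer
#' activity, and a TF trio with planted cooperativity classes and knockout
#' effects. The seed fully determines every output.
#'
#' Enhancers are assigned one of nine activity archetypes (patterns of
#' cell types in which they are active); in inactive cell types they carry
#' a per-enhancer background state (neutral, primed, repressed or poised).
#' With \code{null_structure = TRUE} all planted structure is removed:
#' every enhancer is constitutively active, no links are planted, and all
#' means are flat across cell types - the channel used for calibration
#' checks.
#'
#' @param seed master RNG seed.
#' @param n_chromosomes,chrom_length genome shape (default 2 x 10 Mb).
#' @param n_genes,n_enhancers element counts (defaults 300 and 2000).
#' @param cell_types,replicates sample design (defaults: the 6-stage
#'   trajectory, 2 replicates).
#' @param link_fraction fraction of enhancers with a planted link to their
#'   nearest gene (default 0.1).
#' @param link_strength multiplier on the expression contrast of linked
#'   genes (1 = the default 8-fold contrast between active and inactive
#'   cell types).
#' @param nb_dispersion,expr_dispersion NB dispersion of chromatin and
#'   expression counts (0 = noise-free rounded means).
#' @param mean_by_state list per mark of expected fragment counts by
#'   enhancer state.
#' @param peak_noise list: \code{drop_prob} (per-replicate peak dropout)
#'   and \code{shift_sd} (bp jitter of replicate peaks).
#' @param tf_config list: \code{tfs}, \code{context}, \code{n_up_per_class},
#'   \code{n_down_per_class}, \code{ko_lfc}, \code{ko_noise_sd},
#'   \code{background_peaks}.
#' @param null_structure remove all planted structure (see above).
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2, chrom_length = 1e7,
                       n_genes = 300, n_enhancers = 2000,
                       cell_types = c("hESC", "PreME", "ME", "DE",
                                      "hPGCLC", "hPGC"),
                       replicates = 2,
                       link_fraction = 0.1, link_strength = 1,
                       nb_dispersion = 0.05, expr_dispersion = 0.05,
                       mean_by_state = NULL,
                       peak_noise = list(drop_prob = 0.05, shift_sd = 50),
                       tf_config = list(tfs = c("SOX17", "PRDM1",
                                                "TFAP2C"),
                                        context = "hPGCLC",
                                        n_up_per_class = 6,
                                        n_down_per_class = 4,
                                        ko_lfc = 2.5, ko_noise_sd = 0,
                                        background_peaks = 40),
                       null_structure = FALSE) {
  states <- ENHANCER_STATES
  default_means <- list(
    ATAC     = c(active = 150, mixed = 100, primed = 30, poised = 20,
                 repressed = 10, neutral = 10),
    H3K4me1  = c(active = 120, mixed = 120, primed = 120, poised = 120,
                 repressed = 6, neutral = 6),
    H3K27ac  = c(active = 200, mixed = 150, primed = 8, poised = 8,
                 repressed = 5, neutral = 5),
    H3K27me3 = c(active = 5, mixed = 100, primed = 6, poised = 100,
                 repressed = 100, neutral = 5))
  mean_by_state <- mean_by_state %||% default_means
  stopifnot(link_fraction >= 0, link_fraction <= 1,
            peak_noise$drop_prob >= 0, peak_noise$drop_prob <= 1,
            nb_dispersion >= 0, expr_dispersion >= 0,
            all(unlist(mean_by_state) >= 0))
  cfg <- list(seed = seed, n_chromosomes = n_chromosomes,
              chrom_length = chrom_length, n_genes = n_genes,
              n_enhancers = n_enhancers, cell_types = cell_types,
              replicates = replicates, link_fraction = link_fraction,
              link_strength = link_strength,
              nb_dispersion = nb_dispersion,
              expr_dispersion = expr_dispersion,
              mean_by_state = mean_by_state, peak_noise = peak_noise,
              tf_config = tf_config, null_structure = null_structure)
  class(cfg) <- "sim_config"
  cfg
}

## nine activity archetypes over the six-stage trajectory (rows) -
## binary: in which cell types is the enhancer active
.archetype_matrix <- function(cell_types) {
  n <- length(cell_types)
  pat <- list(c(1, 0, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0),
              c(0, 1, 1, 0, 0, 0), c(0, 0, 1, 1, 0, 0),
              c(0, 0, 0, 1, 0, 0), c(0, 0, 0, 0, 1, 1),
              c(0, 0, 0, 0, 0, 1), c(0, 1, 0, 0, 1, 1),
              c(1, 1, 1, 1, 1, 0))
  m <- do.call(rbind, lapply(pat, function(p) p[seq_len(n)]))
  colnames(m) <- cell_types
  m
}

## canonical mark flags emitted for each planted enhancer state,
## order (H3K4me1, H3K27ac, H3K27me3); consistent with the default
## truth table
.enh_state_flags <- list(
  active = c(1, 1, 0), mixed = c(1, 1, 1), primed = c(1, 0, 0),
  poised = c(1, 0, 1), repressed = c(0, 0, 1), neutral = c(0, 0, 0))
## promoter flags, order (H3K4me3, H3K27ac, H3K27me3)
.prom_state_flags <- list(
  active = c(1, 1, 0), mixed = c(0, 1, 1), poised = c(1, 0, 1),
  repressed = c(0, 0, 1), neutral = c(0, 0, 0))

#' Simulate a gene annotation table
#'
#' Genes are laid out on a jittered grid per chromosome, which guarantees
#' a minimum pairwise TSS spacing of 40% of the grid step; strand and
#' biotype (90% protein_coding, 10% lincRNA) are random. Deterministic
#' under the config seed.
#'
#' @param config a [sim_config()].
#' @return gene annotation data.frame (one TSS per gene).
#' @export
simulate_annotation <- function(config) {
  set.seed(derive_seed(config$seed, 1))
  per_chr <- ceiling(config$n_genes / config$n_chromosomes)
  step <- config$chrom_length / per_chr
  if (step < 5000) stop("infeasible gene spacing", call. = FALSE)
  rows <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    n_here <- min(per_chr, config$n_genes - (ci - 1) * per_chr)
    if (n_here <= 0) break
    tss <- round((seq_len(n_here) - 0.5) * step +
                 stats::runif(n_here, -0.3, 0.3) * step)
    rows[[ci]] <- data.frame(
      chrom = paste0("chr", ci), tss = pmax(tss, 2000),
      strand = sample(c("+", "-"), n_here, replace = TRUE),
      biotype = sample(c("protein_coding", "lincRNA"), n_here,
                       replace = TRUE, prob = c(0.9, 0.1)),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  ann <- ann[order(ann$chrom, ann$tss), ]
  ann$gene_id <- sprintf("G%04d", seq_len(nrow(ann)))
  ann$gene_name <- ann$gene_id
  rownames(ann) <- NULL
  ann[, c("gene_id", "gene_name", "chrom", "tss", "strand", "biotype")]
}

## plant enhancer positions, archetypes, background states, links and
## promoter states; the single source of ground truth
.plan_truth <- function(config, annotation) {
  set.seed(derive_seed(config$seed, 2))
  n_att <- ceiling(config$n_enhancers * 1.25)
  per_chr <- ceiling(n_att / config$n_chromosomes)
  step <- config$chrom_length / per_chr
  if (step < 3000) stop("infeasible enhancer spacing", call. = FALSE)
  rows <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    ch <- paste0("chr", ci)
    centre <- round((seq_len(per_chr) - 0.5) * step +
                    stats::runif(per_chr, -0.28, 0.28) * step)
    tss <- annotation$tss[annotation$chrom == ch]
    near_tss <- vapply(centre, function(p) any(abs(tss - p) < 2600),
                       logical(1))
    rows[[ci]] <- data.frame(chrom = ch, centre = centre[!near_tss],
                             stringsAsFactors = FALSE)
  }
  enh <- do.call(rbind, rows)
  if (nrow(enh) < config$n_enhancers)
    stop("could not place the requested number of enhancers",
         call. = FALSE)
  keep <- round(seq(1, nrow(enh), length.out = config$n_enhancers))
  enh <- enh[keep, , drop = FALSE]
  enh <- enh[order(enh$chrom, enh$centre), ]
  enh$enhancer_id <- sprintf("tenh_%04d", seq_len(nrow(enh)))
  rownames(enh) <- NULL

  arch <- .archetype_matrix(config$cell_types)
  if (config$null_structure) {
    enh$archetype <- 0L                     # constitutive active
    enh$background_state <- "active"
  } else {
    enh$archetype <- sample(nrow(arch), nrow(enh), replace = TRUE)
    enh$background_state <- sample(c("neutral", "primed", "repressed",
                                     "poised"),
                                   nrow(enh), replace = TRUE,
                                   prob = c(0.35, 0.3, 0.2, 0.15))
  }
  enh$baseline <- exp(stats::rnorm(nrow(enh), 0, 0.3))

  nd <- nearest_tss_distance(enh$chrom, enh$centre, annotation)
  enh$nearest_gene <- nd$gene_id
  enh$nearest_distance <- abs(nd$distance)

  links <- data.frame(enhancer_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (!config$null_structure && config$link_fraction > 0) {
    n_link <- round(config$link_fraction * nrow(enh))
    elig <- which(!is.na(enh$nearest_distance) &
                  enh$nearest_distance < 8e4)
    elig <- sample(elig)
    used_genes <- character()
    pick <- integer()
    for (i in elig) {
      g <- enh$nearest_gene[i]
      if (g %in% used_genes) next
      used_genes <- c(used_genes, g)
      pick <- c(pick, i)
      if (length(pick) == n_link) break
    }
    links <- data.frame(enhancer_id = enh$enhancer_id[pick],
                        gene_id = enh$nearest_gene[pick],
                        stringsAsFactors = FALSE)
  }

  ## long state table: planted state per enhancer x cell type
  states <- expand.grid(enhancer_id = enh$enhancer_id,
                        cell_type = config$cell_types,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  idx <- match(states$enhancer_id, enh$enhancer_id)
  if (config$null_structure) {
    states$state <- "active"
  } else {
    act <- arch[cbind(enh$archetype[idx],
                      match(states$cell_type, config$cell_types))]
    states$state <- ifelse(act == 1, "active",
                           enh$background_state[idx])
  }

  prom <- expand.grid(gene_id = annotation$gene_id,
                      cell_type = config$cell_types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prom$state <- if (config$null_structure) "active" else
    sample(c("active", "poised", "repressed", "neutral"),
           nrow(prom), replace = TRUE, prob = c(0.4, 0.15, 0.15, 0.3))

  list(enhancers = enh, states = states, links = links,
       promoter_states = prom, archetypes = arch)
}

.noisy_copy <- function(gr, drop_prob, shift_sd) {
  if (length(gr) == 0) return(gr)
  keep <- stats::runif(length(gr)) >= drop_prob
  gr <- gr[keep]
  if (length(gr) > 0 && shift_sd > 0) {
    shift <- round(stats::rnorm(length(gr), 0, shift_sd))
    gr <- GenomicRanges::shift(gr, shift)
    gr <- GenomicRanges::trim(gr)
  }
  gr
}

.peak_granges <- function(chrom, centre, halfwidth, q, prefix) {
  n <- length(centre)
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(pmax(centre - halfwidth, 1),
                           centre + halfwidth - 1))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("%s_%05d", prefix, seq_len(n)),
    score = as.integer(round(q * 10)),
    signalValue = q / 2, pValue = q + 2, qValue = q,
    peak = centre - GenomicRanges::start(gr))
  gr
}

#' Simulate per-mark, per-cell-type peak sets with replicate structure
#'
#' For every enhancer and cell type, peaks of H3K4me1/H3K27ac/H3K27me3 are
#' emitted according to the planted state's mark flags (width 800 bp,
#' summit at the enhancer centre), and an ATAC peak where the enhancer is
#' active; promoters emit H3K4me3/H3K27ac/H3K27me3 peaks per the planted
#' promoter state and an ATAC peak when active. The clean set doubles as
#' the pooled call; biological replicates and pooled pseudoreplicates are
#' noisy copies (dropout and coordinate jitter at \code{peak_noise}
#' rates), so with zero noise all five sets are identical.
#'
#' @param config a [sim_config()].
#' @param annotation from [simulate_annotation()].
#' @param truth planted truth; computed internally when NULL. Pass the
#'   truth returned by [simulate_tf_experiment()] to include its state
#'   overrides.
#' @return list with \code{peaks} (nested: mark, cell type, then pooled /
#'   rep1 / rep2 / pseudo1 / pseudo2 \code{GRanges}) and \code{truth}.
#' @export
simulate_elements_and_peaks <- function(config, annotation, truth = NULL) {
  truth <- truth %||% .plan_truth(config, annotation)
  set.seed(derive_seed(config$seed, 3))
  enh <- truth$enhancers
  marks_e <- c("H3K4me1", "H3K27ac", "H3K27me3")
  marks_p <- c("H3K4me3", "H3K27ac", "H3K27me3")
  peaks <- list()
  for (ct in config$cell_types) {
    st_e <- truth$states$state[truth$states$cell_type == ct]
    flag_e <- do.call(rbind, .enh_state_flags[st_e])
    st_p <- truth$promoter_states$state[
      truth$promoter_states$cell_type == ct]
    flag_p <- do.call(rbind, .prom_state_flags[st_p])
    for (mk in unique(c("ATAC", marks_e, marks_p))) {
      on_e <- if (mk == "ATAC") st_e == "active"
              else if (mk %in% marks_e) flag_e[, match(mk, marks_e)] == 1
              else rep(FALSE, nrow(enh))
      on_p <- if (mk == "ATAC") st_p == "active"
              else if (mk %in% marks_p) flag_p[, match(mk, marks_p)] == 1
              else rep(FALSE, length(st_p))
      q_e <- stats::runif(sum(on_e), 6, 40)
      q_p <- stats::runif(sum(on_p), 6, 40)
      hw <- if (mk == "ATAC") 400 else 400
      g_e <- .peak_granges(enh$chrom[on_e], enh$centre[on_e], hw, q_e,
                           paste0(mk, "_", ct, "_e"))
      g_p <- .peak_granges(annotation$chrom[on_p],
                           annotation$tss[on_p],
                           if (mk == "ATAC") 400 else 800, q_p,
                           paste0(mk, "_", ct, "_p"))
      pooled <- GenomicRanges::sort(suppressWarnings(c(g_e, g_p)),
                                    ignore.strand = TRUE)
      sets <- list(pooled = pooled)
      for (nm in c("rep1", "rep2", "pseudo1", "pseudo2"))
        sets[[nm]] <- .noisy_copy(pooled, config$peak_noise$drop_prob,
                                  config$peak_noise$shift_sd)
      peaks[[mk]][[ct]] <- sets
    }
  }
  list(peaks = peaks, truth = truth)
}

.nb_draw <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate fragment counts at enhancers and gene expression
#'
#' Chromatin counts follow NB(mean = depth_j x baseline_e x
#' state mean, dispersion); expression of genes with a planted link
#' follows the linked enhancer's activity profile (8^link_strength fold
#' between active and inactive cell types), unlinked genes get an
#' independent random activity profile. Count matrices are returned as
#' \code{SummarizedExperiment}s keyed by the planted enhancer ids.
#'
#' @param config a [sim_config()].
#' @param truth planted truth (from [simulate_elements_and_peaks()] or
#'   [simulate_tf_experiment()]).
#' @param annotation from [simulate_annotation()].
#' @return list: \code{samples} (chromatin sample sheet), \code{mark_se}
#'   (named list of normalized \code{SummarizedExperiment}s, one per
#'   mark), \code{expression_counts} and \code{expression} (genes x 12
#'   log2-normalized matrix), \code{rna_samples}.
#' @export
simulate_signal <- function(config, truth, annotation) {
  set.seed(derive_seed(config$seed, 4))
  enh <- truth$enhancers
  cts <- config$cell_types
  reps <- seq_len(config$replicates)
  samples <- expand.grid(replicate = reps, cell_type = cts,
                         KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)[, c(2, 1)]
  state_wide <- matrix(truth$states$state[
    order(match(truth$states$cell_type, cts),
          match(truth$states$enhancer_id, enh$enhancer_id))],
    nrow = nrow(enh), dimnames = list(enh$enhancer_id, cts))

  regions <- GenomicRanges::GRanges(enh$chrom,
               IRanges::IRanges(pmax(enh$centre - 500, 1),
                                enh$centre + 499))
  regions$element_id <- enh$enhancer_id
  regions$summit <- enh$centre

  ## graded latent activity per enhancer x cell type, shared between the
  ## enhancer chromatin signal and any linked gene's expression; flat in
  ## the null channel
  latent <- matrix(1, nrow(enh), length(cts),
                   dimnames = list(enh$enhancer_id, cts))
  if (!config$null_structure)
    latent[] <- exp(stats::rnorm(length(latent), 0, 0.75))

  mark_se <- list()
  for (mk in names(config$mean_by_state)) {
    depth_f <- stats::runif(nrow(samples), 0.8, 1.25)
    mu_state <- config$mean_by_state[[mk]]
    mu <- matrix(0, nrow(enh), nrow(samples))
    for (j in seq_len(nrow(samples))) {
      st <- state_wide[, samples$cell_type[j]]
      mu[, j] <- depth_f[j] * enh$baseline * mu_state[st] *
        latent[, samples$cell_type[j]]
    }
    counts <- matrix(.nb_draw(mu, config$nb_dispersion), nrow(enh))
    smp <- data.frame(
      sample_id = sprintf("%s_%s_r%d", mk, samples$cell_type,
                          samples$replicate),
      cell_type = samples$cell_type, replicate = samples$replicate,
      mark = mk, library_depth = round(1e6 * depth_f),
      stringsAsFactors = FALSE)
    se <- count_experiment(counts, smp, regions)
    mark_se[[mk]] <- normalize_counts(se)
  }

  ## expression: latent activity per gene x cell type
  act <- matrix(0, nrow(annotation), length(cts),
                dimnames = list(annotation$gene_id, cts))
  if (config$null_structure) {
    act[] <- 1
  } else {
    arch <- truth$archetypes
    gene_arch <- sample(nrow(arch), nrow(annotation), replace = TRUE)
    act[] <- arch[gene_arch, ]
    if (nrow(truth$links)) {
      ei <- match(truth$links$enhancer_id, enh$enhancer_id)
      gi <- match(truth$links$gene_id, annotation$gene_id)
      act[gi, ] <- (state_wide[ei, , drop = FALSE] == "active") * 1
    }
  }
  ## linked genes inherit the linked enhancer's graded latent activity
  gene_latent <- matrix(1, nrow(annotation), length(cts),
                        dimnames = list(annotation$gene_id, cts))
  if (!config$null_structure && nrow(truth$links)) {
    ei <- match(truth$links$enhancer_id, enh$enhancer_id)
    gi <- match(truth$links$gene_id, annotation$gene_id)
    gene_latent[gi, ] <- latent[ei, , drop = FALSE]
  }
  gene_base <- exp(stats::rnorm(nrow(annotation), 0, 0.3))
  depth_r <- stats::runif(nrow(samples), 0.8, 1.25)
  mu_expr <- matrix(0, nrow(annotation), nrow(samples))
  for (j in seq_len(nrow(samples)))
    mu_expr[, j] <- depth_r[j] * gene_base * 20 *
      8^(config$link_strength * act[, samples$cell_type[j]]) *
      gene_latent[, samples$cell_type[j]]^config$link_strength
  expr_counts <- matrix(.nb_draw(mu_expr, config$expr_dispersion),
                        nrow(annotation))
  rna <- data.frame(
    sample_id = sprintf("RNA_%s_r%d", samples$cell_type,
                        samples$replicate),
    cell_type = samples$cell_type, replicate = samples$replicate,
    mark = "RNA", library_depth = round(1e6 * depth_r),
    stringsAsFactors = FALSE)
  sf <- depth_r / geometric_mean(depth_r)
  expr_norm <- log2(sweep(expr_counts, 2, sf, "/") + 1)
  dimnames(expr_counts) <- dimnames(expr_norm) <-
    list(annotation$gene_id, rna$sample_id)

  list(samples = samples, mark_se = mark_se,
       expression_counts = expr_counts, expression = expr_norm,
       rna_samples = rna)
}

#' Simulate fragment interval files reproducing given counts
#'
#' Emits, per sample, one fragment interval per count unit placed inside
#' its region, so that '-O'-style counting on disjoint regions recovers
#' the count matrix exactly. Intended for small configurations that
#' exercise the counting path.
#'
#' @param se a \code{SummarizedExperiment} with a counts assay and
#'   disjoint row ranges.
#' @param fragment_width emitted fragment width in bp (clipped to the
#'   region).
#' @return named list of \code{GRanges}, one per sample.
#' @export
simulate_fragments <- function(se, fragment_width = 200) {
  counts <- SummarizedExperiment::assay(se, "counts")
  rr <- SummarizedExperiment::rowRanges(se)
  lapply(stats::setNames(seq_len(ncol(counts)), colnames(counts)),
         function(j) {
    n <- counts[, j]
    idx <- rep(seq_along(n), n)
    w <- pmin(fragment_width, GenomicRanges::width(rr)[idx])
    GenomicRanges::GRanges(GenomicRanges::seqnames(rr)[idx],
      IRanges::IRanges(GenomicRanges::start(rr)[idx], width = w))
  })
}

#' Simulate the TF trio experiment: peaks, knockouts, planted targets
#'
#' Plants direct up and down targets for each of the seven cooperativity
#' classes of the TF trio. An up target gets a peak of every class member
#' at a nearby enhancer whose state in the context cell type is forced to
#' active; a down target's enhancer is forced non-active. Knockout
#' differential-expression tables give planted targets the configured
#' log2 fold change (negative for up targets, positive for down) in every
#' member TF's knockout, plus optional noise. Background peaks are placed
#' away from all target genes. Because target planting overrides enhancer
#' states, the returned (updated) truth must be passed on to
#' [simulate_elements_and_peaks()] and [simulate_signal()].
#'
#' @param config a [sim_config()].
#' @param annotation from [simulate_annotation()].
#' @param truth planted truth; computed internally when NULL.
#' @return list: \code{tf_peaks} (named list of \code{GRanges} per TF),
#'   \code{ko_tables} (named list of data.frames gene_id / log2_fc /
#'   adj_p), \code{targets} (planted table: gene_id, class, direction,
#'   enhancer_id), \code{truth} (updated).
#' @export
simulate_tf_experiment <- function(config, annotation, truth = NULL) {
  truth <- truth %||% .plan_truth(config, annotation)
  set.seed(derive_seed(config$seed, 5))
  tfc <- config$tf_config
  tfs <- tfc$tfs
  context <- tfc$context
  enh <- truth$enhancers
  arch <- truth$archetypes
  ctx_col <- match(context, config$cell_types)
  active_arch <- which(arch[, ctx_col] == 1)
  inactive_arch <- which(arch[, ctx_col] == 0)

  classes <- unlist(lapply(seq_along(tfs), function(k)
    apply(utils::combn(tfs, k), 2, paste, collapse = "+")))

  ## candidate enhancers: close to a gene, not linked (links tie
  ## expression, keep channels separate)
  cand <- which(!is.na(enh$nearest_distance) &
                enh$nearest_distance < 5e4 &
                !(enh$enhancer_id %in% truth$links$enhancer_id) &
                !(enh$nearest_gene %in% truth$links$gene_id))
  cand <- sample(cand)
  used_genes <- character()
  targets <- list()
  peaks <- stats::setNames(vector("list", length(tfs)), tfs)
  take <- function(n) {
    out <- integer()
    while (length(out) < n && length(cand) > 0) {
      i <- cand[1]; cand <<- cand[-1]
      if (enh$nearest_gene[i] %in% used_genes) next
      used_genes <<- c(used_genes, enh$nearest_gene[i])
      out <- c(out, i)
    }
    if (length(out) < n)
      stop("not enough candidate enhancers for TF targets",
           call. = FALSE)
    out
  }
  for (cl in classes) {
    members <- strsplit(cl, "+", fixed = TRUE)[[1]]
    for (dir in c("up", "down")) {
      n_t <- if (dir == "up") tfc$n_up_per_class else
        tfc$n_down_per_class
      if (n_t == 0) next
      idx <- take(n_t)
      for (i in idx) {
        ## force the context state of the supporting enhancer
        if (dir == "up") {
          enh$archetype[i] <- active_arch[1]
          new_state <- "active"
        } else {
          enh$archetype[i] <- inactive_arch[1]
          enh$background_state[i] <- "repressed"
          new_state <- "repressed"
        }
        sel <- truth$states$enhancer_id == enh$enhancer_id[i]
        acts <- arch[enh$archetype[i],
                     match(truth$states$cell_type[sel],
                           config$cell_types)]
        truth$states$state[sel] <- ifelse(acts == 1, "active",
                                          enh$background_state[i])
        for (tf in members)
          peaks[[tf]] <- c(peaks[[tf]],
                           list(data.frame(chrom = enh$chrom[i],
                                           centre = enh$centre[i])))
        targets[[length(targets) + 1]] <- data.frame(
          gene_id = enh$nearest_gene[i], class = cl, direction = dir,
          enhancer_id = enh$enhancer_id[i], stringsAsFactors = FALSE)
      }
    }
  }
  targets <- do.call(rbind, targets)
  truth$enhancers <- enh

  ## background peaks: far (>1.2 * window) from every target gene TSS
  tgt_tss <- annotation$tss[match(targets$gene_id, annotation$gene_id)]
  tgt_chr <- annotation$chrom[match(targets$gene_id, annotation$gene_id)]
  far_pool <- which(!(enh$enhancer_id %in% targets$enhancer_id))
  is_far <- vapply(far_pool, function(i) {
    same <- tgt_chr == enh$chrom[i]
    !any(same & abs(tgt_tss - enh$centre[i]) <= 1.2e5)
  }, logical(1))
  far_pool <- far_pool[is_far]
  for (tf in tfs) {
    bg <- sample(far_pool, min(tfc$background_peaks, length(far_pool)))
    peaks[[tf]] <- c(peaks[[tf]],
                     list(data.frame(chrom = enh$chrom[bg],
                                     centre = enh$centre[bg])))
    df <- do.call(rbind, peaks[[tf]])
    q <- stats::runif(nrow(df), 6, 40)
    peaks[[tf]] <- .peak_granges(df$chrom, df$centre, 150, q,
                                 paste0(tf, "_pk"))
  }

  ko_tables <- list()
  for (tf in tfs) {
    lfc <- stats::rnorm(nrow(annotation), 0, tfc$ko_noise_sd)
    adjp <- rep(1, nrow(annotation))
    mine <- targets[vapply(strsplit(targets$class, "+", fixed = TRUE),
                           function(m) tf %in% m, logical(1)), ,
                    drop = FALSE]
    gi <- match(mine$gene_id, annotation$gene_id)
    lfc[gi] <- ifelse(mine$direction == "up", -tfc$ko_lfc, tfc$ko_lfc) +
      stats::rnorm(length(gi), 0, tfc$ko_noise_sd)
    adjp[gi] <- 1e-6
    ko_tables[[tf]] <- data.frame(gene_id = annotation$gene_id,
                                  log2_fc = lfc, adj_p = adjp,
                                  stringsAsFactors = FALSE)
  }
  list(tf_peaks = peaks, ko_tables = ko_tables, targets = targets,
       truth = truth)
}

#' Simulate a complete in-silico study
#'
#' Orchestrates annotation, truth planting, the TF experiment (whose state
#' overrides feed back into the truth), peak emission and signal
#' generation. Identical config and seed give identical output.
#'
#' @param config a [sim_config()].
#' @param tf include the TF channel (default TRUE).
#' @return list: config, annotation, truth, peaks, signal, tf.
#' @export
simulate_study <- function(config = sim_config(), tf = TRUE) {
  annotation <- simulate_annotation(config)
  truth <- .plan_truth(config, annotation)
  tf_out <- NULL
  if (tf) {
    tf_out <- simulate_tf_experiment(config, annotation, truth)
    truth <- tf_out$truth
  }
  pk <- simulate_elements_and_peaks(config, annotation, truth)
  sig <- simulate_signal(config, pk$truth, annotation)
  list(config = config, annotation = annotation, truth = pk$truth,
       peaks = pk$peaks, signal = sig, tf = tf_out)
}
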