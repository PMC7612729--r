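#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates the stages simulate -> repro -> elements -> classify ->
#' counts -> diff -> dynamic -> cluster -> link -> tf, writing every
#' output as plain text (narrowPeak / BED / TSV) under \code{outdir} and
#' returning a manifest of output files with content hashes. Stages can
#' be rerun selectively: a requested stage whose upstream outputs are
#' absent from \code{outdir} raises an error naming the stage to run
#' first. No stage mutates its inputs; rerunning with an identical config
#' reproduces identical hashes.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param stages subset of stages to run, in any order; dependencies are
#'   enforced.
#' @param contrasts list of cell-type pairs for differential signal;
#'   default consecutive pairs along \code{config$cell_types}.
#' @param k_clusters k for dynamic-enhancer clustering (default 9).
#' @return invisibly, a data.frame manifest (file, md5) also written to
#'   \code{manifest.tsv}.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = c("simulate", "repro", "elements",
                                    "classify", "counts", "diff",
                                    "dynamic", "cluster", "link", "tf"),
                         contrasts = NULL, k_clusters = 9) {
  all_stages <- c("simulate", "repro", "elements", "classify", "counts",
                  "diff", "dynamic", "cluster", "link", "tf")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cts <- config$cell_types
  contrasts <- contrasts %||% lapply(seq_len(length(cts) - 1),
                                     function(i) cts[c(i, i + 1)])
  written <- character()
  emit <- function(path) written <<- c(written, path)
  p <- function(...) file.path(outdir, ...)
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("missing ", path, "; run stage '", stage, "' first",
           call. = FALSE)
    path
  }
  marks <- c("ATAC", "H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3")

  if ("simulate" %in% stages) {
    study <- simulate_study(config)
    yaml::write_yaml(config[setdiff(names(config), "mean_by_state")],
                     p("config.yaml"))
    emit(p("config.yaml"))
    write_gene_annotation(study$annotation, p("annotation.tsv"))
    emit(p("annotation.tsv"))
    dir.create(p("truth"), showWarnings = FALSE)
    for (nm in c("enhancers", "states", "links", "promoter_states")) {
      utils::write.table(study$truth[[nm]], p("truth", paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p("truth", paste0(nm, ".tsv")))
    }
    dir.create(p("peaks"), showWarnings = FALSE)
    for (mk in names(study$peaks)) for (ct in names(study$peaks[[mk]]))
      for (set in names(study$peaks[[mk]][[ct]])) {
        f <- p("peaks", sprintf("%s_%s_%s.narrowPeak", mk, ct, set))
        write_narrowpeak(study$peaks[[mk]][[ct]][[set]], f)
        emit(f)
      }
    dir.create(p("counts"), showWarnings = FALSE)
    for (mk in names(study$signal$mark_se)) {
      se <- study$signal$mark_se[[mk]]
      cm <- SummarizedExperiment::assay(se, "counts")
      rr <- SummarizedExperiment::rowRanges(se)
      df <- data.frame(element_id = rownames(cm),
                       chrom = as.character(GenomicRanges::seqnames(rr)),
                       start = GenomicRanges::start(rr) - 1L,
                       end = GenomicRanges::end(rr),
                       summit = rr$summit, cm, check.names = FALSE)
      utils::write.table(df, p("counts", paste0(mk, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(p("counts", paste0(mk, ".tsv")))
      sm <- as.data.frame(SummarizedExperiment::colData(se))
      utils::write.table(sm, p("counts", paste0(mk, "_samples.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p("counts", paste0(mk, "_samples.tsv")))
    }
    expr <- data.frame(gene_id = rownames(study$signal$expression),
                       study$signal$expression, check.names = FALSE)
    utils::write.table(expr, p("expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(p("expression.tsv"))
    if (!is.null(study$tf)) {
      dir.create(p("tf"), showWarnings = FALSE)
      for (tf in names(study$tf$tf_peaks)) {
        write_narrowpeak(study$tf$tf_peaks[[tf]],
                         p("tf", paste0(tf, ".narrowPeak")))
        emit(p("tf", paste0(tf, ".narrowPeak")))
        utils::write.table(study$tf$ko_tables[[tf]],
                           p("tf", paste0(tf, "_ko.tsv")), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit(p("tf", paste0(tf, "_ko.tsv")))
      }
      utils::write.table(study$tf$targets, p("tf", "planted_targets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p("tf", "planted_targets.tsv"))
    }
  }

  read_peak_sets <- function(mk, ct) {
    lapply(stats::setNames(nm = c("pooled", "rep1", "rep2", "pseudo1",
                                  "pseudo2")),
           function(set) read_narrowpeak(need(
             p("peaks", sprintf("%s_%s_%s.narrowPeak", mk, ct, set)),
             "simulate")))
  }

  if ("repro" %in% stages) {
    dir.create(p("repro"), showWarnings = FALSE)
    for (mk in marks) for (ct in cts) {
      sets <- read_peak_sets(mk, ct)
      assay_kind <- if (mk == "ATAC") "ATAC" else "histone"
      kept <- retain_reproducible(sets$pooled, sets$rep1, sets$rep2,
                                  sets$pseudo1, sets$pseudo2,
                                  assay = assay_kind)
      kept <- filter_by_qscore(kept, if (mk == "ATAC") 4 else 3)
      f <- p("repro", sprintf("%s_%s.narrowPeak", mk, ct))
      write_narrowpeak(kept, f)
      emit(f)
    }
  }

  repro_peaks <- function(mk, ct)
    read_narrowpeak(need(p("repro", sprintf("%s_%s.narrowPeak", mk, ct)),
                         "repro"))

  if ("elements" %in% stages) {
    ann <- read_gene_annotation(need(p("annotation.tsv"), "simulate"))
    promoters <- build_promoter_set(ann)
    atac <- lapply(stats::setNames(nm = cts), repro_peaks, mk = "ATAC")
    enhancers <- build_enhancer_set(atac, promoters)
    dir.create(p("elements"), showWarnings = FALSE)
    write_bed(.as_bed6(promoters), p("elements", "promoters.bed"),
              extra_cols = c("associated_gene", "tss"))
    emit(p("elements", "promoters.bed"))
    write_bed(.as_bed6(enhancers), p("elements", "enhancers.bed"),
              extra_cols = c("summit", "summit_q"))
    emit(p("elements", "enhancers.bed"))
  }

  read_elements <- function(file, stage = "elements") {
    df <- utils::read.table(need(p("elements", file), stage), sep = "\t",
                            stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df[[1]],
            IRanges::IRanges(df[[2]] + 1L, df[[3]]))
    gr$element_id <- df[[4]]
    if (file == "promoters.bed") {
      gr$kind <- "promoter"; gr$associated_gene <- df[[7]]
      gr$tss <- df[[8]]
    } else {
      gr$kind <- "enhancer"; gr$summit <- df[[7]]
      gr$summit_q <- df[[8]]
    }
    gr
  }

  if ("classify" %in% stages) {
    enhancers <- read_elements("enhancers.bed")
    promoters <- read_elements("promoters.bed")
    mark_peaks <- list()
    for (mk in setdiff(marks, "ATAC"))
      for (ct in cts) mark_peaks[[mk]][[ct]] <- repro_peaks(mk, ct)
    tt <- read_truth_table()
    enh_states <- classify_elements(enhancers, mark_peaks, cts,
                                    "enhancer", truth_table = tt)
    prom_states <- classify_elements(promoters, mark_peaks, cts,
                                     "promoter", truth_table = tt)
    utils::write.table(enh_states, p("enhancer_states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(p("enhancer_states.tsv"))
    utils::write.table(prom_states, p("promoter_states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(p("promoter_states.tsv"))
    trans <- state_transitions(enh_states, cts, states = ENHANCER_STATES)
    dir.create(p("transitions"), showWarnings = FALSE)
    for (nm in names(trans)) {
      f <- p("transitions", paste0(gsub("->", "_to_", nm), ".tsv"))
      utils::write.table(as.data.frame.matrix(trans[[nm]]), f,
                         sep = "\t", quote = FALSE)
      emit(f)
    }
  }

  load_counts <- function(mk) {
    df <- utils::read.table(need(p("counts", paste0(mk, ".tsv")),
                                 "simulate"),
                            sep = "\t", header = TRUE, check.names = FALSE)
    meta <- c("element_id", "chrom", "start", "end", "summit")
    cm <- as.matrix(df[, setdiff(names(df), meta)])
    rownames(cm) <- df$element_id
    rr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(df$start + 1L, df$end))
    rr$element_id <- df$element_id
    rr$summit <- df$summit
    sm <- utils::read.table(p("counts", paste0(mk, "_samples.tsv")),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    normalize_counts(count_experiment(cm, sm, rr))
  }

  if ("counts" %in% stages) {
    ## normalized signal at built enhancers: counts are keyed by the
    ## simulator's element ids; map them onto built elements by identical
    ## summit coordinates
    enhancers <- read_elements("enhancers.bed")
    se <- load_counts("H3K27ac")
    norm <- SummarizedExperiment::assay(se, "normalized")
    key_built <- paste(GenomicRanges::seqnames(enhancers),
                       enhancers$summit)
    rr <- SummarizedExperiment::rowRanges(se)
    key_sim <- paste(GenomicRanges::seqnames(rr), rr$summit)
    idx <- match(key_built, key_sim)
    matched <- norm[idx[!is.na(idx)], , drop = FALSE]
    rownames(matched) <- enhancers$element_id[!is.na(idx)]
    df <- data.frame(element_id = rownames(matched), matched,
                     check.names = FALSE)
    utils::write.table(df, p("enhancer_H3K27ac_normalized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p("enhancer_H3K27ac_normalized.tsv"))
  }

  if ("diff" %in% stages) {
    se <- load_counts("H3K27ac")
    dir.create(p("diff"), showWarnings = FALSE)
    for (cp in contrasts) {
      d <- differential_signal(se, cp)
      f <- p("diff", sprintf("H3K27ac_%s_vs_%s.tsv", cp[1], cp[2]))
      utils::write.table(d, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(f)
    }
  }

  read_diffs <- function() lapply(contrasts, function(cp)
    utils::read.table(need(p("diff", sprintf("H3K27ac_%s_vs_%s.tsv",
                                             cp[1], cp[2])), "diff"),
                      sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))

  sim_to_built <- function(ids) {
    ## translate simulator element ids to built element ids via summits
    enhancers <- read_elements("enhancers.bed")
    se <- load_counts("H3K27ac")
    rr <- SummarizedExperiment::rowRanges(se)
    key_sim <- paste(GenomicRanges::seqnames(rr), rr$summit)
    key_built <- paste(GenomicRanges::seqnames(enhancers),
                       enhancers$summit)
    stats::setNames(enhancers$element_id[match(key_sim, key_built)],
                    rr$element_id)[ids]
  }

  if ("dynamic" %in% stages) {
    states <- utils::read.table(need(p("enhancer_states.tsv"),
                                     "classify"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    diffs <- read_diffs()
    ## differential results are keyed by simulator ids; translate
    diffs <- lapply(diffs, function(d) {
      d$region_id <- unname(sim_to_built(d$region_id)); d
    })
    dyn <- select_dynamic_elements(states, diffs, "active", cts)
    writeLines(dyn, p("dynamic_enhancers.txt"))
    emit(p("dynamic_enhancers.txt"))
  }

  if ("cluster" %in% stages) {
    dyn <- readLines(need(p("dynamic_enhancers.txt"), "dynamic"))
    df <- utils::read.table(need(p("enhancer_H3K27ac_normalized.tsv"),
                                 "counts"),
                            sep = "\t", header = TRUE,
                            check.names = FALSE)
    norm <- as.matrix(df[, -1]); rownames(norm) <- df[[1]]
    dyn <- intersect(dyn, rownames(norm))
    sm <- utils::read.table(p("counts", "H3K27ac_samples.tsv"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    se <- count_experiment(round(2^norm - 1), sm)
    SummarizedExperiment::assays(se)$normalized <- norm
    cl <- cluster_dynamic(se, dyn, k = min(k_clusters, length(dyn)),
                          seed = derive_seed(config$seed, 9))
    utils::write.table(
      data.frame(element_id = names(cl$labels), cluster = cl$labels),
      p("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p("clusters.tsv"))
    utils::write.table(round(cl$centers, 6), p("cluster_centers.tsv"),
                       sep = "\t", quote = FALSE)
    emit(p("cluster_centers.tsv"))
  }

  if ("link" %in% stages) {
    enhancers <- read_elements("enhancers.bed")
    ann <- read_gene_annotation(need(p("annotation.tsv"), "simulate"))
    df <- utils::read.table(need(p("enhancer_H3K27ac_normalized.tsv"),
                                 "counts"),
                            sep = "\t", header = TRUE,
                            check.names = FALSE)
    sig <- as.matrix(df[, -1]); rownames(sig) <- df[[1]]
    ex <- utils::read.table(need(p("expression.tsv"), "simulate"),
                            sep = "\t", header = TRUE,
                            check.names = FALSE)
    expr <- as.matrix(ex[, -1]); rownames(expr) <- ex[[1]]
    links <- link_enhancers_to_genes(sig, expr, enhancers, ann)
    utils::write.table(links, p("links.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(p("links.tsv"))
  }

  if ("tf" %in% stages) {
    tfs <- config$tf_config$tfs
    ann <- read_gene_annotation(need(p("annotation.tsv"), "simulate"))
    tf_peaks <- lapply(stats::setNames(nm = tfs), function(tf)
      read_narrowpeak(need(p("tf", paste0(tf, ".narrowPeak")),
                           "simulate")))
    ko <- lapply(stats::setNames(nm = tfs), function(tf)
      utils::read.table(need(p("tf", paste0(tf, "_ko.tsv")), "simulate"),
                        sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE))
    classes <- intersect_tf_peaks(tf_peaks)
    utils::write.table(
      data.frame(class = names(classes$class_counts),
                 count = as.integer(classes$class_counts)),
      p("tf_class_counts.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    emit(p("tf_class_counts.tsv"))
    utils::write.table(classes$pairwise, p("tf_pairwise_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p("tf_pairwise_overlap.tsv"))
    enhancers <- read_elements("enhancers.bed")
    promoters <- read_elements("promoters.bed")
    states <- rbind(
      utils::read.table(need(p("enhancer_states.tsv"), "classify"),
                        sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)[
        , c("element_id", "cell_type", "state")],
      utils::read.table(need(p("promoter_states.tsv"), "classify"),
                        sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)[
        , c("element_id", "cell_type", "state")])
    elements <- suppressWarnings(c(
      enhancers[, c("element_id", "kind")],
      promoters[, c("element_id", "kind")]))
    targets <- call_direct_targets(classes, ko, elements, states,
                                   config$tf_config$context, ann)
    utils::write.table(targets, p("direct_targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(p("direct_targets.tsv"))
  }

  rel <- substring(written, nchar(outdir) + 2)
  manifest <- data.frame(file = rel, md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

.as_bed6 <- function(gr) {
  gr$name <- gr$element_id
  gr$score <- 0L
  gr
}
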