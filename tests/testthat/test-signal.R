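test_that("analysis bins keep exactly the tiles overlapping a peak", {
  sizes <- c(chr1 = 10000)
  # peak 1500-1700 (BED) sits in tile 1000-2000 only
  b1 <- make_analysis_bins(gr_bed("chr1", 1500, 1700), sizes)
  expect_equal(length(b1), 1L)
  expect_equal(start(b1) - 1L, 1000)
  # peak 900-2100 spans three tiles
  b3 <- make_analysis_bins(gr_bed("chr1", 900, 2100), sizes)
  expect_equal(length(b3), 3L)

  set.seed(71)
  peaks <- random_intervals(100, max_pos = 9000, max_len = 800,
                            chroms = "chr1")
  bins <- make_analysis_bins(peaks, sizes)
  cov <- base_coverage_oracle(peaks)$chr1
  want <- vapply(0:9, function(k)
    any(cov[(k * 1000 + 1):min((k + 1) * 1000, 10000)]), logical(1))
  expect_equal(start(bins) - 1L, (0:9)[want] * 1000)
})

test_that("fragment counting follows multi-overlap ('-O') semantics", {
  regions <- gr_bed("chr1", c(0, 1000), c(1000, 2000),
                    element_id = c("r1", "r2"))
  samples <- data.frame(sample_id = "s1")
  # fragment spanning the boundary increments both regions
  frag <- list(s1 = gr_bed("chr1", 900, 1100))
  se <- count_fragments(frag, regions, samples)
  expect_equal(unname(SummarizedExperiment::assay(se)[, 1]), c(1L, 1L))
  # non-overlapping fragment increments nothing
  se0 <- count_fragments(list(s1 = gr_bed("chr1", 5000, 5100)),
                         regions, samples)
  expect_equal(sum(SummarizedExperiment::assay(se0)), 0L)

  set.seed(72)
  frs <- random_intervals(1000, max_pos = 3000, max_len = 300,
                          chroms = "chr1")
  se2 <- count_fragments(list(s1 = frs), regions, samples)
  want <- vapply(seq_along(regions), function(i)
    sum(start(frs) <= end(regions)[i] & end(frs) >= start(regions)[i]),
    integer(1))
  expect_equal(unname(SummarizedExperiment::assay(se2)[, 1]), want)
})

test_that("depth normalization matches the closed form and preserves ranks", {
  counts <- matrix(c(100L, 0L, 50L, 100L, 3L, 50L, 100L, 7L, 50L), nrow = 3,
                   dimnames = list(c("r1", "r2", "r3"), NULL))
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        library_depth = c(1e6, 2e6, 4e6))
  se <- normalize_counts(count_experiment(counts, samples))
  sf <- c(1e6, 2e6, 4e6) / 2e6   # geometric mean is 2M
  expect_equal(unname(SummarizedExperiment::colData(se)$size_factor), sf)
  norm <- SummarizedExperiment::assay(se, "normalized")
  expect_equal(unname(norm["r1", ]), log2(100 / sf + 1))
  expect_equal(unname(norm["r2", 1]), 0)   # count 0 -> 0 for any factor
  # equal depths: identity scaling
  se2 <- normalize_counts(count_experiment(
    counts, data.frame(sample_id = c("a", "b", "c"),
                       library_depth = rep(1e6, 3))))
  expect_equal(unname(SummarizedExperiment::assay(se2, "normalized")),
               unname(log2(counts + 1)))
  # rank preservation within sample
  expect_equal(order(norm[, 2]), order(counts[, 2]))
  expect_error(normalize_counts(count_experiment(
    counts, data.frame(sample_id = c("a", "b", "c"),
                       library_depth = c(0, 1, 1)))), "zero-depth")
})

nb_experiment <- function(mu_a, mu_b, n_regions, dispersion = 0.05,
                          seed = 1) {
  set.seed(seed)
  cnt <- cbind(
    matrix(rnbinom(2 * n_regions, mu = mu_a, size = 1 / dispersion),
           n_regions),
    matrix(rnbinom(2 * n_regions, mu = mu_b, size = 1 / dispersion),
           n_regions))
  rownames(cnt) <- sprintf("r%04d", seq_len(n_regions))
  samples <- data.frame(
    sample_id = c("A1", "A2", "B1", "B2"),
    cell_type = c("A", "A", "B", "B"),
    library_depth = rep(1e6, 4))
  normalize_counts(count_experiment(cnt, samples))
}

test_that("differential signal: nulls are flat, planted 8-fold changes are dynamic", {
  cnt <- matrix(200L, nrow = 5, ncol = 4,
                dimnames = list(sprintf("r%d", 1:5), NULL))
  samples <- data.frame(sample_id = c("A1", "A2", "B1", "B2"),
                        cell_type = c("A", "A", "B", "B"),
                        library_depth = rep(1e6, 4))
  se <- normalize_counts(count_experiment(cnt, samples))
  d <- differential_signal(se, c("A", "B"))
  expect_true(all(d$log2_fc == 0))
  expect_false(any(d$dynamic))

  se2 <- nb_experiment(mu_a = 25, mu_b = 200, n_regions = 50, seed = 5)
  d2 <- differential_signal(se2, c("A", "B"))
  expect_gt(mean(d2$dynamic), 0.9)
  expect_gt(median(d2$log2_fc), 2)
})

test_that("differential signal is antisymmetric and BH-monotone", {
  se <- nb_experiment(mu_a = 60, mu_b = 90, n_regions = 200, seed = 9)
  ab <- differential_signal(se, c("A", "B"))
  ba <- differential_signal(se, c("B", "A"))
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$p_value, ba$p_value)
  ord <- order(ab$p_value)
  expect_true(all(diff(ab$adj_p_value[ord]) >= -1e-12))
  expect_gte(min(ab$adj_p_value), min(ab$p_value))
  expect_error(differential_signal(se, c("A", "missing")), "replicates")
})

test_that("dynamic-element selection applies the any/all state logic", {
  cts <- c("c1", "c2", "c3")
  asg <- expand.grid(element_id = c("always", "once", "never"),
                     cell_type = cts, stringsAsFactors = FALSE)
  asg$state <- "neutral"
  asg$state[asg$element_id == "always"] <- "active"
  asg$state[asg$element_id == "once" & asg$cell_type == "c2"] <- "active"
  diffs <- list(data.frame(region_id = c("always", "once", "never"),
                           dynamic = c(TRUE, TRUE, TRUE)))
  got <- select_dynamic_elements(asg, diffs, "active", cts)
  expect_equal(got, "once")   # constitutive excluded, never-active excluded
  keep_const <- select_dynamic_elements(asg, diffs, "active", cts,
                                        exclude_constitutive = FALSE)
  expect_equal(keep_const, c("always", "once"))
  # not dynamic anywhere -> excluded
  no_dyn <- list(data.frame(region_id = "once", dynamic = FALSE))
  expect_equal(length(select_dynamic_elements(asg, no_dyn, "active", cts)),
               0L)
})

test_that("k-means on z-profiles recovers planted archetypes and is seeded", {
  set.seed(81)
  prof <- rbind(matrix(rep(c(5, 5, 0, 0), each = 30), 30),
                matrix(rep(c(0, 0, 5, 5), each = 30), 30))
  cnt <- round(2^(prof + matrix(rnorm(240, 0, 0.1), 60)) - 1)
  cnt[cnt < 0] <- 0
  rownames(cnt) <- sprintf("e%02d", 1:60)
  samples <- data.frame(sample_id = sprintf("s%d", 1:4),
                        library_depth = rep(1e6, 4))
  se <- normalize_counts(count_experiment(cnt, samples))
  cl <- cluster_dynamic(se, rownames(cnt), k = 2, seed = 7)
  truth <- rep(1:2, each = 30)
  expect_equal(abs(mclust::adjustedRandIndex(cl$labels, truth)), 1)
  # duplicates co-cluster; k = 1 trivially groups; determinism under seed
  expect_equal(cl$labels[["e01"]], cl$labels[["e02"]])
  expect_equal(unname(cluster_dynamic(se, rownames(cnt), 1, 7)$labels),
               rep(1L, 60))
  again <- cluster_dynamic(se, rownames(cnt), k = 2, seed = 7)
  expect_identical(cl$labels, again$labels)
  expect_error(cluster_dynamic(se, rownames(cnt)[1:3], k = 5, seed = 1),
               "k exceeds")
})

test_that("rank AUC equals exhaustive pair counting and is transform-invariant", {
  score <- c(3.2, 1.1, 4.8, 2.0, 4.0, 0.5)
  positive <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  pairs <- expand.grid(p = which(positive), n = which(!positive))
  want <- mean(ifelse(score[pairs$p] > score[pairs$n], 1,
                      ifelse(score[pairs$p] == score[pairs$n], 0.5, 0)))
  expect_equal(rank_auc(score, positive), want)
  expect_equal(rank_auc(exp(score), positive), want)
  expect_equal(rank_auc(rank(score), positive), want)
  # perfect separation
  expect_equal(rank_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
})

test_that("mark-vs-expression AUC behaves at the extremes", {
  set.seed(91)
  n <- 2000
  expr <- rnorm(n)
  states <- sample(c("active", "poised", "neutral"), n, replace = TRUE)
  sig <- cbind(perfect = expr, noise = rnorm(n))
  auc <- mark_expression_auc(sig, expr, states, top_n = 300)
  expect_equal(unname(auc["perfect"]), 1)
  expect_lt(abs(auc["noise"] - 0.5), 0.05)
  # bottom tail: a mark tracking low expression scores high
  auc_b <- mark_expression_auc(-sig, expr, states, top_n = 300,
                               tail = "bottom")
  expect_equal(unname(auc_b["perfect"]), 1)
  expect_warning(mark_expression_auc(sig[1:50, ], expr[1:50], states[1:50],
                                     top_n = 1000), "fewer")
})
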