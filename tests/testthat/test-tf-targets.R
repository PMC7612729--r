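test_that("cooperativity classes partition the combined peak universe", {
  A <- gr_bed("chr1", c(0, 5000), c(1000, 6000))
  B <- gr_bed("chr1", c(10000, 15000), c(11000, 16000))
  C <- gr_bed("chr1", 20000, 21000)
  got <- intersect_tf_peaks(list(A = A, B = B, C = C))
  # disjoint sets: only singleton classes populated
  expect_equal(unname(got$class_counts[c("A", "B", "C")]), c(2, 2, 1))
  expect_equal(sum(got$class_counts), length(got$universe))
  expect_true(all(got$class_counts[c("A+B", "A+C", "B+C", "A+B+C")] == 0))

  # identical sets: only the triple class
  got2 <- intersect_tf_peaks(list(A = A, B = A, C = A))
  expect_equal(unname(got2$class_counts[["A+B+C"]]), 2)
  expect_equal(sum(got2$class_counts), 2)

  # reordering inputs permutes labels, not the partition
  got3 <- intersect_tf_peaks(list(C = C, B = B, A = A))
  expect_equal(sort(unname(got3$class_counts)),
               sort(unname(got$class_counts)))
  expect_warning(intersect_tf_peaks(list(A = A, B = GRanges())), "empty")
})

test_that("pairwise overlap p-value equals the exact hypergeometric summation", {
  # direct summation oracle for P[X >= k] with |A|=100, |B|=100, N=1000
  k <- 30; K <- 100; n <- 100; N <- 1000
  want <- sum(choose(K, k:n) * choose(N - K, n - (k:n))) / choose(N, n)
  expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE), want)

  # and the same statistic computed from constructed peak sets
  pos <- (0:999) * 10000
  A <- gr_bed("chr1", pos[1:100], pos[1:100] + 500)
  B <- gr_bed("chr1", pos[c(1:30, 201:270)], pos[c(1:30, 201:270)] + 500)
  filler <- gr_bed("chr1", pos[301:1000] + 600, pos[301:1000] + 1100)
  got <- intersect_tf_peaks(list(A = A, B = B, X = filler))
  pw <- got$pairwise[got$pairwise$tf1 == "A" & got$pairwise$tf2 == "B", ]
  expect_equal(pw$overlap, 30)
  N2 <- length(got$universe)
  want2 <- sum(choose(100, 30:100) * choose(N2 - 100, 100 - (30:100))) /
    choose(N2, 100)
  expect_equal(pw$p_value, want2)
})

test_that("regulatory potential follows the configured decay closed form", {
  ann <- toy_annotation(c(100000, 500000), ids = c("G1", "G2"))
  # single peak with summit exactly at the G1 TSS
  pk <- np("chr1", 99500, 100500, summit = 499)
  rp <- regulatory_potential(pk, ann)
  expect_equal(rp$score[rp$gene_id == "G1"], exp(-0.5), tolerance = 1e-12)
  # no peak within 100 kb of G2
  expect_equal(rp$score[rp$gene_id == "G2"], 0)
  # two equidistant peaks double the score; additivity
  pk2 <- np("chr1", c(79500, 119500), c(80500, 120500), summit = c(499, 499))
  rp2 <- regulatory_potential(pk2, ann)
  one <- exp(-(0.5 + 4 * 20000 / 1e5))
  expect_equal(rp2$score[1], 2 * one, tolerance = 1e-12)
  # monotone decreasing in distance
  d <- seq(0, 1e5, by = 1e4)
  expect_true(all(diff(beta_decay(d / 1e5)) < 0))
  # custom decay is honoured
  rp3 <- regulatory_potential(pk, ann, decay = function(x) 1 - x)
  expect_equal(rp3$score[1], 1)
})

test_that("KS-based function prediction gets direction and degenerate cases right", {
  po <- data.frame(gene_id = sprintf("g%03d", 1:60),
                   score = c(seq(2, 3, length.out = 20),
                             seq(0, 0.5, length.out = 20),
                             seq(0.9, 1.4, length.out = 20)))
  up <- sprintf("g%03d", 1:20)       # all higher than unchanged
  dn <- sprintf("g%03d", 21:40)      # all lower
  unch <- sprintf("g%03d", 41:60)
  got <- predict_tf_function(po, up, dn, unch)
  expect_equal(got$D[got$group == "up"], 1)
  expect_lt(got$p_value[got$group == "up"], 1e-4)
  # down group lies entirely below: one-sided test in this direction is null
  expect_gt(got$p_value[got$group == "down"], 0.5)
  # identical groups: D = 0, p = 1
  po2 <- data.frame(gene_id = sprintf("h%02d", 1:30),
                    score = rep(seq_len(10), 3))
  same <- predict_tf_function(po2, sprintf("h%02d", 1:10),
                              sprintf("h%02d", 11:20),
                              sprintf("h%02d", 21:30))
  expect_equal(same$D, c(0, 0))
  expect_equal(same$p_value, c(1, 1))
  expect_true(all(!same$unreliable))
  small <- predict_tf_function(po2, sprintf("h%02d", 1:3),
                               sprintf("h%02d", 11:20),
                               sprintf("h%02d", 21:30))
  expect_true(small$unreliable[small$group == "up"])
  expect_error(predict_tf_function(po2, "h01", "h01", "h03"), "disjoint")
})

test_that("direct-target rules evaluate peaks, knockouts and element states jointly", {
  ann <- toy_annotation(c(100000, 300000, 500000),
                        ids = c("GUP", "GDN", "GNO"))
  # SOX17-only peaks 20 kb from each TSS
  sox <- np("chr1", c(119500, 319500, 519500), c(120500, 320500, 520500),
            summit = 499)
  classes <- intersect_tf_peaks(list(SOX17 = sox,
                                     PRDM1 = gr_bed("chr1", 9e5, 9.01e5),
                                     TFAP2C = gr_bed("chr1", 9.5e5, 9.51e5)))
  elements <- gr_bed("chr1", c(119000, 319000, 519000),
                     c(121000, 321000, 521000),
                     element_id = c("eA", "eB", "eC"))
  asg <- data.frame(element_id = c("eA", "eB", "eC"),
                    cell_type = "hPGCLC",
                    state = c("active", "repressed", "neutral"))
  ko <- list(SOX17 = data.frame(
    gene_id = c("GUP", "GDN", "GNO"),
    log2_fc = c(-2.5, 2.5, -2.5), adj_p = c(1e-5, 1e-5, 1e-5)),
    PRDM1 = data.frame(gene_id = character(), log2_fc = numeric(),
                       adj_p = numeric()),
    TFAP2C = data.frame(gene_id = character(), log2_fc = numeric(),
                        adj_p = numeric()))
  got <- call_direct_targets(classes, ko, elements, asg, "hPGCLC", ann)
  # down in KO + peak overlapping an active enhancer -> direct up target
  expect_true(any(got$gene_id == "GUP" & got$class == "SOX17" &
                  got$direction == "up"))
  # up in KO + peak not on an active element -> direct down target
  expect_true(any(got$gene_id == "GDN" & got$direction == "down"))
  # down in KO but peak overlaps only a neutral element -> no call
  expect_false("GNO" %in% got$gene_id)

  # flipping the element state flips the calls
  asg2 <- within(asg, state[element_id == "eC"] <- "mixed")
  got2 <- call_direct_targets(classes, ko, elements, asg2, "hPGCLC", ann)
  expect_true("GNO" %in% got2$gene_id[got2$direction == "up"])
  asg3 <- within(asg, state[element_id == "eB"] <- "active")
  got3 <- call_direct_targets(classes, ko, elements, asg3, "hPGCLC", ann)
  expect_false("GDN" %in% got3$gene_id)

  # missing KO table: classes containing that TF are skipped with a warning
  w <- testthat::capture_warnings(
    part <- call_direct_targets(classes, ko["SOX17"], elements, asg,
                                "hPGCLC", ann))
  expect_true(any(grepl("skipping class", w)))
  expect_true(all(part$class == "SOX17"))
})

test_that("multi-TF classes require the knockout response in every member", {
  ann <- toy_annotation(100000, ids = "G1")
  sox <- np("chr1", 119500, 120500, summit = 499)
  prd <- np("chr1", 119600, 120600, summit = 499)
  classes <- intersect_tf_peaks(list(SOX17 = sox, PRDM1 = prd))
  elements <- gr_bed("chr1", 119000, 121000, element_id = "e1")
  asg <- data.frame(element_id = "e1", cell_type = "ctx", state = "active")
  both <- list(SOX17 = data.frame(gene_id = "G1", log2_fc = -3,
                                  adj_p = 1e-6),
               PRDM1 = data.frame(gene_id = "G1", log2_fc = -3,
                                  adj_p = 1e-6))
  one <- list(SOX17 = data.frame(gene_id = "G1", log2_fc = -3,
                                 adj_p = 1e-6),
              PRDM1 = data.frame(gene_id = "G1", log2_fc = 0, adj_p = 1))
  got_both <- call_direct_targets(classes, both, elements, asg, "ctx", ann)
  expect_true(any(got_both$class == "SOX17+PRDM1" &
                  got_both$direction == "up"))
  got_one <- call_direct_targets(classes, one, elements, asg, "ctx", ann)
  expect_false(any(got_one$class == "SOX17+PRDM1"))
})

test_that("region-set enrichment reports fractions and exact hypergeometric p", {
  pos <- (0:499) * 10000
  universe <- gr_bed("chr1", pos, pos + 500)
  query <- universe[1:40]
  ref <- gr_bed("chr1", pos[c(1:12, 101:138)], pos[c(1:12, 101:138)] + 500)
  got <- region_set_enrichment(query, list(ref = ref), universe)
  expect_equal(got$fraction, 12 / 40)
  want <- sum(choose(50, 12:40) * choose(450, 40 - (12:40))) /
    choose(500, 40)
  expect_equal(got$p_value, want)
  # subset and disjoint references
  full <- region_set_enrichment(query, list(all = query), universe)
  expect_equal(full$fraction, 1)
  far <- region_set_enrichment(query,
                               list(none = gr_bed("chr2", 0, 100)),
                               universe)
  expect_equal(far$fraction, 0)
  expect_gt(far$p_value, 0.99)
  expect_error(region_set_enrichment(gr_bed("chr9", 0, 100),
                                     list(x = ref), universe),
               "universe")
})
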