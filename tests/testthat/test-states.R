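## build one element plus peak sets realizing a given flag combination
flag_fixture <- function(flags, marks, ct = "hESC") {
  el <- gr_bed("chr1", 10000, 11000, element_id = "e1")
  mark_peaks <- list()
  for (i in seq_along(marks)) {
    mark_peaks[[marks[i]]][[ct]] <-
      if (flags[i]) np("chr1", 10000, 11000) else GRanges()
  }
  list(elements = el, mark_peaks = mark_peaks)
}

test_that("enhancer classification matches the truth table on all 8 combinations", {
  tt <- read_truth_table()
  marks <- tt$enhancer$marks
  for (key in names(tt$enhancer$states)) {
    flags <- as.integer(strsplit(key, "")[[1]]) == 1
    fx <- flag_fixture(flags, marks)
    got <- classify_elements(fx$elements, fx$mark_peaks, "hESC",
                             "enhancer", truth_table = tt)
    expect_equal(got$state, tt$enhancer$states[[key]],
                 label = paste("enhancer flags", key))
  }
})

test_that("promoter classification matches the truth table on all 8 combinations", {
  tt <- read_truth_table()
  marks <- tt$promoter$marks
  for (key in names(tt$promoter$states)) {
    flags <- as.integer(strsplit(key, "")[[1]]) == 1
    fx <- flag_fixture(flags, marks)
    got <- classify_elements(fx$elements, fx$mark_peaks, "hESC",
                             "promoter", truth_table = tt)
    expect_equal(got$state, tt$promoter$states[[key]],
                 label = paste("promoter flags", key))
  }
})

test_that("hallmark enhancer combinations land on the expected states", {
  tt <- read_truth_table()
  # K4me1 + K27ac without K27me3 -> active; no mark -> neutral
  expect_equal(tt$enhancer$states[["110"]], "active")
  expect_equal(tt$enhancer$states[["000"]], "neutral")
  # K4me1 + K27me3 -> poised; K4me1 alone -> primed
  expect_equal(tt$enhancer$states[["101"]], "poised")
  expect_equal(tt$enhancer$states[["100"]], "primed")
})

test_that("classification is order-invariant and 20% overlap gates the flags", {
  set.seed(51)
  els <- gr_bed("chr1", (0:19) * 5000, (0:19) * 5000 + 1000,
                element_id = sprintf("e%02d", 1:20))
  mark_peaks <- list()
  for (m in c("H3K4me1", "H3K27ac", "H3K27me3"))
    mark_peaks[[m]][["ct"]] <- random_intervals(40, max_pos = 1e5,
                                                max_len = 2000,
                                                chroms = "chr1")
  a <- classify_elements(els, mark_peaks, "ct", "enhancer")
  perm <- sample(20)
  b <- classify_elements(els[perm], mark_peaks, "ct", "enhancer")
  expect_equal(a$state[match(b$element_id, a$element_id)], b$state)
  # only 19% covered: flag off -> neutral
  el <- gr_bed("chr1", 0, 1000, element_id = "x")
  mp <- list(H3K4me1 = list(ct = gr_bed("chr1", 0, 190)),
             H3K27ac = list(ct = GRanges()),
             H3K27me3 = list(ct = GRanges()))
  expect_equal(classify_elements(el, mp, "ct", "enhancer")$state, "neutral")
  # impossible fraction: everything neutral
  all_neutral <- classify_elements(els, mark_peaks, "ct", "enhancer",
                                   min_overlap_frac = 1.01)
  expect_true(all(all_neutral$state == "neutral"))
})

test_that("missing mark/cell-type peak sets are reported as a hard error", {
  el <- gr_bed("chr1", 0, 1000, element_id = "x")
  mp <- list(H3K4me1 = list(ct = GRanges()))
  expect_error(classify_elements(el, mp, "ct", "enhancer"),
               "H3K27ac/ct")
})

test_that("transition matrices tally flows and agree with state fractions", {
  ids <- sprintf("e%02d", 1:10)
  asg <- rbind(
    data.frame(element_id = ids, cell_type = "A", state = "active"),
    data.frame(element_id = ids, cell_type = "B", state = "active"))
  tm <- state_transitions(asg, c("A", "B"))[["A->B"]]
  expect_equal(tm["active", "active"], 10)
  expect_equal(sum(tm), 10)

  asg2 <- rbind(
    data.frame(element_id = "e1", cell_type = "A", state = "primed"),
    data.frame(element_id = "e1", cell_type = "B", state = "active"))
  tm2 <- state_transitions(asg2, c("A", "B"),
                           states = c("active", "primed"))[["A->B"]]
  expect_equal(tm2["primed", "active"], 1)
  expect_equal(sum(tm2), 1)

  set.seed(61)
  sts <- c("active", "mixed", "primed", "poised", "repressed", "neutral")
  ids <- sprintf("e%03d", 1:200)
  asg3 <- do.call(rbind, lapply(c("A", "B", "C"), function(ct)
    data.frame(element_id = ids, cell_type = ct,
               state = sample(sts, 200, replace = TRUE))))
  tms <- state_transitions(asg3, c("A", "B", "C"), states = sts)
  expect_equal(names(tms), c("A->B", "B->C"))
  # brute-force tally oracle
  wide <- reshape(asg3, idvar = "element_id", timevar = "cell_type",
                  direction = "wide")
  for (pair in list(c("A", "B"), c("B", "C"))) {
    want <- table(factor(wide[[paste0("state.", pair[1])]], levels = sts),
                  factor(wide[[paste0("state.", pair[2])]], levels = sts))
    expect_equal(as.vector(tms[[paste0(pair[1], "->", pair[2])]]),
                 as.vector(want))
  }
  # marginals equal per-cell-type state tallies
  fa <- state_fractions(asg3, "A", states = sts)
  fb <- state_fractions(asg3, "B", states = sts)
  expect_equal(unname(rowSums(tms[["A->B"]])), fa$count)
  expect_equal(unname(colSums(tms[["A->B"]])), fb$count)
  expect_equal(sum(fa$fraction), 1)
})

test_that("transition tracking restricted to a subset and errors on gaps", {
  asg <- rbind(
    data.frame(element_id = c("e1", "e2"), cell_type = "A",
               state = c("active", "neutral")),
    data.frame(element_id = c("e1", "e2"), cell_type = "B",
               state = c("mixed", "neutral")))
  tm <- state_transitions(asg, c("A", "B"), element_ids = "e1",
                          states = c("active", "mixed", "neutral"))
  expect_equal(sum(tm[["A->B"]]), 1)
  bad <- asg[-4, ]
  expect_error(state_transitions(bad, c("A", "B")), "differ")
})
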