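test_that("best matches keep the single best hit per query", {
  hits <- manual_hits(
    hit("AAAA_1_x", "BBBB_1_y", 85, bitscore = 300),
    hit("AAAA_1_x", "BBBB_2_y", 99, bitscore = 800),
    hit("AAAA_2_x", "BBBB_3_y", 90, bitscore = 500))
  m <- best_hit_matches(hits)
  expect_equal(nrow(m), 2L)
  expect_equal(m$subject_id[m$query_id == "AAAA_1_x"], "BBBB_2_y")
  expect_equal(m$pct_identity[m$query_id == "AAAA_1_x"], 99)
})

test_that("tie-breaking is deterministic under input permutation", {
  hits <- manual_hits(
    hit("AAAA_1_x", "BBBB_2_y", 97, bitscore = 800, evalue = 1e-50),
    hit("AAAA_1_x", "BBBB_1_y", 97, bitscore = 800, evalue = 1e-50),
    hit("AAAA_1_x", "BBBB_3_y", 99, bitscore = 800, evalue = 1e-50))
  set.seed(5)
  for (i in 1:10) {
    m <- best_hit_matches(hits[sample(nrow(hits)), ])
    # identity breaks the bitscore/evalue tie, then subject id would
    expect_equal(m$subject_id, "BBBB_3_y")
  }
  # equal identity too: lexicographic subject wins
  hits$pct_identity <- 97
  for (i in 1:10) {
    m <- best_hit_matches(hits[sample(nrow(hits)), ])
    expect_equal(m$subject_id, "BBBB_1_y")
  }
})

test_that("no hits yield no matches", {
  expect_equal(nrow(best_hit_matches(manual_hits(
    hit("AAAA_1_x", "AAAA_2_x", 99)))), 0L)  # self-sample pairs dropped
})

test_that("histogram bins identities half-open with 100 in the top bin", {
  h <- identity_histogram(c(85.2, 85.9, 99.5, 100), bin_width = 1)
  expect_equal(unname(h$counts[["85"]]), 2)
  expect_equal(unname(h$counts[["99"]]), 2)  # 99.5 and 100 share the top
  expect_equal(h$n_total, 4L)
  expect_equal(sum(h$counts), h$n_total)
  expect_error(identity_histogram(50, bin_width = 0), "positive")
  expect_error(identity_histogram(50, bin_width = 3), "divide 100")
})

test_that("histogram counts always sum to the match total", {
  set.seed(9)
  for (i in 1:20) {
    ids <- runif(sample(0:500, 1), 0, 100)
    for (bw in c(0.5, 1, 2)) {
      h <- identity_histogram(ids, bin_width = bw)
      expect_equal(sum(h$counts), length(ids))
    }
  }
})

test_that("cutoff detection finds the first minimum below the peak", {
  h <- as_identity_histogram(c(`100` = 50, `99` = 30, `98` = 5,
                               `97` = 2, `96` = 10, `95` = 40,
                               `94` = 60))
  th <- find_cutoff(h)
  expect_equal(th$status, "found")
  expect_equal(th$cutoff, 97)
  expect_equal(th$peak_support, 80)
})

test_that("histograms without a near-100% peak yield no cutoff", {
  h <- as_identity_histogram(stats::setNames(c(100, rep(0, 20)), 80:100))
  th <- find_cutoff(h)
  expect_equal(th$status, "no_peak")
  expect_true(is.na(th$cutoff))
  # raising min_peak_support never converts no_peak to found
  h2 <- as_identity_histogram(c(`100` = 6, `90` = 0, `85` = 50))
  expect_equal(find_cutoff(h2, min_peak_support = 5)$status, "found")
  expect_equal(find_cutoff(h2, min_peak_support = 7)$status, "no_peak")
})

test_that("a unimodal near-100% histogram is degenerate", {
  h <- as_identity_histogram(stats::setNames(c(0, 1, 2, 5, 20, 80),
                                             95:100))
  expect_warning(th <- find_cutoff(h), "unimodal")
  expect_equal(th$status, "degenerate")
  expect_true(is.na(th$cutoff))
})

test_that("smoothing parameters are validated", {
  h <- as_identity_histogram(c(`100` = 50, `90` = 5, `80` = 60))
  expect_error(find_cutoff(h, smooth_window = 2), "odd")
  expect_error(find_cutoff(h, smooth_window = 0), "odd")
  expect_equal(find_cutoff(h, smooth_window = 1)$status, "found")
})

test_that("cutoff agrees with the exhaustive oracle on random input", {
  set.seed(33)
  for (i in 1:200) {
    counts <- random_histogram()
    th <- suppressWarnings(find_cutoff(as_identity_histogram(counts)))
    or <- oracle_cutoff(counts)
    expect_equal(th$status, or$status)
    expect_equal(th$cutoff, or$cutoff)
  }
})

test_that("cutoff lies strictly between the background mode and 100", {
  set.seed(17)
  sim <- small_sim(seed = 17)
  res <- screen_contamination(sim$libraries, sim$pair_hits, sim$samples,
                              sim$tree, sim$research_hits)
  key <- pair_key(sim$config$donor, sim$config$recipient)
  th <- res$thresholds[[key]]
  h <- res$histograms[[key]]
  mode_edge <- as.numeric(names(which.max(h$counts)))
  expect_equal(th$status, "found")
  expect_gt(th$cutoff, mode_edge)
  expect_lt(th$cutoff, 100)
})

test_that("candidates are flagged symmetrically above the cutoff", {
  matches <- best_hit_matches(manual_hits(
    hit("AAAA_1_x", "BBBB_1_y", 99.5),
    hit("AAAA_2_x", "BBBB_2_y", 96.0),
    hit("AAAA_3_x", "BBBB_3_y", 98.2),
    hit("AAAA_4_x", "BBBB_4_y", 97.0)))
  th <- structure(list(pair = "AAAA|BBBB", status = "found", cutoff = 97,
                       peak_support = 10, n_total = 4),
                  class = "contam_threshold")
  cands <- call_candidates(matches, th)
  # 99.5, 98.2 and the tie at exactly 97 are flagged, two records each
  expect_equal(nrow(cands), 6L)
  expect_setequal(unique(cands$sample), c("AAAA", "BBBB"))
  expect_true(all(cands$identity >= 97))
  # raising the cutoff never adds candidates
  th2 <- th
  th2$cutoff <- 99
  expect_true(all(call_candidates(matches, th2)$seq_id %in%
                    cands$seq_id))
  # no cutoff, no candidates
  th$status <- "no_peak"
  expect_equal(nrow(call_candidates(matches, th)), 0L)
})

test_that("threshold and histogram reports serialize cleanly", {
  h <- as_identity_histogram(c(`100` = 50, `97` = 2, `95` = 40),
                             pair = "AAAA|BBBB")
  th <- find_cutoff(h)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_threshold_report(list(th), f)
  rep <- read.delim(f)
  expect_equal(rep$code_a, "AAAA")
  expect_equal(rep$status, "found")
  expect_equal(rep$cutoff, 97)
  write_histogram(h, f)
  dump <- read.delim(f)
  expect_equal(sum(dump$count), h$n_total)
})
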