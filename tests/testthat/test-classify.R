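# A 4-library world: recipient RRRR holds a candidate; DDDD is a
# distant donor, SSSS shares RRRR's family, TTTT is distant.
classify_world <- function() {
  list(samples = sample_table(c("RRRR", "DDDD", "SSSS", "TTTT"),
                              c("Rosaceae", "Gunneraceae", "Rosaceae",
                                "Fabaceae")),
       tree = ape::read.tree(
         text = "((RRRR,SSSS),(DDDD,TTTT));"),
       cand = data.frame(seq_id = "RRRR_9_x", sample = "RRRR",
                         partner_seq_id = "DDDD_9_x",
                         partner_sample = "DDDD", identity = 99.4,
                         stringsAsFactors = FALSE))
}

test_that("a same-family hit among the top 3 excludes the candidate", {
  w <- classify_world()
  rh <- manual_hits(
    hit("RRRR_9_x", "DDDD_9_x", 99.4, bitscore = 900),
    hit("RRRR_9_x", "SSSS_1_x", 95.0, bitscore = 700),
    hit("RRRR_9_x", "TTTT_1_x", 90.0, bitscore = 500))
  cl <- classify_candidates(w$cand, rh, w$samples, w$tree)
  expect_equal(cl$status, "excluded_close_taxon")
  expect_true(is.na(cl$donor_sample))
})

test_that("exclusively distant top hits verify the contaminant", {
  w <- classify_world()
  rh <- manual_hits(
    hit("RRRR_9_x", "DDDD_9_x", 99.4, bitscore = 900),
    hit("RRRR_9_x", "TTTT_1_x", 85.0, bitscore = 500))
  cl <- classify_candidates(w$cand, rh, w$samples, w$tree)
  expect_equal(cl$status, "verified_contaminant")
  expect_equal(cl$donor_sample, "DDDD")  # best hit's library
})

test_that("no re-search evidence leaves the candidate unresolved", {
  w <- classify_world()
  cl <- classify_candidates(w$cand, NULL, w$samples, w$tree)
  expect_equal(cl$status, "unresolved_possible")
  # hits against the candidate's own library do not count as evidence
  rh <- manual_hits(hit("RRRR_9_x", "RRRR_2_x", 99.9))
  cl <- classify_candidates(w$cand, rh, w$samples, w$tree)
  expect_equal(cl$status, "unresolved_possible")
})

test_that("only the first n_top hits are considered", {
  w <- classify_world()
  rh <- manual_hits(
    hit("RRRR_9_x", "DDDD_9_x", 99.4, bitscore = 900),
    hit("RRRR_9_x", "DDDD_3_x", 98.0, bitscore = 850),
    hit("RRRR_9_x", "TTTT_1_x", 90.0, bitscore = 700),
    hit("RRRR_9_x", "SSSS_1_x", 95.0, bitscore = 100))  # rank 4
  cl <- classify_candidates(w$cand, rh, w$samples, w$tree)
  expect_equal(cl$status, "verified_contaminant")
  cl4 <- classify_candidates(w$cand, rh, w$samples, w$tree, n_top = 4)
  expect_equal(cl4$status, "excluded_close_taxon")
})

test_that("the strict close-branch bound only excludes below it", {
  w <- classify_world()
  # TTTT is 4 edges from RRRR; DDDD too. With close_branches = 5 any
  # considered hit counts as close.
  rh <- manual_hits(hit("RRRR_9_x", "TTTT_1_x", 99.0, bitscore = 900))
  expect_equal(classify_candidates(w$cand, rh, w$samples, w$tree,
                                   close_branches = 2)$status,
               "verified_contaminant")
  expect_equal(classify_candidates(w$cand, rh, w$samples, w$tree,
                                   close_branches = 5)$status,
               "excluded_close_taxon")
})

test_that("classification ignores hit order for equally scored hits", {
  w <- classify_world()
  rh <- manual_hits(
    hit("RRRR_9_x", "TTTT_1_x", 99.4, bitscore = 900),
    hit("RRRR_9_x", "DDDD_9_x", 99.4, bitscore = 900))
  set.seed(8)
  donors <- replicate(10, {
    classify_candidates(w$cand, rh[sample(nrow(rh)), ], w$samples,
                        w$tree)$donor_sample
  })
  expect_true(all(donors == "DDDD"))  # lexicographic tie-break
})

test_that("verdicts partition a library into the four statuses", {
  records <- data.frame(seq_id = paste0("RRRR_", 1:10, "_x"),
                        sample_code = "RRRR",
                        sequence = strrep("A", 10),
                        stringsAsFactors = FALSE)
  classified <- data.frame(
    seq_id = c("RRRR_2_x", "RRRR_5_x"), sample = "RRRR",
    status = c("verified_contaminant", "unresolved_possible"),
    donor_sample = c("DDDD", NA), partner_seq_id = c("DDDD_2_x", NA),
    stringsAsFactors = FALSE)
  v <- assign_verdicts(records, classified)
  expect_equal(nrow(v), 10L)
  expect_equal(sum(v$status == "clean"), 8L)
  expect_equal(v$status[v$seq_id == "RRRR_2_x"], "verified_contaminant")
  # zero candidates: all clean
  v0 <- assign_verdicts(records, classified[0, ])
  expect_true(all(v0$status == "clean"))
  # unknown candidate id is a consistency error
  classified$seq_id[1] <- "RRRR_99_x"
  expect_error(assign_verdicts(records, classified), "unknown sequence")
})

test_that("library splitting conserves records and keeps possibles", {
  records <- data.frame(seq_id = paste0("RRRR_", 1:5, "_x"),
                        sample_code = "RRRR",
                        sequence = replicate(5, paste(
                          sample(c("A", "C", "G", "T"), 20,
                                 replace = TRUE), collapse = "")),
                        stringsAsFactors = FALSE)
  verdicts <- data.frame(
    seq_id = records$seq_id, sample = "RRRR",
    status = c("clean", "verified_contaminant", "clean",
               "unresolved_possible", "excluded_close_taxon"),
    donor_sample = NA, partner_seq_id = NA, stringsAsFactors = FALSE)
  sp <- split_library(records, verdicts)
  expect_equal(nrow(sp$clean), 4L)
  expect_equal(nrow(sp$contaminant), 1L)
  expect_equal(sp$contaminant$seq_id, "RRRR_2_x")
  # possible contaminants stay in the clean set
  expect_true("RRRR_4_x" %in% sp$clean$seq_id)
  # conservation, bitwise on sequences
  expect_setequal(c(sp$clean$sequence, sp$contaminant$sequence),
                  records$sequence)
  expect_error(split_library(records, verdicts[-1, ]),
               "missing verdict")
})

test_that("library summaries, matrix and pair list are consistent", {
  verdicts <- rbind(
    data.frame(seq_id = paste0("AAAA_", 1:4, "_x"), sample = "AAAA",
               status = c("clean", "clean", "verified_contaminant",
                          "unresolved_possible"),
               donor_sample = c(NA, NA, "BBBB", NA),
               partner_seq_id = c(NA, NA, "BBBB_3_x", NA)),
    data.frame(seq_id = paste0("BBBB_", 1:3, "_x"), sample = "BBBB",
               status = "clean", donor_sample = NA,
               partner_seq_id = NA))
  out <- summarize_libraries(verdicts)
  s <- out$summary
  expect_equal(s$n_contaminant + s$n_clean + s$n_possible, s$n_total)
  expect_equal(s$n_contaminant[s$sample == "AAAA"], 1L)
  expect_equal(s$n_contaminant_in_others[s$sample == "BBBB"], 1L)
  expect_equal(unname(out$matrix["AAAA", "BBBB"]), 1)
  expect_equal(sum(out$matrix, na.rm = TRUE),
               sum(verdicts$status == "verified_contaminant"))
  expect_true(all(is.na(diag(out$matrix))))
  expect_equal(out$pairs$contaminant_seq_id, "AAAA_3_x")
  expect_equal(out$pairs$partner_seq_id, "BBBB_3_x")
  # no verified contaminants: all-zero matrix
  verdicts$status[verdicts$status == "verified_contaminant"] <- "clean"
  verdicts$donor_sample <- NA
  out0 <- summarize_libraries(verdicts)
  expect_equal(sum(out0$matrix, na.rm = TRUE), 0)
})
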