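test_that("configuration invariants are enforced", {
  expect_error(sim_config(contamination_fraction = 0), "contamination")
  expect_error(sim_config(noise_rate = 0.5), "noise_rate")
  expect_error(sim_config(divergence_identity = 100), "divergence")
  expect_error(sim_config(donor = "LAAA", recipient = "LAAA"), "donor")
  cfg <- sim_config(n_libraries = 4)
  expect_equal(length(cfg$codes), 4L)
  expect_true(all(grepl("^[A-Z]{4}$", cfg$codes)))
})

test_that("library generation is deterministic and well-formed", {
  cfg <- sim_config(n_transcripts = 10, length_range = c(50, 100))
  set.seed(99)
  lib1 <- generate_library("AAAA", cfg)
  set.seed(99)
  lib2 <- generate_library("AAAA", cfg)
  expect_identical(lib1, lib2)
  expect_equal(nrow(lib1), 10L)
  expect_equal(anyDuplicated(lib1$seq_id), 0L)
  expect_true(all(extract_sample_code(lib1$seq_id) == "AAAA"))
  len <- nchar(lib1$sequence)
  expect_true(all(len >= 50 & len <= 100))
  expect_true(all(grepl("^[ACGT]+$", lib1$sequence)))
})

test_that("generated bases are close to uniform", {
  cfg <- sim_config(n_transcripts = 40, length_range = c(900, 1100))
  set.seed(5)
  lib <- generate_library("AAAA", cfg)
  gc <- mean(strsplit(paste(lib$sequence, collapse = ""), NULL)[[1]]
             %in% c("G", "C"))
  n <- sum(nchar(lib$sequence))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / n))
})

test_that("ortholog divergence matches the binomial model", {
  set.seed(31)
  base <- random_sequence(10000)
  expect_identical(make_ortholog(base, 100), base)
  orth <- make_ortholog(base, 85)
  sd3 <- 3 * 100 * sqrt(0.15 * 0.85 / 10000)
  expect_lt(abs(seq_identity(base, orth) - 85), sd3)
  expect_equal(seq_identity(base, orth), seq_identity(orth, base))
  expect_error(make_ortholog(base, 45), "target_identity")
})

test_that("spiking copies the right number of donor sequences", {
  cfg <- sim_config(n_transcripts = 1000, length_range = c(100, 200))
  set.seed(7)
  donor <- generate_library("AAAA", cfg)
  recipient <- generate_library("BBBB", cfg)
  sp <- spike_contamination(donor, recipient, 0.05, noise_rate = 0)
  expect_equal(nrow(sp$recipient), 1050L)
  expect_equal(nrow(sp$truth), 50L)
  expect_true(all(sp$truth$is_contaminant))
  expect_true(all(sp$truth$donor_sample == "AAAA"))
  # noiseless copies are 100% identical to their donors
  spikes <- sp$recipient[1001:1050, ]
  donors <- donor$sequence[match(sp$truth$ortholog_of, donor$seq_id)]
  expect_true(all(mapply(seq_identity, spikes$sequence, donors) == 100))
})

test_that("noisy spikes stay near-identical to their donors", {
  cfg <- sim_config(n_transcripts = 200,
                    length_range = c(1000, 1000))
  set.seed(13)
  donor <- generate_library("AAAA", cfg)
  recipient <- generate_library("BBBB", cfg)
  sp <- spike_contamination(donor, recipient, 0.25, noise_rate = 0.005)
  spikes <- sp$recipient[201:250, ]
  donors <- donor$sequence[match(sp$truth$ortholog_of, donor$seq_id)]
  ident <- mapply(seq_identity, spikes$sequence, donors)
  expect_true(mean(ident >= 98.5) > 0.95)
})

test_that("the full simulation is reproducible and truth-conserving", {
  sim1 <- small_sim(seed = 6)
  sim2 <- small_sim(seed = 6)
  expect_identical(sim1$libraries, sim2$libraries)
  expect_identical(sim1$pair_hits, sim2$pair_hits)
  expect_identical(sim1$truth, sim2$truth)
  cfg <- sim1$config
  expect_equal(sum(sim1$truth$is_contaminant),
               ceiling(cfg$contamination_fraction * cfg$n_transcripts))
  expect_equal(nrow(sim1$truth),
               sum(vapply(sim1$libraries, nrow, integer(1))))
})

test_that("emitted hit tables hold one row per ortholog and spike", {
  sim <- small_sim(seed = 10)
  cfg <- sim$config
  n_spike <- ceiling(cfg$contamination_fraction * cfg$n_transcripts)
  key <- pair_key(cfg$donor, cfg$recipient)
  expect_equal(nrow(sim$pair_hits[[key]]),
               cfg$n_transcripts + n_spike)
  other <- setdiff(names(sim$pair_hits), key)
  for (k in other) {
    expect_equal(nrow(sim$pair_hits[[k]]), cfg$n_transcripts)
  }
})

test_that("spike rows separate cleanly from ortholog rows", {
  sim <- small_sim(seed = 11)
  cfg <- sim$config
  key <- pair_key(cfg$donor, cfg$recipient)
  hits <- sim$pair_hits[[key]]
  spike_ids <- sim$truth$seq_id[sim$truth$is_contaminant]
  is_spike <- hits$query_id %in% spike_ids |
    hits$subject_id %in% spike_ids
  expect_gt(min(hits$pct_identity[is_spike]),
            max(hits$pct_identity[!is_spike]))
})

test_that("simulation files round trip through the package readers", {
  sim <- small_sim(seed = 12)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  expect_equal(samples, sim$samples)
  tree <- read_newick_tree(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, sim$config$codes)
  lib <- read_transcript_fasta(
    file.path(dir, paste0(sim$config$codes[1], ".fasta")))
  expect_equal(lib$sequence, sim$libraries[[1]]$sequence)
  key <- names(sim$pair_hits)[1]
  codes <- strsplit(key, "|", fixed = TRUE)[[1]]
  back <- parse_tabular_hits(
    file.path(dir, "hits", sprintf("pair_%s_%s.tsv", codes[1],
                                   codes[2])))
  expect_equal(back, sim$pair_hits[[key]], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("SSU fixtures express the configured truth", {
  sim <- simulate_contamination(
    sim_config(n_transcripts = 30, length_range = c(100, 200),
               seed = 2, ssu_worrisome = "LAAB",
               ssu_missing = "LAAC"))
  ssu <- sim$ssu_hits
  lin <- sim$ssu_lineages
  joined <- data.frame(scaffold_id = ssu$query_id,
                       sample = extract_sample_code(ssu$query_id),
                       ref_id = ssu$subject_id,
                       ref_family = lin$family[match(ssu$subject_id,
                                                     lin$ref_id)],
                       ref_lineage = lin$lineage[match(ssu$subject_id,
                                                       lin$ref_id)],
                       aln_length = ssu$aln_length,
                       evalue = ssu$evalue,
                       pct_identity = ssu$pct_identity)
  assignments <- assign_scaffold_taxa(filter_ssu_hits(joined))
  v <- validate_samples(sim$samples, assignments)
  expect_equal(v$validated[v$sample == "LAAA"], TRUE)
  expect_equal(v$worrisome[v$sample == "LAAA"], FALSE)
  expect_equal(v$validated[v$sample == "LAAB"], TRUE)
  expect_equal(v$worrisome[v$sample == "LAAB"], TRUE)
  expect_equal(v$validated[v$sample == "LAAC"], FALSE)
  expect_equal(v$worrisome[v$sample == "LAAC"], FALSE)
})
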