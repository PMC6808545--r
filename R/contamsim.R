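# Synthetic contaminated-library simulator.
#
# Generates multi-library transcriptome sets with known pairwise
# divergence, a spiked cross-contamination event, SSU fixtures and
# ground-truth labels, plus the tabular hit files an external all-vs-all
# search would produce -- so every pipeline stage runs with no external
# data. Divergence is substitution-only (no indels), so percent identity
# between any two related sequences has a closed form and is computed
# exactly by position-wise comparison; e-values and bit scores in the
# emitted tables are synthetic monotone functions of identity and
# length, of which only the ordering is meaningful.

SIM_BASES <- c("A", "C", "G", "T")

# alternatives[base, k]: the k-th of the 3 bases different from `base`
SIM_ALT <- local({
  m <- t(vapply(SIM_BASES, function(b) setdiff(SIM_BASES, b),
                character(3L)))
  rownames(m) <- SIM_BASES
  m
})

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. The default scenario
#' is three libraries of 2000 transcripts with a pairwise ortholog
#' identity of 85%, one directed contamination spike of 5% of the donor
#' library copied into the recipient with 0.5% per-base noise, distinct
#' families per library, and a ladder phylogeny -- mirroring a single
#' heavily contaminated recipient among otherwise clean pairs.
#'
#' @param n_libraries Number of libraries.
#' @param n_transcripts Transcripts per library (before spiking).
#' @param length_range Transcript length bounds in bp (uniform draw).
#' @param divergence_identity Target pairwise percent identity between
#'   ortholog sets of any two libraries, in (50, 100).
#' @param contamination_fraction Fraction of the donor library copied
#'   into the recipient, in (0, 1).
#' @param noise_rate Per-base substitution probability applied to each
#'   contaminant copy, in `[0, 0.5)`.
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#' @param codes Library codes (default [make_library_codes()]).
#' @param family_map Named character vector code -> family (default one
#'   distinct family per library).
#' @param newick Newick text for the consensus tree (default a ladder
#'   over `codes`).
#' @param donor,recipient Codes of the spike's donor and recipient
#'   libraries (defaults: first and second code).
#' @param ssu_worrisome Codes that additionally receive a foreign-family
#'   plant SSU scaffold (worrisome-contamination truth).
#' @param ssu_missing Codes that receive no SSU scaffold at all
#'   (validation-failure truth).
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_libraries = 3, n_transcripts = 2000,
                       length_range = c(300, 3000),
                       divergence_identity = 85,
                       contamination_fraction = 0.05,
                       noise_rate = 0.005, seed = 1,
                       codes = NULL, family_map = NULL, newick = NULL,
                       donor = NULL, recipient = NULL,
                       ssu_worrisome = character(),
                       ssu_missing = character()) {
  stopifnot(n_libraries >= 2, n_transcripts >= 1,
            length(length_range) == 2L,
            length_range[1L] >= 1, length_range[1L] <= length_range[2L],
            divergence_identity > 50, divergence_identity < 100,
            contamination_fraction > 0, contamination_fraction < 1,
            noise_rate >= 0, noise_rate < 0.5)
  codes <- codes %||% make_library_codes(n_libraries)
  stopifnot(length(codes) == n_libraries, all(is_valid_code(codes)),
            !anyDuplicated(codes))
  family_map <- family_map %||%
    stats::setNames(sprintf("Simfamily%02d", seq_len(n_libraries)), codes)
  stopifnot(all(codes %in% names(family_map)))
  newick <- newick %||% ladder_newick(codes)
  donor <- donor %||% codes[1L]
  recipient <- recipient %||% codes[2L]
  stopifnot(donor %in% codes, recipient %in% codes, donor != recipient)
  structure(list(n_libraries = n_libraries,
                 n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 divergence_identity = divergence_identity,
                 contamination_fraction = contamination_fraction,
                 noise_rate = noise_rate, seed = as.integer(seed),
                 codes = codes, family_map = family_map, newick = newick,
                 donor = donor, recipient = recipient,
                 ssu_worrisome = ssu_worrisome,
                 ssu_missing = ssu_missing),
            class = "sim_config")
}

# Ladder (caterpillar) topology: (c1,(c2,(c3,c4)));  leaf-to-leaf
# distances are >= 3 for the first pair, so the default donor/recipient
# pair is never excluded by the tree rule.
ladder_newick <- function(codes) {
  n <- length(codes)
  if (n == 2L) return(paste0("(", codes[1L], ",", codes[2L], ");"))
  inner <- paste0("(", codes[n - 1L], ",", codes[n], ")")
  for (i in rev(seq_len(n - 2L))) {
    inner <- paste0("(", codes[i], ",", inner, ")")
  }
  paste0(inner, ";")
}

random_sequence <- function(len) {
  paste(sample(SIM_BASES, len, replace = TRUE), collapse = "")
}

# Substitution-only mutation: each site independently replaced with
# probability `rate`, drawing uniformly from the 3 alternative bases.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- which(stats::runif(n) < rate)
  if (!length(k)) return(seq)
  ch <- strsplit(seq, NULL)[[1L]]
  alt <- sample.int(3L, length(k), replace = TRUE)
  ch[k] <- SIM_ALT[cbind(match(ch[k], SIM_BASES), alt)]
  paste(ch, collapse = "")
}

#' Exact percent identity of two equal-length sequences
#'
#' Position-wise comparison; valid because simulated divergence is
#' substitution-only.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Percent identity in `[0, 100]`.
#' @export
seq_identity <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  100 * sum(ra == rb) / length(ra)
}

#' Derive a diverged ortholog of a sequence
#'
#' Copies the sequence with independent per-site substitutions at rate
#' `(100 - target_identity) / 100`; substitutions draw uniformly from
#' the three alternative bases and there are no indels, so the realized
#' identity to the template is binomial around the target.
#'
#' @param seq Nucleotide string.
#' @param target_identity Target percent identity in (50, 100].
#' @return Mutated copy of `seq`.
#' @export
make_ortholog <- function(seq, target_identity) {
  stopifnot(target_identity > 50, target_identity <= 100)
  mutate_sequence(seq, (100 - target_identity) / 100)
}

# Per-branch substitution rate q such that two lineages independently
# diverged from a common ancestor at rate q show the requested pairwise
# identity in expectation: P(match) = (1-q)^2 + q^2/3.
branch_rate_for_pairwise <- function(pair_identity) {
  t <- pair_identity / 100
  disc <- 1 - (4 / 3) * (1 - t)
  stopifnot(disc > 0)
  0.75 * (1 - sqrt(disc))
}

sim_seq_id <- function(code, serial) {
  sprintf("%s_%d_sim%s", code, serial, tolower(code))
}

#' Generate one library of random transcripts
#'
#' Uniform-random nucleotide sequences with lengths uniform in
#' `cfg$length_range`, identified by the `CODE_serial_species` grammar.
#' Uses the current R random-number state; call [set.seed()] (or use
#' [simulate_contamination()], which seeds from the configuration) for
#' reproducibility.
#'
#' @param code 4-letter library code.
#' @param cfg A [sim_config()].
#' @return Transcript data.frame (`seq_id`, `sample_code`, `sequence`,
#'   `serial`).
#' @export
generate_library <- function(code, cfg) {
  stopifnot(is_valid_code(code))
  n <- cfg$n_transcripts
  lens <- sample(seq(cfg$length_range[1L], cfg$length_range[2L]), n,
                 replace = TRUE)
  data.frame(seq_id = sim_seq_id(code, seq_len(n)),
             sample_code = code,
             sequence = vapply(lens, random_sequence, character(1L)),
             serial = seq_len(n), stringsAsFactors = FALSE)
}

#' Spike contamination from a donor into a recipient library
#'
#' Copies `ceiling(fraction * nrow(donor))` randomly chosen donor
#' sequences into the recipient with per-base noise at `noise_rate`,
#' re-identified under the recipient's code with serials continuing
#' after the recipient's own, and records the ground truth.
#'
#' @param donor,recipient Transcript data.frames
#'   ([generate_library()]).
#' @param fraction Fraction of the donor library copied, in (0, 1).
#' @param noise_rate Per-base substitution probability on each copy.
#' @return List with `recipient` (augmented data.frame) and `truth`
#'   (data.frame `seq_id`, `is_contaminant`, `donor_sample`,
#'   `ortholog_of`).
#' @export
spike_contamination <- function(donor, recipient, fraction,
                                noise_rate = 0) {
  stopifnot(fraction > 0, fraction < 1)
  m <- as.integer(ceiling(fraction * nrow(donor)))
  idx <- sort(sample.int(nrow(donor), m))
  code <- unique(recipient$sample_code)
  stopifnot(length(code) == 1L)
  serial <- nrow(recipient) + seq_len(m)
  spikes <- data.frame(
    seq_id = sim_seq_id(code, serial),
    sample_code = code,
    sequence = vapply(donor$sequence[idx], mutate_sequence,
                      character(1L), rate = noise_rate,
                      USE.NAMES = FALSE),
    serial = donor$serial[idx],    # ancestor index: provenance
    stringsAsFactors = FALSE)
  truth <- data.frame(seq_id = spikes$seq_id, is_contaminant = TRUE,
                      donor_sample = unique(donor$sample_code),
                      ortholog_of = donor$seq_id[idx],
                      stringsAsFactors = FALSE)
  list(recipient = rbind(recipient, spikes), truth = truth)
}

# Synthetic e-value / bit score: deterministic, strictly monotone in
# identity x length. Only the ordering is contractually meaningful.
synthetic_evalue <- function(identity, len) {
  10^(-pmin(250, identity * len / 1500))
}

synthetic_bitscore <- function(identity, len) {
  round(identity * len / 50, 1)
}

hit_row <- function(query_id, subject_id, identity, len) {
  mism <- round(len * (100 - identity) / 100)
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = identity, aln_length = len,
             mismatches = mism, gap_opens = 0,
             q_start = 1, q_end = len, s_start = 1, s_end = len,
             evalue = synthetic_evalue(identity, len),
             bitscore = synthetic_bitscore(identity, len),
             stringsAsFactors = FALSE)
}

#' Run the full contaminated-library simulation
#'
#' Seeds the generator from `cfg$seed`, builds an ancestral transcript
#' pool, derives each library's orthologs at the per-branch rate that
#' yields the configured pairwise identity, applies the contamination
#' spike, and emits everything the pipeline consumes: per-pair hit
#' tables (exact position-wise identities), re-search hit tables for the
#' spiked sequences, SSU hit and lineage fixtures, the sample table, the
#' Newick tree and ground-truth labels. Identical configurations give
#' identical output.
#'
#' @param cfg A [sim_config()].
#' @return List of class `"contam_sim"` with elements `config`,
#'   `samples`, `newick`, `tree`, `libraries` (named list of transcript
#'   data.frames), `truth`, `pair_hits` (named list keyed `"A|B"`),
#'   `research_hits`, `ssu_hits`, `ssu_lineages`.
#' @export
simulate_contamination <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  codes <- cfg$codes
  n <- cfg$n_transcripts

  ancestors <- generate_library(codes[1L], cfg)$sequence
  q <- branch_rate_for_pairwise(cfg$divergence_identity)
  branch_target <- 100 * (1 - q)

  libraries <- lapply(codes, function(code) {
    data.frame(seq_id = sim_seq_id(code, seq_len(n)),
               sample_code = code,
               sequence = vapply(ancestors, make_ortholog, character(1L),
                                 target_identity = branch_target,
                                 USE.NAMES = FALSE),
               serial = seq_len(n), stringsAsFactors = FALSE)
  })
  names(libraries) <- codes

  spiked <- spike_contamination(libraries[[cfg$donor]],
                                libraries[[cfg$recipient]],
                                cfg$contamination_fraction,
                                cfg$noise_rate)
  libraries[[cfg$recipient]] <- spiked$recipient
  spike_truth <- spiked$truth

  truth <- do.call(rbind, lapply(libraries, function(lib) {
    data.frame(seq_id = lib$seq_id, is_contaminant = FALSE,
               donor_sample = NA_character_, ortholog_of = NA_character_,
               stringsAsFactors = FALSE)
  }))
  m <- match(spike_truth$seq_id, truth$seq_id)
  truth$is_contaminant[m] <- TRUE
  truth$donor_sample[m] <- spike_truth$donor_sample
  truth$ortholog_of[m] <- spike_truth$ortholog_of
  rownames(truth) <- NULL

  pair_hits <- emit_hit_tables(libraries, spike_truth, cfg)
  research_hits <- emit_research_hits(libraries, spike_truth, cfg)
  ssu <- emit_ssu_fixtures(sim_samples(cfg), cfg)

  structure(list(config = cfg, samples = sim_samples(cfg),
                 newick = cfg$newick,
                 tree = ape::read.tree(text = cfg$newick),
                 libraries = libraries, truth = truth,
                 pair_hits = pair_hits, research_hits = research_hits,
                 ssu_hits = ssu$hits, ssu_lineages = ssu$lineages),
            class = "contam_sim")
}

sim_samples <- function(cfg) {
  data.frame(code = cfg$codes,
             species = paste("Simulatus", tolower(cfg$codes)),
             family = unname(cfg$family_map[cfg$codes]),
             clade = "Simulatae", stringsAsFactors = FALSE)
}

#' Emit per-pair tabular hit files
#'
#' For each library pair, one 12-column row per ortholog pair (query
#' from the lexicographically first code) and one per spiked
#' copy/donor-sequence pair, with exact position-wise identities.
#'
#' @param libraries Named list of transcript data.frames with a
#'   `serial` (ancestor index) column.
#' @param spike_truth Spike truth data.frame
#'   ([spike_contamination()]`$truth`).
#' @param cfg The [sim_config()].
#' @return Named list of hit data.frames keyed `"A|B"`.
#' @export
emit_hit_tables <- function(libraries, spike_truth, cfg) {
  codes <- sort(names(libraries))
  pairs <- utils::combn(codes, 2L)
  out <- list()
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    lib_a <- libraries[[a]]
    lib_b <- libraries[[b]]
    orig_a <- lib_a[seq_len(cfg$n_transcripts), , drop = FALSE]
    orig_b <- lib_b[seq_len(cfg$n_transcripts), , drop = FALSE]
    ident <- vapply(seq_len(cfg$n_transcripts), function(j) {
      seq_identity(orig_a$sequence[j], orig_b$sequence[j])
    }, numeric(1L))
    rows <- hit_row(orig_a$seq_id, orig_b$seq_id, ident,
                    nchar(orig_a$sequence))

    # spiked copies vs their donor sequences, when both ends lie in
    # this pair
    st <- spike_truth[spike_truth$donor_sample %in% c(a, b), ,
                      drop = FALSE]
    st <- st[extract_sample_code(st$seq_id) %in% c(a, b), , drop = FALSE]
    if (nrow(st) > 0L) {
      rec <- extract_sample_code(st$seq_id)
      spike_seq <- libraries[[rec[1L]]]$sequence[
        match(st$seq_id, libraries[[rec[1L]]]$seq_id)]
      donor_seq <- libraries[[st$donor_sample[1L]]]$sequence[
        match(st$ortholog_of, libraries[[st$donor_sample[1L]]]$seq_id)]
      sid <- vapply(seq_len(nrow(st)), function(j) {
        seq_identity(spike_seq[j], donor_seq[j])
      }, numeric(1L))
      qfirst <- rec == a      # query drawn from code `a` by convention
      rows <- rbind(rows,
                    hit_row(ifelse(qfirst, st$seq_id, st$ortholog_of),
                            ifelse(qfirst, st$ortholog_of, st$seq_id),
                            sid, nchar(spike_seq)))
    }
    out[[pair_key(a, b)]] <- rows
  }
  out
}

# Re-search evidence: each spiked sequence's top hits are its donor
# sequence plus the background orthologs in the remaining libraries.
# Original (non-spiked) sequences carry no re-search rows: they are not
# known contaminants and the re-search targets only flagged queries.
emit_research_hits <- function(libraries, spike_truth, cfg) {
  if (nrow(spike_truth) == 0L) return(empty_hits())
  codes <- names(libraries)
  rows <- lapply(seq_len(nrow(spike_truth)), function(i) {
    seq_id <- spike_truth$seq_id[i]
    rec <- extract_sample_code(seq_id)
    donor <- spike_truth$donor_sample[i]
    spike_seq <- libraries[[rec]]$sequence[
      match(seq_id, libraries[[rec]]$seq_id)]
    anc_serial <- libraries[[rec]]$serial[
      match(seq_id, libraries[[rec]]$seq_id)]
    subj_codes <- setdiff(codes, rec)
    do.call(rbind, lapply(subj_codes, function(code) {
      j <- match(anc_serial, libraries[[code]]$serial)
      subj <- libraries[[code]][j, , drop = FALSE]
      hit_row(seq_id, subj$seq_id,
              seq_identity(spike_seq, subj$sequence),
              nchar(spike_seq))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emit SSU hit and lineage fixtures
#'
#' Per sample, one 18S-like scaffold hit against a same-family reference
#' that survives the standard filters (length >= 300 bp, e-value
#' <= 1e-9). Samples listed in `cfg$ssu_worrisome` additionally get a
#' hit against a foreign plant family; samples in `cfg$ssu_missing` get
#' no hit at all.
#'
#' @param samples Sample metadata data.frame.
#' @param cfg The [sim_config()].
#' @return List with `hits` (12-column hit data.frame) and `lineages`
#'   (data.frame `ref_id`, `family`, `lineage`).
#' @export
emit_ssu_fixtures <- function(samples, cfg) {
  hit_list <- list()
  lin_list <- list()
  plant_lineage <- function(family) {
    paste("Eukaryota", "Viridiplantae", "Streptophyta", family, sep = ";")
  }
  for (i in seq_len(nrow(samples))) {
    code <- samples$code[i]
    family <- samples$family[i]
    ref <- paste0("SSUREF.", code)
    lin_list[[length(lin_list) + 1L]] <-
      data.frame(ref_id = ref, family = family,
                 lineage = plant_lineage(family),
                 stringsAsFactors = FALSE)
    if (code %in% cfg$ssu_missing) next
    hit_list[[length(hit_list) + 1L]] <-
      hit_row(paste0(code, "_ssu1_sim", tolower(code)), ref, 99.3, 950)
    if (code %in% cfg$ssu_worrisome) {
      foreign <- "Foreignfamily"
      fref <- paste0("SSUREF.FOREIGN.", code)
      lin_list[[length(lin_list) + 1L]] <-
        data.frame(ref_id = fref, family = foreign,
                   lineage = plant_lineage(foreign),
                   stringsAsFactors = FALSE)
      hit_list[[length(hit_list) + 1L]] <-
        hit_row(paste0(code, "_ssu2_sim", tolower(code)), fref, 98.1, 620)
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else empty_hits()
  list(hits = hits, lineages = do.call(rbind, lin_list))
}

#' Write a simulation to disk in the pipeline's input layout
#'
#' Writes per-library FASTA files (`<CODE>.fasta`), per-pair hit tables
#' (`hits/pair_<A>_<B>.tsv`), the re-search table
#' (`research_hits.tsv`), SSU fixtures (`ssu_hits.tsv`,
#' `ssu_lineage.tsv`), the sample table (`samples.tsv`), the tree
#' (`tree.nwk`) and the truth labels (`truth.tsv`).
#'
#' @param sim A `"contam_sim"` from [simulate_contamination()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "contam_sim"))
  dir.create(file.path(dir, "hits"), recursive = TRUE,
             showWarnings = FALSE)
  for (code in names(sim$libraries)) {
    write_transcript_fasta(sim$libraries[[code]],
                           file.path(dir, paste0(code, ".fasta")))
  }
  for (key in names(sim$pair_hits)) {
    codes <- strsplit(key, "|", fixed = TRUE)[[1L]]
    write_tabular_hits(sim$pair_hits[[key]],
                       file.path(dir, "hits",
                                 sprintf("pair_%s_%s.tsv", codes[1L],
                                         codes[2L])))
  }
  write_tabular_hits(sim$research_hits,
                     file.path(dir, "research_hits.tsv"))
  write_tabular_hits(sim$ssu_hits, file.path(dir, "ssu_hits.tsv"))
  write_tsv(sim$ssu_lineages, file.path(dir, "ssu_lineage.tsv"))
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  writeLines(sim$newick, file.path(dir, "tree.nwk"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
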