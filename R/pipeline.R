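# End-to-end orchestration: pair screening -> per-pair thresholding ->
# candidate classification -> verdicts, summaries and file outputs, plus
# optional SSU validation and completeness summaries when their inputs
# are present.

#' Screen a set of libraries for cross-contamination
#'
#' Runs the in-memory pipeline: enumerate eligible pairs, reduce each
#' eligible pair's hits to per-query best matches, build the identity
#' histogram and detect the cutoff, flag candidates, classify them with
#' the re-search rule, and assign one verdict per sequence.
#'
#' @param libraries Named list (by code) of transcript data.frames.
#' @param pair_hits Named list of hit data.frames keyed by canonical
#'   pair key `"A|B"` (lexicographic order).
#' @param samples Sample metadata data.frame.
#' @param tree Consensus `"phylo"` or `NULL`.
#' @param research_hits Re-search hit data.frame (candidates vs
#'   non-candidate assemblies) or `NULL`; without it all candidates stay
#'   `unresolved_possible`.
#' @param bin_width,min_peak_support,smooth_window Threshold-detection
#'   parameters, see [identity_histogram()] and [find_cutoff()].
#' @param max_branches Pair-screening tree bound, see
#'   [decide_exclusion()].
#' @param close_branches,n_top Re-search classification parameters, see
#'   [classify_candidates()].
#' @return List with `pairs` ([eligible_pairs()] output), `histograms`,
#'   `thresholds`, `candidates`, `classified`, `verdicts` (one row per
#'   sequence across all libraries), and `tables`
#'   ([summarize_libraries()] output).
#' @export
screen_contamination <- function(libraries, pair_hits, samples,
                                 tree = NULL, research_hits = NULL,
                                 bin_width = 1, min_peak_support = 5,
                                 smooth_window = 1, max_branches = 2,
                                 close_branches = 2, n_top = 3) {
  stopifnot(is.list(libraries), length(libraries) >= 2L,
            !is.null(names(libraries)))
  ep <- eligible_pairs(samples, tree, max_branches = max_branches)

  histograms <- list()
  thresholds <- list()
  cand_list <- list()
  for (i in seq_len(nrow(ep$eligible))) {
    a <- ep$eligible$code_a[i]
    b <- ep$eligible$code_b[i]
    key <- pair_key(a, b)
    hits <- pair_hits[[key]]
    if (is.null(hits)) {
      warning("no hit table for eligible pair ", key, "; skipped")
      next
    }
    matches <- best_hit_matches(hits, pair = c(a, b))
    hist <- identity_histogram(matches$pct_identity,
                               bin_width = bin_width, pair = key)
    th <- suppressWarnings(find_cutoff(hist,
                                       min_peak_support = min_peak_support,
                                       smooth_window = smooth_window))
    histograms[[key]] <- hist
    thresholds[[key]] <- th
    cand_list[[key]] <- call_candidates(matches, th)
  }
  candidates <- do.call(rbind, cand_list) %||%
    call_candidates(data.frame(), structure(list(status = "no_peak"),
                                            class = "contam_threshold"))
  rownames(candidates) <- NULL

  classified <- classify_candidates(candidates, research_hits, samples,
                                    tree, close_branches = close_branches,
                                    n_top = n_top)
  verdicts <- do.call(rbind, lapply(libraries, assign_verdicts,
                                    classified = classified))
  rownames(verdicts) <- NULL

  list(pairs = ep, histograms = histograms, thresholds = thresholds,
       candidates = candidates, classified = classified,
       verdicts = verdicts, tables = summarize_libraries(verdicts))
}

#' Compare verdicts against simulator ground truth
#'
#' Precision and recall of the `verified_contaminant` call against the
#' truth labels, and donor-assignment accuracy among true positives.
#'
#' @param verdicts Verdict data.frame (`screen_contamination()$verdicts`).
#' @param truth Truth data.frame (`seq_id`, `is_contaminant`,
#'   `donor_sample`).
#' @return One-row data.frame: `n_true`, `n_called`, `tp`, `precision`,
#'   `recall`, `donor_accuracy` (`NA` when undefined).
#' @export
evaluate_against_truth <- function(verdicts, truth) {
  m <- match(verdicts$seq_id, truth$seq_id)
  is_true <- !is.na(m) & truth$is_contaminant[m]
  called <- verdicts$status == "verified_contaminant"
  tp <- called & is_true
  donor_ok <- tp & !is.na(verdicts$donor_sample) &
    verdicts$donor_sample == truth$donor_sample[m]
  data.frame(
    n_true = sum(is_true), n_called = sum(called), tp = sum(tp),
    precision = if (sum(called)) sum(tp) / sum(called) else NA_real_,
    recall = if (sum(is_true)) sum(tp) / sum(is_true) else NA_real_,
    donor_accuracy = if (sum(tp)) sum(donor_ok) / sum(tp) else NA_real_)
}

read_pair_hit_dir <- function(dir) {
  files <- list.files(dir, pattern = "^pair_[A-Z]{4}_[A-Z]{4}\\.tsv$",
                      full.names = TRUE)
  out <- list()
  for (f in files) {
    codes <- regmatches(basename(f),
                        gregexpr("[A-Z]{4}", basename(f)))[[1L]]
    out[[pair_key(codes[1L], codes[2L])]] <- parse_tabular_hits(f)
  }
  out
}

#' Run the file-based pipeline
#'
#' Reads all inputs from `input_dir` (the layout written by
#' [write_simulation()]: `samples.tsv`, `tree.nwk`, `<CODE>.fasta`,
#' `hits/pair_<A>_<B>.tsv`, optional `research_hits.tsv`,
#' `ssu_hits.tsv` + `ssu_lineage.tsv`, `ceg_counts.tsv`,
#' `busco_summary.tsv`), runs every applicable stage and writes reports,
#' the clean/contaminant FASTA split of every library, and a manifest
#' recording parameter values and input digests. Reruns on identical
#' inputs produce identical outputs.
#'
#' @param input_dir Input directory.
#' @param output_dir Output directory (created if needed).
#' @param params Named list overriding the screening parameters of
#'   [screen_contamination()], plus optionally `min_len`, `max_evalue`
#'   (SSU) and `busco_floor` (completeness).
#' @return Invisibly, the full results list (`screen` plus, when inputs
#'   exist, `ssu` and `completeness`).
#' @export
run_pipeline <- function(input_dir, output_dir, params = list()) {
  path <- function(...) file.path(input_dir, ...)
  for (f in c("samples.tsv", "tree.nwk")) {
    if (!file.exists(path(f))) {
      stop("required input '", f, "' not found in ", input_dir)
    }
  }
  samples <- read_sample_table(path("samples.tsv"))
  tree <- read_newick_tree(path("tree.nwk"))
  fasta <- path(paste0(samples$code, ".fasta"))
  if (!all(file.exists(fasta))) {
    stop("missing library FASTA file(s): ",
         paste(basename(fasta[!file.exists(fasta)]), collapse = ", "))
  }
  libraries <- lapply(fasta, read_transcript_fasta)
  names(libraries) <- samples$code
  pair_hits <- read_pair_hit_dir(path("hits"))
  research_hits <- if (file.exists(path("research_hits.tsv"))) {
    parse_tabular_hits(path("research_hits.tsv"))
  }

  p <- function(name, default) params[[name]] %||% default
  screen <- screen_contamination(
    libraries, pair_hits, samples, tree, research_hits,
    bin_width = p("bin_width", 1),
    min_peak_support = p("min_peak_support", 5),
    smooth_window = p("smooth_window", 1),
    max_branches = p("max_branches", 2),
    close_branches = p("close_branches", 2),
    n_top = p("n_top", 3))

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(output_dir, ...)
  write_excluded_pairs(screen$pairs$decisions, out("excluded_pairs.tsv"))
  write_threshold_report(screen$thresholds, out("thresholds.tsv"))
  dir.create(out("histograms"), showWarnings = FALSE)
  for (key in names(screen$histograms)) {
    codes <- strsplit(key, "|", fixed = TRUE)[[1L]]
    write_histogram(screen$histograms[[key]],
                    out("histograms", sprintf("pair_%s_%s.tsv",
                                              codes[1L], codes[2L])))
  }
  write_tsv(screen$verdicts, out("verdicts.tsv"))
  write_library_summary(screen$tables$summary, out("summary.tsv"))
  write_contamination_matrix(screen$tables$matrix,
                             out("contamination_matrix.tsv"))
  write_contaminant_pairs(screen$tables$pairs,
                          out("contaminant_pairs.tsv"))
  for (code in samples$code) {
    verd <- screen$verdicts[screen$verdicts$sample == code, ,
                            drop = FALSE]
    split <- split_library(libraries[[code]], verd)
    write_transcript_fasta(split$clean,
                           out(paste0(code, ".clean.fasta")))
    write_transcript_fasta(split$contaminant,
                           out(paste0(code, ".contam.fasta")))
  }

  results <- list(screen = screen)

  if (file.exists(path("ssu_hits.tsv")) &&
      file.exists(path("ssu_lineage.tsv"))) {
    ssu <- read_ssu_hits(path("ssu_hits.tsv"), path("ssu_lineage.tsv"))
    filtered <- filter_ssu_hits(ssu, min_len = p("min_len", 300),
                                max_evalue = p("max_evalue", 1e-9))
    assignments <- assign_scaffold_taxa(filtered)
    validations <- validate_samples(samples, assignments)
    write_validation_reports(validations, assignments,
                             out("ssu_validation.tsv"),
                             out("ssu_scaffolds.tsv"))
    results$ssu <- list(assignments = assignments,
                        validations = validations)
  }

  if (file.exists(path("ceg_counts.tsv")) ||
      file.exists(path("busco_summary.tsv"))) {
    ceg <- if (file.exists(path("ceg_counts.tsv"))) {
      read_ceg_counts(path("ceg_counts.tsv"))
    }
    busco <- if (file.exists(path("busco_summary.tsv"))) {
      read_busco_summary(path("busco_summary.tsv"))
    }
    records <- completeness_records(ceg, busco)
    write_tsv(records, out("completeness_records.tsv"))
    write_tsv(summarize_completeness(records),
              out("completeness_percentiles.tsv"))
    results$completeness <- records
  }

  write_manifest(input_dir, output_dir, params)
  invisible(results)
}

write_manifest <- function(input_dir, output_dir, params) {
  inputs <- sort(list.files(input_dir, recursive = TRUE,
                            full.names = TRUE))
  outputs <- sort(setdiff(
    list.files(output_dir, recursive = TRUE, full.names = FALSE),
    "manifest.tsv"))
  rows <- rbind(
    data.frame(kind = rep("parameter", length(params)),
               name = names(params) %||% character(),
               value = vapply(params, function(x)
                 paste(format(x), collapse = ","), character(1L)),
               stringsAsFactors = FALSE),
    data.frame(kind = "input",
               name = substring(inputs, nchar(input_dir) + 2L),
               value = unname(tools::md5sum(inputs)),
               stringsAsFactors = FALSE),
    data.frame(kind = "output", name = outputs,
               value = unname(tools::md5sum(
                 file.path(output_dir, outputs))),
               stringsAsFactors = FALSE))
  write_tsv(rows, file.path(output_dir, "manifest.tsv"))
}
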