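# Donor/recipient resolution for candidate contaminants and per-sequence
# verdicts.
#
# Each candidate sequence is re-searched against all non-candidate
# assemblies and the top hits examined. A candidate whose best alignments
# include a library from its own family, or one topologically very close
# in the consensus tree, is a legitimate shared sequence and is excluded
# from the contaminant list. A candidate whose best alignments are
# exclusively against distantly related libraries is verified as a
# contaminant; its donor is the library of the single best hit. A
# candidate with no re-search evidence at all stays in the grey
# "possible" category: verification requires positive distant-hit
# evidence.

VERDICT_LEVELS <- c("clean", "verified_contaminant", "excluded_close_taxon",
                    "unresolved_possible")

#' Classify candidate contaminants with the top-hit re-search rule
#'
#' For each candidate sequence (de-duplicated by `seq_id` across pairs)
#' the re-search hits are sorted best-first (bit score descending,
#' e-value ascending, identity descending, subject lexicographic), hits
#' against the candidate's own library are dropped, and the first
#' `n_top` hits are considered. If at least one considered hit belongs
#' to a library from the candidate's family, or to a library fewer than
#' `close_branches` edges away in the tree, the candidate is
#' `excluded_close_taxon`. Otherwise it is `verified_contaminant` and
#' the donor is the library of the best considered hit. A candidate with
#' no usable hits is `unresolved_possible`.
#'
#' Note the asymmetry with pair screening: there, pairs at a distance of
#' `max_branches` *or fewer* are excluded, while here the comparison is
#' strict (`< close_branches`). Both thresholds are configurable.
#'
#' @param candidates data.frame from [call_candidates()] (possibly
#'   concatenated over pairs).
#' @param research_hits Hit data.frame of candidate queries vs the
#'   non-candidate assemblies, or `NULL` when no re-search was run (all
#'   candidates then remain `unresolved_possible`).
#' @param samples Sample metadata data.frame.
#' @param tree Consensus `"phylo"`, or `NULL` to apply the family rule
#'   only.
#' @param close_branches Strict tree-distance bound below which a
#'   re-search subject counts as a close taxon (default 2).
#' @param n_top Number of best re-search hits considered (default 3).
#' @return data.frame with one row per distinct candidate `seq_id`:
#'   `seq_id`, `sample`, `status`, `donor_sample`, `partner_seq_id`,
#'   `evidence` (semicolon-separated `sample:identity` of the considered
#'   hits).
#' @export
classify_candidates <- function(candidates, research_hits, samples,
                                tree = NULL, close_branches = 2,
                                n_top = 3) {
  empty <- data.frame(seq_id = character(), sample = character(),
                      status = character(), donor_sample = character(),
                      partner_seq_id = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)

  # one record per candidate sequence; keep the highest-identity flagging
  ord <- order(candidates$seq_id, -candidates$identity,
               candidates$partner_seq_id, method = "radix")
  cand <- candidates[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand$seq_id), , drop = FALSE]

  dist <- if (!is.null(tree)) tree_distance_matrix(tree) else NULL
  fam_of <- stats::setNames(fold_taxon(samples$family), samples$code)

  hits_by_query <- NULL
  if (!is.null(research_hits) && nrow(research_hits) > 0L) {
    rh <- research_hits
    rh$subject_sample <- extract_sample_code(rh$subject_id)
    if (anyNA(rh$subject_sample)) {
      warning(sum(is.na(rh$subject_sample)),
              " re-search hit(s) with unparseable subject code skipped")
      rh <- rh[!is.na(rh$subject_sample), , drop = FALSE]
    }
    hits_by_query <- split(rh, rh$query_id)
  }

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    seq_id <- cand$seq_id[i]
    sample <- cand$sample[i]
    h <- hits_by_query[[seq_id]]
    if (!is.null(h)) h <- h[h$subject_sample != sample, , drop = FALSE]
    if (is.null(h) || nrow(h) == 0L) {
      return(data.frame(seq_id = seq_id, sample = sample,
                        status = "unresolved_possible",
                        donor_sample = NA_character_,
                        partner_seq_id = cand$partner_seq_id[i],
                        evidence = "", stringsAsFactors = FALSE))
    }
    hord <- order(-h$bitscore, h$evalue, -h$pct_identity, h$subject_id,
                  method = "radix")
    h <- h[hord, , drop = FALSE][seq_len(min(n_top, nrow(h))), ,
                                 drop = FALSE]
    subj <- h$subject_sample
    close <- vapply(subj, function(s) {
      fam_match <- !is.na(fam_of[sample]) && !is.na(fam_of[s]) &&
        nzchar(fam_of[sample]) && fam_of[sample] == fam_of[s]
      if (fam_match) return(TRUE)
      if (!is.null(dist) && sample %in% rownames(dist) &&
          s %in% rownames(dist)) {
        return(unname(dist[sample, s]) < close_branches)
      }
      FALSE
    }, logical(1L))
    status <- if (any(close)) "excluded_close_taxon" else
      "verified_contaminant"
    donor <- if (status == "verified_contaminant") subj[1L] else
      NA_character_
    data.frame(seq_id = seq_id, sample = sample, status = status,
               donor_sample = donor,
               partner_seq_id = cand$partner_seq_id[i],
               evidence = paste(sprintf("%s:%.2f", subj, h$pct_identity),
                                collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign a verdict to every sequence of a library
#'
#' Non-candidate sequences are `clean`; candidate sequences take their
#' re-search classification. Exactly one verdict is produced per
#' sequence.
#'
#' @param records Library transcript data.frame
#'   ([read_transcript_fasta()]).
#' @param classified Classified candidates from [classify_candidates()]
#'   (any subset; rows for other libraries are ignored).
#' @return data.frame with `seq_id`, `sample`, `status`, `donor_sample`,
#'   `partner_seq_id`, one row per input record, input order preserved.
#' @export
assign_verdicts <- function(records, classified) {
  sample <- unique(records$sample_code)
  cl <- classified[classified$sample %in% sample, , drop = FALSE]
  unknown <- setdiff(cl$seq_id, records$seq_id)
  if (length(unknown)) {
    stop("candidate(s) reference unknown sequence id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  m <- match(records$seq_id, cl$seq_id)
  data.frame(
    seq_id = records$seq_id,
    sample = records$sample_code,
    status = ifelse(is.na(m), "clean", cl$status[m]),
    donor_sample = ifelse(is.na(m), NA_character_, cl$donor_sample[m]),
    partner_seq_id = ifelse(is.na(m), NA_character_,
                            cl$partner_seq_id[m]),
    stringsAsFactors = FALSE)
}

#' Split a library into clean and contaminant record sets
#'
#' Only `verified_contaminant` sequences go to the contaminant set;
#' `clean`, `excluded_close_taxon` and `unresolved_possible` sequences
#' stay in the clean set (the grey "possible" category is counted in the
#' summary but not removed). Input order is preserved within each set
#' and every record appears in exactly one of them.
#'
#' @param records Library transcript data.frame.
#' @param verdicts Verdicts for this library from [assign_verdicts()].
#' @return List with `clean` and `contaminant` record data.frames.
#' @export
split_library <- function(records, verdicts) {
  m <- match(records$seq_id, verdicts$seq_id)
  if (anyNA(m)) {
    stop("missing verdict for sequence(s): ",
         paste(utils::head(records$seq_id[is.na(m)], 5L), collapse = ", "))
  }
  contam <- verdicts$status[m] == "verified_contaminant"
  list(clean = records[!contam, , drop = FALSE],
       contaminant = records[contam, , drop = FALSE])
}

#' Summarise verdicts across libraries
#'
#' Produces the per-library summary table (total, contaminant, clean and
#' possible-contaminant counts, plus the number of verified contaminants
#' elsewhere whose donor is this library), the contamination matrix
#' (rows: contaminated libraries, columns: contaminating libraries,
#' diagonal structurally absent), and the contaminant pair list
#' (contaminant sequence first, its orthologous partner second).
#' `excluded_close_taxon` sequences count as clean in the summary.
#'
#' @param verdicts Verdict data.frame over all libraries (rbind of
#'   [assign_verdicts()] outputs).
#' @return List with `summary` (data.frame), `matrix` (numeric matrix,
#'   `NA` diagonal) and `pairs` (data.frame `contaminant_seq_id`,
#'   `partner_seq_id`).
#' @export
summarize_libraries <- function(verdicts) {
  stopifnot(all(verdicts$status %in% VERDICT_LEVELS))
  codes <- sort(unique(verdicts$sample))
  ver <- verdicts[verdicts$status == "verified_contaminant", ,
                  drop = FALSE]
  summary <- do.call(rbind, lapply(codes, function(code) {
    v <- verdicts[verdicts$sample == code, , drop = FALSE]
    n_contaminant <- sum(v$status == "verified_contaminant")
    n_possible <- sum(v$status == "unresolved_possible")
    data.frame(sample = code, n_total = nrow(v),
               n_contaminant = n_contaminant,
               n_clean = nrow(v) - n_contaminant - n_possible,
               n_possible = n_possible,
               n_contaminant_in_others =
                 sum(ver$donor_sample == code, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  mat <- matrix(0, nrow = length(codes), ncol = length(codes),
                dimnames = list(contaminated = codes,
                                contaminating = codes))
  if (nrow(ver) > 0L) {
    tab <- table(ver$sample, ver$donor_sample)
    mat[rownames(tab), colnames(tab)] <- tab
  }
  diag(mat) <- NA_real_

  list(summary = summary, matrix = mat,
       pairs = data.frame(contaminant_seq_id = ver$seq_id,
                          partner_seq_id = ver$partner_seq_id,
                          stringsAsFactors = FALSE))
}

#' Write the per-library contamination summary
#' @param summary `summary` element of [summarize_libraries()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_library_summary <- function(summary, path) {
  write_tsv(summary, path)
  invisible(path)
}

#' Write the contamination matrix
#' @param matrix `matrix` element of [summarize_libraries()].
#' @param path Output TSV with row and column headers of sample codes.
#' @return `path`, invisibly.
#' @export
write_contamination_matrix <- function(matrix, path) {
  df <- data.frame(contaminated = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Write the contaminant pair list
#' @param pairs `pairs` element of [summarize_libraries()].
#' @param path Output TSV (`contaminant_seq_id`, `partner_seq_id`).
#' @return `path`, invisibly.
#' @export
write_contaminant_pairs <- function(pairs, path) {
  write_tsv(pairs, path)
  invisible(path)
}
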