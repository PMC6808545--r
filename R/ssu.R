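# 18S/SSU-based sample validation.
#
# Assembled scaffolds are searched against a lineage-annotated reference
# set of nuclear 18S rRNA sequences (e.g. the SILVA SSU database). The
# reference with the lowest e-value indicates the scaffold's likely
# taxonomic origin. Short or weak alignments (< 300 bp or e-value
# > 1e-9) tend to match several distantly related species and are
# ignored. A sample is validated when at least one surviving scaffold
# assignment is to the expected taxonomic family; it is flagged as
# "worrisome contamination" when any assignment is to a *plant* family
# other than the expected one.

#' Read SSU search hits with reference lineage annotation
#'
#' Joins a 12-column tabular hit file (scaffold queries vs 18S
#' references) with a reference lineage table
#' (`ref_id<TAB>family<TAB>lineage`). References are annotated from the
#' table, not parsed from free-text headers, because reference header
#' formats vary between database releases.
#'
#' @param hits_path 12-column tabular hits file.
#' @param lineage_path Reference lineage TSV with header columns
#'   `ref_id`, `family`, `lineage`.
#' @return data.frame with `scaffold_id`, `sample`, `ref_id`,
#'   `ref_family`, `ref_lineage`, `aln_length`, `evalue`,
#'   `pct_identity`.
#' @export
read_ssu_hits <- function(hits_path, lineage_path) {
  hits <- parse_tabular_hits(hits_path)
  lin <- utils::read.delim(lineage_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("ref_id", "family", "lineage")
  if (!all(required %in% names(lin))) {
    stop("lineage table '", lineage_path, "' must have columns: ",
         paste(required, collapse = ", "))
  }
  m <- match(hits$subject_id, lin$ref_id)
  if (anyNA(m) && nrow(hits) > 0L) {
    warning(sum(is.na(m)), " SSU hit(s) against reference(s) absent ",
            "from the lineage table; their family is NA")
  }
  data.frame(scaffold_id = hits$query_id,
             sample = extract_sample_code(hits$query_id),
             ref_id = hits$subject_id,
             ref_family = lin$family[m],
             ref_lineage = lin$lineage[m],
             aln_length = hits$aln_length,
             evalue = hits$evalue,
             pct_identity = hits$pct_identity,
             stringsAsFactors = FALSE)
}

#' Filter SSU hits on alignment length and e-value
#'
#' Alignments under `min_len` bp or with e-values greater than
#' `max_evalue` often align to several distantly related species and are
#' dropped. Both thresholds are inclusive (a 300 bp, 1e-9 hit survives):
#' the filter removes what is *under* the length floor or *greater than*
#' the e-value ceiling. Input order is preserved and the filter is
#' idempotent.
#'
#' @param hits SSU hit data.frame ([read_ssu_hits()]).
#' @param min_len Minimum alignment length in bp (default 300).
#' @param max_evalue Maximum e-value (default 1e-9).
#' @return Row subset of `hits`.
#' @export
filter_ssu_hits <- function(hits, min_len = 300, max_evalue = 1e-9) {
  hits[hits$aln_length >= min_len & hits$evalue <= max_evalue, ,
       drop = FALSE]
}

#' Assign each scaffold to its best reference
#'
#' Per scaffold, the hit with the lowest e-value wins; ties are broken
#' by the larger identity x length product, then by reference id
#' (lexicographic), so the assignment is deterministic under input
#' permutation. Scaffolds with no hits receive no assignment.
#'
#' @param hits Filtered SSU hit data.frame.
#' @return data.frame with one row per assigned scaffold (same columns
#'   as the input).
#' @export
assign_scaffold_taxa <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  score <- hits$pct_identity * hits$aln_length
  ord <- order(hits$scaffold_id, hits$evalue, -score, hits$ref_id,
               method = "radix")
  out <- hits[ord, , drop = FALSE]
  out <- out[!duplicated(out$scaffold_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate one sample from its SSU scaffold assignments
#'
#' `validated` is `TRUE` when at least one assignment is to the sample's
#' expected family (case-insensitive). `worrisome` is `TRUE` when at
#' least one assignment is to a plant family different from the expected
#' one; plant membership is decided by matching `plant_clades` against
#' the reference lineage, and non-plant assignments (bacterial, fungal,
#' metazoan commensals) never set the flag. A sample with no surviving
#' assignments is neither validated nor worrisome -- typically a failure
#' to assemble the 18S sequence.
#'
#' @param sample One-row sample metadata (or a list with `code` and
#'   `family`).
#' @param assignments Scaffold assignments ([assign_scaffold_taxa()]) for
#'   this sample's scaffolds.
#' @param plant_clades Lineage labels marking a reference as plant
#'   (default `"Viridiplantae"`).
#' @return One-row data.frame: `sample`, `validated`, `worrisome`,
#'   `n_ssu_scaffolds`, `assigned_families` (collapsed
#'   `family:count` pairs).
#' @export
validate_sample <- function(sample, assignments,
                            plant_clades = "Viridiplantae") {
  code <- sample$code
  a <- assignments[!is.na(assignments$sample) &
                     assignments$sample == code, , drop = FALSE]
  if (nrow(a) == 0L) {
    return(data.frame(sample = code, validated = FALSE, worrisome = FALSE,
                      n_ssu_scaffolds = 0L, assigned_families = "",
                      stringsAsFactors = FALSE))
  }
  expected <- fold_taxon(sample$family)
  fam <- fold_taxon(a$ref_family)
  lineage_parts <- strsplit(a$ref_lineage %||% "", ";")
  is_plant <- vapply(lineage_parts, function(p) {
    any(fold_taxon(p) %in% fold_taxon(plant_clades))
  }, logical(1L))
  validated <- any(!is.na(fam) & fam == expected)
  worrisome <- any(!is.na(fam) & is_plant & fam != expected)
  tab <- sort(table(a$ref_family), decreasing = TRUE)
  data.frame(sample = code, validated = validated, worrisome = worrisome,
             n_ssu_scaffolds = nrow(a),
             assigned_families = paste(sprintf("%s:%d", names(tab),
                                               as.integer(tab)),
                                       collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Validate all samples from SSU assignments
#'
#' @param samples Sample metadata data.frame.
#' @param assignments Scaffold assignments across all samples.
#' @inheritParams validate_sample
#' @return data.frame with one row per sample (see [validate_sample()]).
#' @export
validate_samples <- function(samples, assignments,
                             plant_clades = "Viridiplantae") {
  out <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    validate_sample(samples[i, , drop = FALSE], assignments,
                    plant_clades = plant_clades)
  }))
  rownames(out) <- NULL
  out
}

#' Write the two SSU validation reports
#'
#' The first file holds the per-sample judgement (validated / worrisome
#' flags); the second, more detailed, lists each scaffold identified as
#' 18S-like and the reference it matched.
#'
#' @param validations data.frame from [validate_samples()].
#' @param assignments Scaffold assignments ([assign_scaffold_taxa()]).
#' @param summary_path,detail_path Output TSV paths.
#' @return Character vector of the two paths, invisibly.
#' @export
write_validation_reports <- function(validations, assignments,
                                     summary_path, detail_path) {
  write_tsv(validations, summary_path)
  detail_cols <- c("scaffold_id", "ref_id", "ref_family", "evalue",
                   "aln_length")
  if (nrow(assignments) == 0L) {
    detail <- data.frame(scaffold_id = character(), ref_id = character(),
                         ref_family = character(), evalue = numeric(),
                         aln_length = numeric(), stringsAsFactors = FALSE)
  } else {
    detail <- assignments[detail_cols]
  }
  write_tsv(detail, detail_path)
  invisible(c(summary_path, detail_path))
}
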