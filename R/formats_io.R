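# Readers and writers for every external format the pipeline touches, and
# the canonical in-memory records the other stages consume:
#   * transcript records: data.frame(seq_id, sample_code, sequence)
#   * alignment hits:     data.frame in the 12-column tabular search dialect
#   * sample metadata:    data.frame(code, species, family, clade)
#   * phylogeny:          an ape "phylo" whose tips are library codes

HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = numeric(),
             mismatches = numeric(), gap_opens = numeric(),
             q_start = numeric(), q_end = numeric(),
             s_start = numeric(), s_end = numeric(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Extract the 4-letter library code from a scaffold identifier
#'
#' Scaffold names embed the library's 4-letter code as a leading prefix
#' followed by a `_` or `-` separator (e.g. `AEPI_1_lineum`). Identifiers
#' that do not follow this grammar yield `NA`.
#'
#' @param seq_id Character vector of sequence identifiers.
#' @return Character vector of codes, `NA` where no valid code is found.
#' @export
#' @examples
#' extract_sample_code(c("AEPI_1_lineum", "badid"))
extract_sample_code <- function(seq_id) {
  code <- substr(seq_id, 1L, 4L)
  sep <- substr(seq_id, 5L, 5L)
  ok <- is_valid_code(code) & sep %in% c("_", "-")
  code[!ok] <- NA_character_
  code
}

#' Read assembled transcripts from a FASTA file
#'
#' Headers are truncated at the first whitespace to form `seq_id`; the
#' library code is parsed from the leading 4 characters of the identifier.
#' Records whose identifier does not start with a valid code are kept with
#' `sample_code = NA` and a warning.
#'
#' @param path FASTA file.
#' @return data.frame with columns `seq_id`, `sample_code`, `sequence`,
#'   in file order.
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("failed to parse FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) {
    return(data.frame(seq_id = character(), sample_code = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  codes <- extract_sample_code(ids)
  if (anyNA(codes)) {
    warning(sum(is.na(codes)), " record(s) in '", path,
            "' lack a valid leading 4-letter library code")
  }
  data.frame(seq_id = ids, sample_code = codes,
             sequence = as.character(set), stringsAsFactors = FALSE)
}

#' Write transcript records as FASTA
#'
#' Standard multi-record FASTA with 60-column sequence wrapping; a
#' round-trip with [read_transcript_fasta()] preserves identifiers and
#' sequences exactly.
#'
#' @param records data.frame with `seq_id` and `sequence` columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("seq_id", "sequence") %in% names(records)))
  set <- Biostrings::DNAStringSet(stats::setNames(records$sequence,
                                                  records$seq_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Parse a 12-column tabular similarity-search file
#'
#' Reads the standard tab-separated 12-column search output dialect
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query/subject coordinates, e-value, bit score). Lines starting
#' with `#` are comments. Column count and numeric fields are validated;
#' no data row is silently dropped.
#'
#' @param path Tabular hits file.
#' @return data.frame with the 12 canonical columns, rows in input order.
#' @export
parse_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (!any(keep)) return(empty_hits())
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 12L)) {
    bad <- which(keep)[which(nf != 12L)[1L]]
    stop("row ", bad, " of '", path, "' has ", nf[which(nf != 12L)[1L]],
         " columns (12 expected)")
  }
  m <- matrix(unlist(rows, use.names = FALSE), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(keep)[which(rowSums(is.na(num)) > 0L)[1L]]
    stop("non-numeric value in numeric field at row ", bad, " of '",
         path, "'")
  }
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     stringsAsFactors = FALSE)
  hits[HIT_COLUMNS[3:12]] <- as.data.frame(num)
  validate_hits(hits, path)
  hits
}

validate_hits <- function(hits, label = "hits") {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("percent identity outside [0, 100] in ", label)
  }
  if (any(hits$aln_length < 1)) stop("alignment length < 1 in ", label)
  if (any(hits$evalue < 0)) stop("negative e-value in ", label)
  invisible(hits)
}

#' Write hits in the 12-column tabular dialect
#'
#' @param hits data.frame as returned by [parse_tabular_hits()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  utils::write.table(hits[HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the sample metadata table
#'
#' Tab-separated with mandatory header `code`, `species`, `family`,
#' `clade`. Headers are required (no positional mode) because silently
#' swapped columns are the classic failure with this kind of table.
#' Duplicate codes are rejected.
#'
#' @param path TSV file.
#' @return data.frame with columns `code`, `species`, `family`, `clade`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("code", "species", "family", "clade")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup)) {
    stop("duplicate sample code(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  }
  bad <- df$code[!is_valid_code(df$code)]
  if (length(bad)) {
    stop("invalid sample code(s) (expected 4 uppercase letters): ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Write a sample metadata table
#' @param samples data.frame with `code`, `species`, `family`, `clade`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  stopifnot(all(c("code", "species", "family", "clade") %in% names(samples)))
  write_tsv(samples[c("code", "species", "family", "clade")], path)
  invisible(path)
}

#' Read the consensus phylogeny
#'
#' Reads a single-tree Newick file whose leaf labels are library codes.
#' Branch lengths are ignored throughout the pipeline: only the topology
#' (edge counts between leaves) is used. Duplicate or invalid leaf names
#' are rejected.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("failed to parse Newick tree in '", path, "'")
  if (inherits(tree, "multiPhylo")) {
    stop("'", path, "' contains more than one tree; a single consensus ",
         "tree is expected")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf name(s) in tree: ", paste(dup, collapse = ", "))
  }
  bad <- tree$tip.label[!is_valid_code(tree$tip.label)]
  if (length(bad)) {
    stop("tree leaf name(s) are not valid 4-letter library codes: ",
         paste(bad, collapse = ", "))
  }
  tree
}
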