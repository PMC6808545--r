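`%||%` <- function(a, b) if (is.null(a)) b else a

# Case-folded, whitespace-trimmed family comparison key. No synonym
# resolution: the sample table is the taxonomic authority.
fold_taxon <- function(x) tolower(trimws(as.character(x)))

#' Generate valid library codes
#'
#' Produces `n` distinct 4-letter uppercase library codes of the kind used
#' to name assembled transcriptome libraries (`LAAA`, `LAAB`, ...).
#'
#' @param n Number of codes (1 to 17576).
#' @return Character vector of length `n`.
#' @export
#' @examples
#' make_library_codes(3)
make_library_codes <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1L, n <= 26L^3)
  idx <- seq_len(n) - 1L
  paste0("L",
         LETTERS[idx %/% 676L + 1L],
         LETTERS[(idx %/% 26L) %% 26L + 1L],
         LETTERS[idx %% 26L + 1L])
}

# Canonical unordered pair key: codes joined in lexicographic order.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

is_valid_code <- function(x) {
  grepl("^[A-Z]{4}$", x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}
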