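# Per-pair percent-identity distribution of best-matched sequences and
# detection of the contamination cutoff.
#
# Between two eligible libraries the identity distribution of matched
# sequences peaks at the evolutionary divergence of the two species. A
# cross-contaminated pair additionally carries many matches near 100%
# identity. Scanning the histogram downward from 100%, the first local
# minimum below that near-100% peak separates contaminant matches from
# ordinarily diverged orthologs and is used as the per-pair cutoff.

#' Per-query best matches between two libraries
#'
#' Reduces raw hits to one match per query sequence: the hit with the
#' highest bit score, ties broken by lower e-value, then higher percent
#' identity, then subject identifier (lexicographic), so the result is
#' deterministic under permutation of the input rows. Matches are counted
#' per sequence, not per alignment.
#'
#' @param hits Hit data.frame ([parse_tabular_hits()]), restricted to
#'   queries and subjects of the two libraries of interest.
#' @param pair Optional character vector of the two library codes; rows
#'   whose query and subject samples are not these two (in either
#'   direction) are dropped first.
#' @return data.frame with one row per query: `query_id`, `subject_id`,
#'   `query_sample`, `subject_sample`, `pct_identity`.
#' @export
best_hit_matches <- function(hits, pair = NULL) {
  qs <- extract_sample_code(hits$query_id)
  ss <- extract_sample_code(hits$subject_id)
  keep <- !is.na(qs) & !is.na(ss) & qs != ss
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L)
    keep <- keep & ((qs == pair[1L] & ss == pair[2L]) |
                      (qs == pair[2L] & ss == pair[1L]))
  }
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      query_sample = character(),
                      subject_sample = character(),
                      pct_identity = numeric(), stringsAsFactors = FALSE))
  }
  h$query_sample <- qs[keep]
  h$subject_sample <- ss[keep]
  ord <- order(h$query_id, -h$bitscore, h$evalue, -h$pct_identity,
               h$subject_id, method = "radix")
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h[c("query_id", "subject_id", "query_sample", "subject_sample",
      "pct_identity")]
}

#' Bin matched-sequence identities into a histogram
#'
#' Counts per half-open bin `[edge, edge + bin_width)` over the full
#' `[0, 100]` range; an identity of exactly 100 is assigned to the top
#' bin. The bin width must divide 100 evenly.
#'
#' @param identities Numeric vector of percent identities in `[0, 100]`.
#' @param bin_width Bin width in percentage points (default 1, i.e. one
#'   bin per percentage identity value).
#' @param pair Optional pair label carried through to reports.
#' @return Object of class `"identity_histogram"`: list with `counts`
#'   (named by bin lower edge, ascending), `bin_width`, `n_total`, `pair`.
#' @export
identity_histogram <- function(identities, bin_width = 1, pair = NULL) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive number")
  }
  nbin <- 100 / bin_width
  if (abs(nbin - round(nbin)) > 1e-9) {
    stop("bin_width must divide 100 evenly")
  }
  nbin <- as.integer(round(nbin))
  identities <- identities[!is.na(identities)]
  if (any(identities < 0 | identities > 100)) {
    stop("identities must lie in [0, 100]")
  }
  edges <- (seq_len(nbin) - 1L) * bin_width
  idx <- pmin(floor(identities / bin_width) + 1L, nbin)
  counts <- tabulate(idx, nbins = nbin)
  names(counts) <- format(edges, trim = TRUE, scientific = FALSE)
  structure(list(counts = counts, bin_width = bin_width,
                 n_total = length(identities), pair = pair),
            class = "identity_histogram")
}

#' Build an identity histogram from explicit bin counts
#'
#' Wraps a named count vector (names are bin lower edges) as an
#' `"identity_histogram"`, e.g. for histograms assembled by hand or read
#' back from a report.
#'
#' @param counts Named non-negative numeric vector; names are numeric bin
#'   lower edges in `[0, 100]`.
#' @param bin_width Bin width the edges refer to.
#' @param pair Optional pair label.
#' @return An `"identity_histogram"` object, bins sorted ascending.
#' @export
as_identity_histogram <- function(counts, bin_width = 1, pair = NULL) {
  edges <- suppressWarnings(as.numeric(names(counts)))
  if (is.null(names(counts)) || anyNA(edges)) {
    stop("counts must be named by numeric bin lower edges")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(edges < 0 | edges > 100)) stop("bin edges must lie in [0, 100]")
  ord <- order(edges)
  counts <- counts[ord]
  names(counts) <- format(edges[ord], trim = TRUE, scientific = FALSE)
  structure(list(counts = counts, bin_width = bin_width,
                 n_total = sum(counts), pair = pair),
            class = "identity_histogram")
}

#' @export
print.identity_histogram <- function(x, ...) {
  cat("identity histogram", if (!is.null(x$pair)) paste0("[", x$pair, "]"),
      "- ", x$n_total, "matches,", sum(x$counts > 0), "occupied bins of",
      x$bin_width, "%\n")
  invisible(x)
}

#' Detect the contamination cutoff in an identity histogram
#'
#' Scans bins downward from 100% identity. If the total (unsmoothed)
#' count in the near-100% region (bin edges >= 99) is below
#' `min_peak_support` there is no contamination peak and no cutoff is
#' returned (`status = "no_peak"`). Otherwise the cutoff is the lower
#' edge of the first bin, in descending order, whose (optionally
#' smoothed) count is no larger than the bin above and strictly smaller
#' than the bin below -- the first local minimum under the peak. If the
#' counts never rise again before the bottom of the histogram (a single
#' mass at ~100%, as for an unexcluded conspecific pair) the histogram is
#' degenerate and no cutoff is returned.
#'
#' @param hist An `"identity_histogram"`.
#' @param min_peak_support Minimum number of matches in bins at >= 99%
#'   identity for a peak to be considered present (default 5; suppresses
#'   single-spurious-hit peaks).
#' @param smooth_window Odd moving-average window in bins applied before
#'   the minimum scan; 1 (the default) disables smoothing.
#' @return Object of class `"contam_threshold"`: list with `pair`,
#'   `status` (`found`, `no_peak` or `degenerate`), `cutoff` (bin lower
#'   edge, NA unless found), `peak_support`, `n_total`.
#' @export
#' @examples
#' h <- as_identity_histogram(
#'   c(`100` = 50, `99` = 30, `98` = 5, `97` = 2,
#'     `96` = 10, `95` = 40, `94` = 60))
#' find_cutoff(h)$cutoff  # 97
find_cutoff <- function(hist, min_peak_support = 5, smooth_window = 1) {
  stopifnot(inherits(hist, "identity_histogram"))
  if (!is.numeric(smooth_window) || length(smooth_window) != 1L ||
      smooth_window < 1 || smooth_window %% 2 != 1) {
    stop("smooth_window must be an odd positive integer")
  }
  edges <- as.numeric(names(hist$counts))
  ord <- order(edges, decreasing = TRUE)
  edges <- edges[ord]
  raw <- as.numeric(hist$counts[ord])

  peak_support <- sum(raw[edges >= 99])
  result <- function(status, cutoff = NA_real_) {
    structure(list(pair = hist$pair, status = status, cutoff = cutoff,
                   peak_support = peak_support, n_total = hist$n_total),
              class = "contam_threshold")
  }
  if (peak_support < min_peak_support) return(result("no_peak"))

  counts <- raw
  if (smooth_window > 1L) {
    sm <- as.numeric(stats::filter(raw, rep(1 / smooth_window,
                                            smooth_window), sides = 2))
    counts <- ifelse(is.na(sm), raw, sm)
  }

  n <- length(counts)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (counts[i] <= counts[i - 1L] && counts[i] < counts[i + 1L]) {
        return(result("found", edges[i]))
      }
    }
  }
  warning("identity histogram", if (!is.null(hist$pair))
    paste0(" [", hist$pair, "]"),
    " is unimodal near 100%: no cutoff below the peak")
  result("degenerate")
}

#' @export
print.contam_threshold <- function(x, ...) {
  cat("contamination threshold",
      if (!is.null(x$pair)) paste0("[", x$pair, "]"), "- status:",
      x$status,
      if (x$status == "found") paste0("cutoff: ", x$cutoff, "%"),
      paste0("(peak support ", x$peak_support, " of ", x$n_total,
             " matches)\n"))
  invisible(x)
}

#' Flag candidate contaminant sequences above the cutoff
#'
#' Every best match whose identity is at or above the pair's cutoff
#' flags both member sequences as potential contaminants ("one or both
#' libraries" may hold the foreign copy): two candidate records are
#' emitted per match, one per library, each naming its partner. Ties at
#' exactly the cutoff are flagged (inclusive comparison), which is
#' conservative toward contamination detection.
#'
#' @param matches data.frame from [best_hit_matches()].
#' @param threshold A `"contam_threshold"`; when its status is not
#'   `"found"` no candidates are produced.
#' @return data.frame with `seq_id`, `sample`, `partner_seq_id`,
#'   `partner_sample`, `identity`.
#' @export
call_candidates <- function(matches, threshold) {
  stopifnot(inherits(threshold, "contam_threshold"))
  empty <- data.frame(seq_id = character(), sample = character(),
                      partner_seq_id = character(),
                      partner_sample = character(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (threshold$status != "found" || nrow(matches) == 0L) return(empty)
  sel <- matches[matches$pct_identity >= threshold$cutoff, , drop = FALSE]
  if (nrow(sel) == 0L) return(empty)
  out <- data.frame(
    seq_id = c(sel$query_id, sel$subject_id),
    sample = c(sel$query_sample, sel$subject_sample),
    partner_seq_id = c(sel$subject_id, sel$query_id),
    partner_sample = c(sel$subject_sample, sel$query_sample),
    identity = c(sel$pct_identity, sel$pct_identity),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a per-pair histogram dump
#' @param hist An `"identity_histogram"`.
#' @param path Output TSV (`bin_lower`, `count`).
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "identity_histogram"))
  write_tsv(data.frame(bin_lower = as.numeric(names(hist$counts)),
                       count = as.numeric(hist$counts)), path)
  invisible(path)
}

#' Write the per-pair threshold report
#'
#' @param thresholds List of `"contam_threshold"` objects whose `pair`
#'   labels are `"A|B"` keys.
#' @param path Output TSV (`code_a`, `code_b`, `status`, `cutoff`,
#'   `n_matches`, `peak_support`).
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(thresholds, path) {
  rows <- lapply(thresholds, function(th) {
    codes <- strsplit(th$pair %||% "NA|NA", "|", fixed = TRUE)[[1L]]
    data.frame(code_a = codes[1L], code_b = codes[2L], status = th$status,
               cutoff = th$cutoff, n_matches = th$n_total,
               peak_support = th$peak_support, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows) %||%
              data.frame(code_a = character(), code_b = character(),
                         status = character(), cutoff = numeric(),
                         n_matches = integer(), peak_support = numeric()),
            path)
  invisible(path)
}
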