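# Transcriptome completeness summaries from external tool reports.
#
# Two completeness proxies are computed from report files (the tools
# themselves are run externally): the fraction of the 248 core
# eukaryotic genes (CEGs) recovered by conditional reciprocal best BLAST,
# and the BUSCO abundance, defined as 100 minus the BUSCO missing
# percentage. Libraries below a BUSCO-abundance floor (57.5% by default)
# can be flagged for exclusion from downstream taxonomic analyses.

N_CEGS <- 248L

#' CEG abundance
#'
#' Percentage of the 248 core eukaryotic genes with a conditional
#' reciprocal best BLAST hit: `100 * ceg_hits / 248`.
#'
#' @param ceg_hits Integer count(s) in `[0, 248]`.
#' @return Percentage(s) in `[0, 100]`.
#' @export
#' @examples
#' ceg_abundance(124)  # 50
ceg_abundance <- function(ceg_hits) {
  if (any(is.na(ceg_hits)) || any(ceg_hits < 0 | ceg_hits > N_CEGS)) {
    stop("ceg_hits must lie in [0, ", N_CEGS, "]")
  }
  100 * ceg_hits / N_CEGS
}

#' BUSCO abundance
#'
#' 100 minus the BUSCO missing percentage, i.e. the percentage of BUSCO
#' genes recovered completely or as fragments.
#'
#' @param missing_pct BUSCO missing percentage(s) in `[0, 100]`.
#' @return Percentage(s) in `[0, 100]`.
#' @export
#' @examples
#' busco_abundance(37.5)  # 62.5
busco_abundance <- function(missing_pct) {
  if (any(is.na(missing_pct)) ||
      any(missing_pct < 0 | missing_pct > 100)) {
    stop("missing_pct must lie in [0, 100]")
  }
  100 - missing_pct
}

#' Percentile summary of a metric across samples
#'
#' One row per requested percentile, computed with linear interpolation
#' between closest ranks ([stats::quantile()] type 7) by default. The
#' convention is configurable because published summaries rarely state
#' theirs.
#'
#' @param values Non-empty numeric vector.
#' @param percentiles Percentile levels in `[0, 100]` (default
#'   5, 25, 50, 75, 95).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return data.frame with columns `percentile` and `value`, value
#'   non-decreasing in percentile.
#' @export
#' @examples
#' percentile_summary(1:100)
percentile_summary <- function(values, percentiles = c(5, 25, 50, 75, 95),
                               type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("values must be non-empty")
  if (any(percentiles < 0 | percentiles > 100)) {
    stop("percentiles must lie in [0, 100]")
  }
  q <- stats::quantile(values, probs = percentiles / 100, type = type,
                       names = FALSE)
  data.frame(percentile = percentiles, value = q)
}

#' Build per-sample completeness records from report tables
#'
#' @param ceg data.frame with columns `sample` and `ceg_hits` (CEG hit
#'   counts from a CRBB report), or `NULL`.
#' @param busco data.frame with columns `sample`, `set`
#'   (`eukaryota`/`embryophyta`), `complete`, `fragment`, `missing`
#'   (BUSCO short-summary percentages), or `NULL`.
#' @return data.frame with one row per sample x BUSCO set (or per sample
#'   when only one table is given) carrying `ceg_abundance`,
#'   `busco_abundance` and `busco_found` (complete + fragment, with
#'   complete alone in `busco_complete`).
#' @export
completeness_records <- function(ceg = NULL, busco = NULL) {
  if (is.null(ceg) && is.null(busco)) {
    stop("at least one of 'ceg' and 'busco' is required")
  }
  if (!is.null(ceg)) {
    stopifnot(all(c("sample", "ceg_hits") %in% names(ceg)))
    ceg$ceg_abundance <- ceg_abundance(ceg$ceg_hits)
  }
  if (!is.null(busco)) {
    stopifnot(all(c("sample", "set", "complete", "fragment", "missing")
                  %in% names(busco)))
    busco$busco_abundance <- busco_abundance(busco$missing)
    busco$busco_found <- busco$complete + busco$fragment
    names(busco)[names(busco) == "complete"] <- "busco_complete"
    names(busco)[names(busco) == "fragment"] <- "busco_fragment"
    names(busco)[names(busco) == "missing"] <- "busco_missing"
    names(busco)[names(busco) == "set"] <- "busco_set"
  }
  if (is.null(busco)) return(ceg)
  if (is.null(ceg)) return(busco)
  merge(busco, ceg, by = "sample", all = TRUE, sort = TRUE)
}

#' Partition samples by a BUSCO-abundance floor
#'
#' The comparison is strict: a sample is excluded when its BUSCO
#' abundance is strictly below the floor, so a sample exactly at the
#' floor is retained.
#'
#' @param records data.frame with a `busco_abundance` column.
#' @param busco_floor Percentage floor (default 57.5).
#' @return List with `retained` and `excluded` row subsets.
#' @export
flag_low_completeness <- function(records, busco_floor = 57.5) {
  stopifnot("busco_abundance" %in% names(records))
  low <- records$busco_abundance < busco_floor
  list(retained = records[!low, , drop = FALSE],
       excluded = records[low, , drop = FALSE])
}

#' Read a per-sample CEG hit-count table
#' @param path TSV with header columns `sample`, `ceg_hits`.
#' @return data.frame.
#' @export
read_ceg_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "ceg_hits") %in% names(df))) {
    stop("CEG table '", path, "' must have columns sample, ceg_hits")
  }
  df
}

#' Read a BUSCO short-summary percentage table
#' @param path TSV with header columns `sample`, `set`, `complete`,
#'   `fragment`, `missing`.
#' @return data.frame.
#' @export
read_busco_summary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample", "set", "complete", "fragment", "missing")
  if (!all(required %in% names(df))) {
    stop("BUSCO table '", path, "' must have columns: ",
         paste(required, collapse = ", "))
  }
  df
}

#' Percentile table of completeness metrics
#'
#' Summarises `ceg_abundance`, and per BUSCO set both the
#' complete-plus-fragment and the complete-only recovery, at the
#' requested percentiles.
#'
#' @param records data.frame from [completeness_records()].
#' @inheritParams percentile_summary
#' @return Tidy data.frame with columns `metric`, `percentile`, `value`.
#' @export
summarize_completeness <- function(records,
                                   percentiles = c(5, 25, 50, 75, 95),
                                   type = 7) {
  out <- list()
  if ("ceg_abundance" %in% names(records)) {
    p <- percentile_summary(records$ceg_abundance, percentiles, type)
    out[[length(out) + 1L]] <- cbind(metric = "ceg_abundance", p)
  }
  if ("busco_set" %in% names(records)) {
    for (set in sort(unique(stats::na.omit(records$busco_set)))) {
      r <- records[!is.na(records$busco_set) & records$busco_set == set, ]
      for (col in c("busco_found", "busco_complete")) {
        p <- percentile_summary(r[[col]], percentiles, type)
        out[[length(out) + 1L]] <-
          cbind(metric = paste(set, col, sep = "_"), p)
      }
    }
  }
  if (!length(out)) stop("no completeness metric columns found")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
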