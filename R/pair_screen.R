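# Enumeration of library pairs eligible for cross-contamination testing.
# Pairs of libraries from the same taxonomic family, and pairs separated
# by at most `max_branches` edges in the consensus phylogeny, are excluded
# before any similarity comparison: closely related species legitimately
# share near-identical sequences and would otherwise be flagged wholesale.

#' Leaf-to-leaf topological distance matrix
#'
#' Number of edges on the unique path between every pair of leaves,
#' ignoring branch lengths. Sister leaves are 2 edges apart.
#'
#' @param tree A `"phylo"` object.
#' @return Symmetric integer matrix with leaf labels as dimnames.
#' @export
tree_distance_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  t1 <- tree
  t1$edge.length <- rep(1, nrow(t1$edge))
  ntip <- length(t1$tip.label)
  d <- ape::dist.nodes(t1)[seq_len(ntip), seq_len(ntip), drop = FALSE]
  dimnames(d) <- list(t1$tip.label, t1$tip.label)
  d
}

#' Topological distance between two leaves
#'
#' @param tree A `"phylo"` object with library codes as leaf labels.
#' @param a,b Leaf names; must differ.
#' @param dist Optional precomputed [tree_distance_matrix()].
#' @return Edge count on the leaf-to-leaf path (symmetric in `a`, `b`).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((AAAA,BBBB),(CCCC,DDDD));")
#' tree_distance(tr, "AAAA", "BBBB")  # sister leaves: 2
#' tree_distance(tr, "AAAA", "CCCC")  # across the root: 4
tree_distance <- function(tree, a, b, dist = NULL) {
  stopifnot(length(a) == 1L, length(b) == 1L, a != b)
  if (is.null(dist)) dist <- tree_distance_matrix(tree)
  for (code in c(a, b)) {
    if (!code %in% rownames(dist)) {
      stop("code '", code, "' is not a leaf of the phylogeny")
    }
  }
  unname(dist[a, b])
}

#' Decide whether a library pair is excluded from contamination testing
#'
#' A pair is excluded when the two samples belong to the same family
#' (case-insensitive comparison) or, failing that, when their leaf-to-leaf
#' distance in the consensus tree is at most `max_branches` edges. When a
#' code is missing from the tree the tree criterion is skipped with a
#' warning and the family rule alone decides.
#'
#' @param a,b Sample codes (order irrelevant; the decision is symmetric).
#' @param samples Sample metadata data.frame from [read_sample_table()].
#' @param tree Consensus `"phylo"`, or `NULL` to use the family rule only.
#' @param max_branches Maximum leaf-to-leaf edge count that still excludes
#'   a pair (default 2, i.e. sister leaves and trichotomous siblings).
#' @param dist Optional precomputed [tree_distance_matrix()].
#' @return One-row data.frame: `code_a`, `code_b` (canonical order),
#'   `excluded`, `reason` (`same_family`, `tree_distance` or `none`) and
#'   `tree_distance` (NA when a code is absent from the tree).
#' @export
decide_exclusion <- function(a, b, samples, tree = NULL, max_branches = 2,
                             dist = NULL) {
  stopifnot(a != b)
  code_a <- min(a, b)
  code_b <- max(a, b)
  for (code in c(code_a, code_b)) {
    if (!code %in% samples$code) {
      stop("code '", code, "' is absent from the sample table")
    }
  }
  fam_a <- samples$family[match(code_a, samples$code)]
  fam_b <- samples$family[match(code_b, samples$code)]

  td <- NA_real_
  if (!is.null(tree)) {
    if (is.null(dist)) dist <- tree_distance_matrix(tree)
    leaves <- rownames(dist)
    if (code_a %in% leaves && code_b %in% leaves) {
      td <- unname(dist[code_a, code_b])
    } else {
      missing <- setdiff(c(code_a, code_b), leaves)
      warning("code(s) absent from the phylogeny, family rule only: ",
              paste(missing, collapse = ", "))
    }
  }

  same_family <- nzchar(trimws(fam_a)) && nzchar(trimws(fam_b)) &&
    fold_taxon(fam_a) == fold_taxon(fam_b)
  if (same_family) {
    reason <- "same_family"
  } else if (!is.na(td) && td <= max_branches) {
    reason <- "tree_distance"
  } else {
    reason <- "none"
  }
  data.frame(code_a = code_a, code_b = code_b,
             excluded = reason != "none", reason = reason,
             tree_distance = td, stringsAsFactors = FALSE)
}

#' Enumerate eligible and excluded library pairs
#'
#' Partitions all C(n, 2) canonical sample pairs into those eligible for
#' pairwise contamination testing and those excluded by
#' [decide_exclusion()].
#'
#' @inheritParams decide_exclusion
#' @return List with `decisions` (one row per pair), `eligible` and
#'   `excluded` (row subsets of `decisions`).
#' @export
eligible_pairs <- function(samples, tree = NULL, max_branches = 2) {
  codes <- sort(samples$code)
  if (length(codes) < 2L) stop("at least 2 samples are required")
  dist <- if (!is.null(tree)) tree_distance_matrix(tree) else NULL
  pairs <- utils::combn(codes, 2L)
  decisions <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    decide_exclusion(pairs[1L, i], pairs[2L, i], samples, tree,
                     max_branches = max_branches, dist = dist)
  }))
  rownames(decisions) <- NULL
  list(decisions = decisions,
       eligible = decisions[!decisions$excluded, , drop = FALSE],
       excluded = decisions[decisions$excluded, , drop = FALSE])
}

#' Write the excluded-pairs report
#'
#' TSV of taxonomically close sample pairs that were not compared:
#' `code_a`, `code_b`, `reason`, `tree_distance`.
#'
#' @param decisions `decisions` element of [eligible_pairs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_excluded_pairs <- function(decisions, path) {
  excl <- decisions[decisions$excluded,
                    c("code_a", "code_b", "reason", "tree_distance"),
                    drop = FALSE]
  write_tsv(excl, path)
  invisible(path)
}
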