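# Independent oracles used to cross-check the implementation. These are
# deliberately naive (explicit loops, neighbour lookup by value, BFS)
# and share no code with the package internals they check.

# First-local-minimum scan over a named count vector, neighbours found
# by value rather than by position.
oracle_cutoff <- function(counts, min_peak_support = 5) {
  edges <- as.numeric(names(counts))
  get_count <- function(e) counts[[which(edges == e)]]
  support <- 0
  for (e in edges) if (e >= 99) support <- support + get_count(e)
  if (support < min_peak_support) {
    return(list(status = "no_peak", cutoff = NA_real_))
  }
  for (e in sort(edges, decreasing = TRUE)) {
    above <- edges[edges > e]
    below <- edges[edges < e]
    if (length(above) == 0 || length(below) == 0) next
    if (get_count(e) <= get_count(min(above)) &&
        get_count(e) < get_count(max(below))) {
      return(list(status = "found", cutoff = e))
    }
  }
  list(status = "degenerate", cutoff = NA_real_)
}

# Breadth-first search over the tree's edge list: number of edges on the
# path between two tips.
oracle_tree_distance <- function(tree, a, b) {
  n_nodes <- max(tree$edge)
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]
    v <- tree$edge[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  start <- match(a, tree$tip.label)
  goal <- match(b, tree$tip.label)
  dist <- rep(NA_integer_, n_nodes)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    if (u == goal) return(dist[u])
    for (v in adj[[u]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  stop("tips not connected")
}

# Random histogram generator: a background hump at a random identity
# plus (usually) a near-100% spike, with occasional flat or empty
# regions, over 1%-wide bins spanning [0, 100].
random_histogram <- function() {
  edges <- 0:100
  mode <- sample(55:95, 1)
  spread <- sample(2:8, 1)
  background <- round(500 * exp(-((edges - mode)^2) / (2 * spread^2)))
  spike <- rep(0, length(edges))
  if (runif(1) < 0.7) {
    height <- sample(c(0:3, 5:80), 1)
    spike[edges >= sample(c(98, 99, 100), 1)] <- height
  }
  counts <- background + spike + rpois(length(edges), 0.2)
  names(counts) <- edges
  counts
}
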