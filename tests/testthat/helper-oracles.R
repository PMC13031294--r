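# Independent oracles used to validate the package implementations.
# These deliberately share no code with R/: the DBSCAN oracle builds the
# core graph explicitly and delegates its connected components to igraph,
# and the ARI oracle counts agreeing pairs by brute force.

# Naive O(m^2) DBSCAN: pairwise distances, core test, igraph connected
# components over core points, border points assigned to the cluster of
# their lowest-index core neighbour (the documented tie-break).
oracle_dbscan <- function(x, eps, min_pts) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  m <- nrow(x)
  d <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  within <- d <= eps
  counts <- rowSums(within)
  core <- counts >= min_pts
  labels <- integer(m)
  type <- rep("noise", m)
  if (any(core)) {
    type[core] <- "core"
    core_idx <- which(core)
    g <- igraph::graph_from_adjacency_matrix(
      within[core_idx, core_idx, drop = FALSE], mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    # renumber components by first core appearance, matching the package
    first_seen <- order(vapply(seq_len(max(comp)), function(cid)
      min(which(comp == cid)), integer(1)))
    renumber <- match(seq_len(max(comp)), first_seen)
    labels[core_idx] <- renumber[comp]
    for (i in which(!core)) {
      nbr <- core_idx[within[i, core_idx]]
      if (length(nbr) > 0L) {
        type[i] <- "border"
        labels[i] <- labels[min(nbr)]
      }
    }
  }
  list(labels = labels, type = type, counts = counts)
}

# Brute-force pair-counting ARI: count pairs together in a, in b, in both.
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- 0; same_b <- 0; same_both <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ia <- a[i] == a[j]
      ib <- b[i] == b[j]
      same_a <- same_a + ia
      same_b <- same_b + ib
      same_both <- same_both + (ia && ib)
    }
  }
  total <- n * (n - 1) / 2
  expected <- same_a * same_b / total
  max_index <- (same_a + same_b) / 2
  if (max_index == expected) return(1)
  (same_both - expected) / (max_index - expected)
}

# Two well-separated labelled blobs, the standard fixture for the
# reduction contract tests.
make_two_blobs <- function(n = 400, sep = 8, sd = 1, seed = 1) {
  make_gaussian_mixture(n, means = rbind(c(0, 0), c(sep, 0)), sds = sd, seed = seed)
}
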