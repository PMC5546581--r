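# Independent oracles and small generators used across the suite.
# Everything here is deliberately brute-force and separate from the
# package's own code paths.

# Closed-form RWR fixed point: p = c * (I - (1-c) T')^{-1} p0, where T' is
# the transition matrix with dangling columns replaced by the restart
# distribution (equivalent to re-injecting lost mass as restart).
rwr_dense_oracle <- function(transition, p0, restart_prob) {
  td <- as.matrix(transition$matrix)
  for (u in transition$dangling_nodes) td[, u] <- p0
  n <- nrow(td)
  solve(diag(n) - (1 - restart_prob) * td, restart_prob * p0)
}

# Random weighted undirected graph as a ppi_network, written via the STRING
# dialect so the loader is exercised too. Ensures at least a spanning path
# so no node is isolated unless allow_isolated.
random_network <- function(n, p_edge = 0.3, rng_seed = 1L,
                           allow_isolated = FALSE) {
  set.seed(rng_seed)
  ids <- sprintf("N%03d", seq_len(n))
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  ii <- pairs[keep, 1L]
  jj <- pairs[keep, 2L]
  if (!allow_isolated) {
    # chain the nodes so everything has degree >= 1
    ii <- c(ii, seq_len(n - 1L))
    jj <- c(jj, 2L:n)
    dup <- duplicated(cbind(pmin(ii, jj), pmax(ii, jj)))
    ii <- ii[!dup]; jj <- jj[!dup]
  }
  scores <- sample.int(1000L, length(ii), replace = TRUE)
  lines <- paste(ids[ii], ids[jj], scores)
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  load_string_links(f)
}

write_network_file <- function(lines, header = FALSE) {
  f <- tempfile(fileext = ".txt")
  writeLines(c(if (header) "protein1 protein2 combined_score", lines), f)
  f
}

write_gmt_file <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}

# Brute-force transitive closure of a parent graph (term -> direct parents).
ancestors_bruteforce <- function(ontology, term) {
  seen <- character(0)
  frontier <- ontology[[term]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- unique(unlist(ontology[frontier]))
    frontier <- setdiff(frontier, seen)
  }
  seen
}

# Exact hypergeometric upper tail P(X >= k) by choose()-sum enumeration.
hyper_tail_bruteforce <- function(k, n_white, n_black, n_draw) {
  kk <- max(k, 0L):min(n_draw, n_white)
  sum(choose(n_white, kk) * choose(n_black, n_draw - kk)) /
    choose(n_white + n_black, n_draw)
}

# Streamed permutation p-values recomputed the naive way: materialize the
# full permutation-by-gene probability matrix and count exceedances.
permutation_pvalues_bruteforce <- function(transition, real_result, genes,
                                           n_perm, seed_set_size, rng_seed,
                                           restart_prob = 0.8) {
  gi <- match(genes, transition$nodes)
  real_p <- real_result$probabilities[gi]
  n <- length(transition$nodes)
  set.seed(rng_seed)
  mat <- matrix(0, n_perm, length(genes))
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n, seed_set_size)
    p0 <- numeric(n)
    p0[idx] <- 1 / seed_set_size
    mat[k, ] <- rwr_propagate(transition, p0, restart_prob)$probabilities[gi]
  }
  stats::setNames(colSums(sweep(mat, 2L, real_p, ">")) / n_perm, genes)
}
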