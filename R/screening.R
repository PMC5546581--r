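with_rng_seed <- function(rng_seed, expr) {
  # run expr under a local, fully reproducible RNG stream
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(rng_seed)
  expr
}

#' Empirical permutation p-values for propagated genes
#'
#' Draws \code{n_permutations} random seed sets of size
#' \code{seed_set_size}, uniformly without replacement from all network
#' nodes, re-runs the identical random walk per set, and for each candidate
#' gene reports the fraction of permutations in which its permuted
#' probability strictly exceeds its probability under the real seeds
#' (exceedances / n). Per-gene exceedance counters are streamed, so memory
#' stays proportional to the number of candidates, never N x n.
#'
#' @param transition A \code{transition_matrix}.
#' @param real_result The converged \code{propagation_result} under the real
#'   seeds.
#' @param rwr_genes An \code{rwr_gene_set} (or character vector of node ids)
#'   to score.
#' @param n_permutations Number of random seed sets; default 1000.
#' @param seed_set_size Size of each random set; defaults to the real seed
#'   count and should match it.
#' @param rng_seed Integer seed fully determining the draws.
#' @param restart_prob,tolerance,max_iter,norm Passed to [rwr_propagate()];
#'   \code{restart_prob} defaults to the real run's value.
#' @param conservative If \code{TRUE}, report (exceedances + 1) / (n + 1)
#'   instead of exceedances / n. Off by default.
#' @param progress Optional function called with the permutation index every
#'   100 permutations.
#' @return Named numeric vector of p-values, one per candidate gene, each a
#'   multiple of 1/n (or of 1/(n+1) under \code{conservative}).
#' @export
permutation_pvalues <- function(transition, real_result, rwr_genes,
                                n_permutations = 1000L, seed_set_size,
                                rng_seed = 1L,
                                restart_prob = real_result$restart_prob,
                                tolerance = 1e-6, max_iter = 10000L,
                                norm = "l1", conservative = FALSE,
                                progress = NULL) {
  stopifnot(inherits(transition, "transition_matrix"),
            inherits(real_result, "propagation_result"))
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  genes <- if (inherits(rwr_genes, "rwr_gene_set")) rwr_genes$entries$node_id else rwr_genes
  n <- length(transition$nodes)
  if (seed_set_size > n) stop("seed_set_size exceeds network size")
  gene_idx <- match(genes, transition$nodes)
  if (anyNA(gene_idx)) stop("candidate gene(s) not in network")
  real_p <- real_result$probabilities[gene_idx]

  exceed <- integer(length(genes))
  with_rng_seed(rng_seed, {
    for (k in seq_len(n_permutations)) {
      idx <- sample.int(n, seed_set_size)
      p0 <- numeric(n)
      p0[idx] <- 1 / seed_set_size
      res <- tryCatch(
        rwr_propagate(transition, p0, restart_prob = restart_prob,
                      tolerance = tolerance, max_iter = max_iter, norm = norm),
        error = function(e) stop("permutation ", k, " failed: ",
                                 conditionMessage(e), call. = FALSE)
      )
      exceed <- exceed + (res$probabilities[gene_idx] > real_p)
      if (!is.null(progress) && k %% 100L == 0L) progress(k)
    }
  })
  pv <- if (conservative) (exceed + 1) / (n_permutations + 1) else exceed / n_permutations
  names(pv) <- genes
  pv
}

#' Maximum interaction score of a gene with a seed set
#'
#' The largest stored edge score between \code{gene} and any seed; pairs
#' with no edge contribute 0, and a gene with no edge to any seed scores
#' (0, NA partner). Ties resolve to the lexicographically smallest seed.
#'
#' @param gene A node identifier present in the network.
#' @param seeds A \code{seed_set} or character vector of seed ids.
#' @param network A \code{ppi_network}.
#' @return List with \code{mis} (numeric, 0-1000) and \code{partner} (seed
#'   id or \code{NA}).
#' @export
max_interaction_score <- function(gene, seeds, network) {
  tab <- mis_table(gene, seeds, network)
  list(mis = tab$mis[[1L]], partner = tab$mis_partner[[1L]])
}

#' Maximum interaction scores for many genes at once
#'
#' Vectorized form of [max_interaction_score()]; one edge-list pass.
#'
#' @inheritParams max_interaction_score
#' @param genes Character vector of node identifiers.
#' @return data.frame \code{node_id}, \code{mis}, \code{mis_partner}.
#' @export
mis_table <- function(genes, seeds, network) {
  stopifnot(inherits(network, "ppi_network"))
  members <- if (inherits(seeds, "seed_set")) seeds$members else seeds
  if (any(!genes %in% network$nodes)) {
    stop("gene(s) not in network: ",
         paste(utils::head(setdiff(genes, network$nodes), 5L), collapse = ", "))
  }
  e <- network$edges
  # orient each edge candidate -> seed, both directions
  cand <- c(e$protein_a, e$protein_b)
  other <- c(e$protein_b, e$protein_a)
  sc <- c(e$score, e$score)
  keep <- cand %in% genes & other %in% members
  cand <- cand[keep]; other <- other[keep]; sc <- sc[keep]

  mis <- setNames(numeric(length(genes)), genes)
  partner <- setNames(rep(NA_character_, length(genes)), genes)
  if (length(cand)) {
    ord <- order(cand, -sc, other)  # per gene: best score first, ties by id
    cand <- cand[ord]; other <- other[ord]; sc <- sc[ord]
    best <- !duplicated(cand)
    mis[cand[best]] <- sc[best]
    partner[cand[best]] <- other[best]
  }
  data.frame(node_id = genes, mis = unname(mis), mis_partner = unname(partner),
             stringsAsFactors = FALSE)
}

cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x * x)); ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Maximum enrichment score of a gene against seed feature vectors
#'
#' The largest direction cosine between the gene's annotation feature
#' vector and any seed's. A zero vector (unannotated gene) has cosine 0
#' with everything, so such genes score (0, NA partner) with a warning.
#' Ties resolve to the lexicographically smallest seed.
#'
#' @param gene A node identifier.
#' @param seeds A \code{seed_set} or character vector of seed ids.
#' @param vectors Feature vectors: a matrix (genes x terms, rownames = gene
#'   ids) as built by [build_feature_matrix()], or a named list of numeric
#'   vectors.
#' @return List with \code{mes} (in [0, 1] for non-negative vectors) and
#'   \code{partner} (seed id or \code{NA}).
#' @export
max_enrichment_score <- function(gene, seeds, vectors) {
  tab <- mes_table(gene, seeds, vectors)
  list(mes = tab$mes[[1L]], partner = tab$mes_partner[[1L]])
}

fv_matrix <- function(vectors, ids) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    have <- intersect(ids, names(vectors))
    dim_t <- if (length(vectors)) length(vectors[[1L]]) else 0L
    m <- matrix(0, nrow = length(ids), ncol = dim_t, dimnames = list(ids, NULL))
    for (g in have) m[g, ] <- vectors[[g]]
    m
  } else {
    have <- intersect(ids, rownames(vectors))
    m <- matrix(0, nrow = length(ids), ncol = ncol(vectors),
                dimnames = list(ids, colnames(vectors)))
    if (length(have)) m[have, ] <- as.matrix(vectors[have, , drop = FALSE])
    m
  }
}

#' Maximum enrichment scores for many genes at once
#'
#' Vectorized form of [max_enrichment_score()]: all gene-by-seed cosines
#' are computed with one matrix product.
#'
#' @inheritParams max_enrichment_score
#' @param genes Character vector of node identifiers.
#' @return data.frame \code{node_id}, \code{mes}, \code{mes_partner}.
#' @export
mes_table <- function(genes, seeds, vectors) {
  members <- if (inherits(seeds, "seed_set")) seeds$members else seeds
  members <- sort(members)  # lexicographic tie-break via first argmax
  gm <- fv_matrix(vectors, genes)
  sm <- fv_matrix(vectors, members)
  gn <- sqrt(rowSums(gm^2))
  sn <- sqrt(rowSums(sm^2))
  if (all(sn == 0)) stop("no seed has a non-zero feature vector")
  cosines <- gm %*% t(sm)
  denom <- outer(gn, sn)
  cosines <- ifelse(denom > 0, cosines / denom, 0)
  if (any(gn == 0)) {
    warning(sum(gn == 0), " gene(s) without annotations scored mes = 0")
  }
  best <- apply(cosines, 1L, which.max)
  mes <- cosines[cbind(seq_along(genes), best)]
  partner <- ifelse(mes > 0, members[best], NA_character_)
  data.frame(node_id = genes, mes = unname(mes), mes_partner = partner,
             stringsAsFactors = FALSE)
}

#' Screening thresholds
#'
#' The cascade's cutoffs with their boundary semantics: permutation p-value
#' strictly below \code{p_value_max}; interaction score at least
#' \code{mis_min} (inclusive — 900 is the STRING highest-confidence cutoff
#' and passes); enrichment cosine strictly above \code{mes_min}; propagation
#' probability strictly above \code{probability_min}.
#'
#' @param p_value_max Default 0.05 (strict \code{<}).
#' @param mis_min Default 900 (\code{>=}).
#' @param mes_min Default 0.8 (strict \code{>}).
#' @param probability_min Default 1e-5 (strict \code{>}).
#' @return A \code{screen_thresholds} list.
#' @export
screen_thresholds <- function(p_value_max = 0.05, mis_min = 900,
                              mes_min = 0.8, probability_min = 1e-5) {
  stopifnot(is.finite(p_value_max), is.finite(mis_min), is.finite(mes_min),
            is.finite(probability_min),
            mis_min >= 0, mis_min <= 1000, mes_min >= 0, mes_min <= 1)
  structure(list(p_value_max = p_value_max, mis_min = mis_min,
                 mes_min = mes_min, probability_min = probability_min),
            class = "screen_thresholds")
}

#' Apply the three-stage screening cascade
#'
#' Combines permutation p-values, maximum interaction scores and maximum
#' enrichment scores into one auditable record per candidate gene. A gene is
#' \emph{inferred} iff it passes all three screens. Records for every
#' candidate are returned, passers and failers alike.
#'
#' @param rwr_genes An \code{rwr_gene_set}.
#' @param p_values Named numeric vector from [permutation_pvalues()].
#' @param mis_results data.frame from [mis_table()].
#' @param mes_results data.frame from [mes_table()].
#' @param thresholds A \code{screen_thresholds}.
#' @return data.frame with columns \code{node_id}, \code{probability},
#'   \code{p_value}, \code{mis}, \code{mis_partner}, \code{mes},
#'   \code{mes_partner}, \code{passed_permutation}, \code{passed_mis},
#'   \code{passed_mes}, \code{inferred}.
#' @export
apply_screens <- function(rwr_genes, p_values, mis_results, mes_results,
                          thresholds = screen_thresholds()) {
  stopifnot(inherits(rwr_genes, "rwr_gene_set"),
            inherits(thresholds, "screen_thresholds"))
  df <- rwr_genes$entries
  ids <- df$node_id
  miss <- function(what, have) {
    lack <- setdiff(ids, have)
    if (length(lack)) {
      stop("missing ", what, " for candidate gene(s): ",
           paste(utils::head(lack, 5L), collapse = ", "))
    }
  }
  miss("p-value", names(p_values))
  miss("MIS", mis_results$node_id)
  miss("MES", mes_results$node_id)

  out <- data.frame(
    node_id = ids,
    probability = df$probability,
    p_value = unname(p_values[ids]),
    mis = mis_results$mis[match(ids, mis_results$node_id)],
    mis_partner = mis_results$mis_partner[match(ids, mis_results$node_id)],
    mes = mes_results$mes[match(ids, mes_results$node_id)],
    mes_partner = mes_results$mes_partner[match(ids, mes_results$node_id)],
    stringsAsFactors = FALSE
  )
  out$passed_permutation <- out$p_value < thresholds$p_value_max
  out$passed_mis <- out$mis >= thresholds$mis_min
  out$passed_mes <- out$mes > thresholds$mes_min
  out$inferred <- out$passed_permutation & out$passed_mis & out$passed_mes
  out
}
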