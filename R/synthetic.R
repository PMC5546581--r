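#' Specification of a planted-community benchmark
#'
#' Parameters of a stochastic block model with community-dependent edge
#' probabilities and STRING-scale (0-1000] integer edge scores, plus a
#' community-structured annotation catalog. Used to plant a recoverable
#' seed module so every stage of the cascade is testable without downloads.
#'
#' Defaults define the package's standard recovery benchmark: 200 nodes in
#' two communities, dense high-scoring within-community edges
#' (p = 0.25, scores 800-1000) against sparse low-scoring background
#' (p = 0.02, scores 100-400), 10 seeds confined to community 1, 10
#' community-specific annotation terms carried with fidelity 0.9.
#'
#' @param n_nodes Total nodes.
#' @param n_communities Number of equal-sized communities.
#' @param p_within,p_between Edge probabilities inside / across communities;
#'   \code{p_between < p_within} required for a planted signal.
#' @param score_within,score_between Integer score ranges (length-2) for
#'   within / between edges, each within (0, 1000].
#' @param seed_community Community index the seeds are drawn from.
#' @param n_seeds Number of seed nodes (must be below the community size).
#' @param n_terms Annotation terms per community.
#' @param annotation_fidelity Probability a community member carries each of
#'   its own community's terms; it carries another community's term with
#'   probability (1 - fidelity) / (n_communities - 1).
#' @param rng_seed Integer seed; every draw is determined by it.
#' @return A \code{planted_module_spec} list.
#' @export
planted_module_spec <- function(n_nodes = 200L, n_communities = 2L,
                                p_within = 0.25, p_between = 0.02,
                                score_within = c(800L, 1000L),
                                score_between = c(100L, 400L),
                                seed_community = 1L, n_seeds = 10L,
                                n_terms = 10L, annotation_fidelity = 0.9,
                                rng_seed = 1L) {
  stopifnot(n_nodes >= n_communities, n_communities >= 1L,
            p_between >= 0, p_between < p_within, p_within <= 1,
            all(score_within >= 1L), all(score_within <= 1000L),
            all(score_between >= 1L), all(score_between <= 1000L),
            seed_community >= 1L, seed_community <= n_communities,
            n_seeds < n_nodes %/% n_communities,
            annotation_fidelity >= 0, annotation_fidelity <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_communities = as.integer(n_communities),
                 p_within = p_within, p_between = p_between,
                 score_within = as.integer(score_within),
                 score_between = as.integer(score_between),
                 seed_community = as.integer(seed_community),
                 n_seeds = as.integer(n_seeds),
                 n_terms = as.integer(n_terms),
                 annotation_fidelity = annotation_fidelity,
                 rng_seed = as.integer(rng_seed)),
            class = "planted_module_spec")
}

#' Generate a planted-community network with seeds and truth labels
#'
#' Stochastic block model: nodes are split evenly into communities; each
#' unordered pair gets an edge with probability \code{p_within} (same
#' community) or \code{p_between} (different), and an integer score drawn
#' uniformly from the corresponding range. Seeds are sampled from the seed
#' community. Generation retries (up to 20 times, advancing the stream) if
#' some seed ends up isolated, then errors.
#'
#' @param spec A \code{planted_module_spec}.
#' @return List with \code{network} (\code{ppi_network}), \code{seeds}
#'   (\code{seed_set}), \code{labels} (named integer community per node).
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "planted_module_spec"))
  with_rng_seed(spec$rng_seed, {
    for (attempt in seq_len(20L)) {
      out <- try(generate_planted_network_once(spec), silent = TRUE)
      if (!inherits(out, "try-error")) return(out)
    }
    stop("could not generate a network with all seeds connected: ",
         attr(out, "condition")$message)
  })
}

generate_planted_network_once <- function(spec) {
  n <- spec$n_nodes
  ids <- sprintf("G%04d", seq_len(n))
  labels <- rep(seq_len(spec$n_communities), length.out = n)
  labels <- sort(labels)
  names(labels) <- ids

  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  same <- labels[pair_i] == labels[pair_j]
  p_edge <- ifelse(same, spec$p_within, spec$p_between)
  keep <- stats::runif(length(p_edge)) < p_edge
  pi <- pair_i[keep]; pj <- pair_j[keep]; same <- same[keep]

  draw <- function(rng, k) {
    if (k == 0L) integer(0)
    else sample(seq.int(rng[1L], rng[2L]), k, replace = TRUE)
  }
  score <- integer(length(pi))
  score[same] <- draw(spec$score_within, sum(same))
  score[!same] <- draw(spec$score_between, sum(!same))

  edges <- data.frame(protein_a = ids[pi], protein_b = ids[pj],
                      score = score, stringsAsFactors = FALSE)
  network <- new_ppi_network(ids, edges)

  community_members <- ids[labels == spec$seed_community]
  seed_ids <- sort(sample(community_members, spec$n_seeds))
  connected <- unique(c(edges$protein_a, edges$protein_b))
  if (!all(seed_ids %in% connected)) stop("isolated seed drawn")
  seeds <- make_seed_set(seed_ids, network)
  list(network = network, seeds = seeds, labels = labels)
}

#' Generate community-structured annotations
#'
#' Each community owns \code{n_terms} terms. A node carries each of its own
#' community's terms with probability \code{annotation_fidelity} and each
#' other community's terms with probability
#' (1 - fidelity) / (n_communities - 1), so fidelity 1 gives perfectly
#' separated binary feature vectors and fidelity 1/n_communities carries no
#' community signal.
#'
#' @param spec A \code{planted_module_spec}.
#' @param labels Truth labels from [generate_planted_network()].
#' @return An \code{annotation_catalog}.
#' @export
generate_planted_annotations <- function(spec, labels) {
  stopifnot(inherits(spec, "planted_module_spec"))
  ids <- names(labels)
  terms <- as.vector(outer(seq_len(spec$n_terms), seq_len(spec$n_communities),
                           function(t, cm) sprintf("TERM_C%d_%02d", cm, t)))
  term_comm <- rep(seq_len(spec$n_communities), each = spec$n_terms)
  p_other <- if (spec$n_communities > 1L) {
    (1 - spec$annotation_fidelity) / (spec$n_communities - 1L)
  } else 0
  with_rng_seed(spec$rng_seed + 1L, {
    sets <- lapply(seq_along(terms), function(t) {
      p <- ifelse(labels == term_comm[t], spec$annotation_fidelity, p_other)
      ids[stats::runif(length(ids)) < p]
    })
  })
  new_annotation_catalog(terms, sets, "mixed")
}

#' Write a complete fixture bundle to disk
#'
#' Emits the four inputs the pipeline consumes — network edge list in the
#' STRING dialect, seed list (one id per line), annotations as GMT, and a
#' truth-label TSV — so an end-to-end run needs no external data.
#'
#' @param spec A \code{planted_module_spec}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_planted_network(spec)
  catalog <- prune_empty_terms(generate_planted_annotations(spec, gen$labels))
  paths <- c(network = file.path(dir, "network.txt"),
             seeds = file.path(dir, "seeds.txt"),
             gmt = file.path(dir, "annotations.gmt"),
             labels = file.path(dir, "truth_labels.tsv"))
  write_string_links(gen$network, paths[["network"]])
  writeLines(gen$seeds$members, paths[["seeds"]])
  writeLines(vapply(seq_along(catalog$terms), function(t) {
    paste(c(catalog$terms[t], "planted community term",
            catalog$term_to_genes[[t]]), collapse = "\t")
  }, ""), paths[["gmt"]])
  utils::write.table(
    data.frame(node_id = names(gen$labels), community = unname(gen$labels)),
    paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
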