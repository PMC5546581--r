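#' Pipeline run configuration
#'
#' Bundles every input path and tunable of the cascade. Defaults are the
#' method's standard settings: restart probability 0.8, convergence
#' tolerance 1e-6, probability threshold 1e-5, 1000 permutations, and the
#' screening cutoffs p < 0.05, MIS >= 900, MES > 0.8.
#'
#' @param network_path STRING-dialect edge list.
#' @param seed_path Seed list, one node identifier per line.
#' @param gmt_paths Character vector of GMT annotation files (concatenated
#'   into one joint catalog).
#' @param obo_path Optional OBO ontology for ancestor propagation.
#' @param out_dir Output directory.
#' @param restart_prob,tolerance,max_iter RWR settings.
#' @param prob_threshold RWR gene selection cutoff (strict >).
#' @param n_permutations Permutation count (>= 1).
#' @param thresholds A [screen_thresholds()].
#' @param encoding Feature-vector encoding, \code{"binary"} (default) or
#'   \code{"neighbor_enrichment"}.
#' @param species_prefix Optional identifier prefix filter for the network
#'   file (e.g. \code{"9606."}).
#' @param min_bipartite_score Score floor for the exported inferred-known
#'   bipartite subgraph; default 900, the MIS cutoff.
#' @param rng_seed Integer seed for the permutation draws.
#' @return A \code{run_config} list.
#' @export
run_config <- function(network_path, seed_path, gmt_paths, obo_path = NULL,
                       out_dir = "rwrscreen_out", restart_prob = 0.8,
                       tolerance = 1e-6, max_iter = 10000L,
                       prob_threshold = 1e-5, n_permutations = 1000L,
                       thresholds = screen_thresholds(),
                       encoding = "binary", species_prefix = NULL,
                       min_bipartite_score = thresholds$mis_min,
                       rng_seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (!(restart_prob > 0 && restart_prob <= 1)) stop("restart_prob must be in (0, 1]")
  if (tolerance <= 0) stop("tolerance must be positive")
  structure(list(network_path = network_path, seed_path = seed_path,
                 gmt_paths = gmt_paths, obo_path = obo_path,
                 out_dir = out_dir, restart_prob = restart_prob,
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 prob_threshold = prob_threshold,
                 n_permutations = as.integer(n_permutations),
                 thresholds = thresholds, encoding = encoding,
                 species_prefix = species_prefix,
                 min_bipartite_score = min_bipartite_score,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full prioritization cascade
#'
#' Load network and seeds, propagate, select RWR genes, permutation-test
#' them, score MIS and MES, apply the screens, and write all tables plus a
#' run manifest into \code{config$out_dir}:
#' \code{rwr_genes.tsv} (ranked propagation table),
#' \code{screening.tsv} (one auditable record per RWR gene),
#' \code{inferred_genes.tsv} (records passing all three screens),
#' \code{bipartite_edges.tsv} (inferred-known subgraph) and
#' \code{manifest.yaml} (config, input checksums, stage counts, versions).
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the stage products and \code{counts}
#'   (named: \code{rwr_genes}, \code{candidates}, \code{inferred}).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  network <- stage("load_network",
                   load_string_links(config$network_path, config$species_prefix))
  say("  ", length(network$nodes), " nodes, ", nrow(network$edges), " edges")
  seeds <- stage("load_seeds", {
    ids <- readLines(config$seed_path)
    ids <- trimws(ids[nzchar(trimws(ids))])
    make_seed_set(ids, network)
  })
  transition <- stage("transition_matrix", build_transition_matrix(network))
  p0 <- make_initial_vector(seeds, network)
  real <- stage("rwr", rwr_propagate(transition, p0,
                                     restart_prob = config$restart_prob,
                                     tolerance = config$tolerance,
                                     max_iter = config$max_iter))
  rwr_genes <- select_rwr_genes(real, seeds, config$prob_threshold)
  say("  ", nrow(rwr_genes$entries), " RWR genes above ", config$prob_threshold)

  pvals <- stage("permutation_test", permutation_pvalues(
    transition, real, rwr_genes,
    n_permutations = config$n_permutations,
    seed_set_size = length(seeds$members),
    rng_seed = config$rng_seed,
    restart_prob = config$restart_prob,
    tolerance = config$tolerance, max_iter = config$max_iter,
    progress = function(k) say("  permutation ", k, "/", config$n_permutations)
  ))

  catalog <- stage("annotations", {
    cats <- lapply(config$gmt_paths, load_gmt)
    cat_all <- do.call(combine_catalogs, cats)
    if (!is.null(config$obo_path)) {
      cat_all <- propagate_ancestors(cat_all, load_obo(config$obo_path))
    }
    prune_empty_terms(cat_all)
  })
  gene_ids <- rwr_genes$entries$node_id
  fv <- stage("feature_vectors", build_feature_matrix(
    union(gene_ids, seeds$members), catalog,
    encoding = config$encoding, network = network))

  mis <- stage("interaction_test", mis_table(gene_ids, seeds, network))
  mes <- stage("enrichment_test",
               suppressWarnings(mes_table(gene_ids, seeds, fv)))
  records <- apply_screens(rwr_genes, pvals, mis, mes, config$thresholds)
  inferred <- records[records$inferred, , drop = FALSE]
  bipartite <- export_bipartite_subgraph(inferred$node_id, seeds, network,
                                         config$min_bipartite_score)

  counts <- c(rwr_genes = nrow(records),
              candidates = sum(records$passed_permutation),
              inferred = nrow(inferred))
  say(sprintf("stage counts: %d RWR genes -> %d candidates -> %d inferred",
              counts[1L], counts[2L], counts[3L]))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(rwr_rank_table(real, seeds), file.path(config$out_dir, "rwr_genes.tsv"))
  write_tsv(records, file.path(config$out_dir, "screening.tsv"))
  write_tsv(inferred, file.path(config$out_dir, "inferred_genes.tsv"))
  write_tsv(bipartite, file.path(config$out_dir, "bipartite_edges.tsv"))
  manifest <- list(
    config = config_as_list(config),
    inputs = list(
      network_md5 = unname(tools::md5sum(config$network_path)),
      seeds_md5 = unname(tools::md5sum(config$seed_path)),
      gmt_md5 = unname(tools::md5sum(config$gmt_paths))
    ),
    seeds = list(requested = length(seeds$requested),
                 mapped = length(seeds$members),
                 dropped = seeds$dropped),
    rwr = list(iterations = real$iterations,
               final_delta = real$final_delta,
               converged = real$converged),
    counts = as.list(counts),
    versions = list(rwrscreen = as.character(utils::packageVersion("rwrscreen")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(network = network, seeds = seeds, result = real,
                 rwr_genes = rwr_genes, records = records,
                 inferred = inferred, bipartite = bipartite,
                 counts = counts))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$thresholds <- unclass(out$thresholds)
  out
}

#' Bipartite subgraph between inferred and known genes
#'
#' All network edges with one inferred endpoint and one seed endpoint whose
#' score is at least \code{min_score} (default 900, the interaction-test
#' cutoff, under which every MIS-passing inferred gene has at least one
#' edge in the export).
#'
#' @param inferred Character vector of inferred gene ids (disjoint from the
#'   seeds).
#' @param seeds A \code{seed_set} or character vector.
#' @param network A \code{ppi_network}.
#' @param min_score Integer score floor.
#' @return data.frame \code{inferred_gene}, \code{known_gene}, \code{score},
#'   sorted by inferred gene then known gene.
#' @export
export_bipartite_subgraph <- function(inferred, seeds, network,
                                      min_score = 900) {
  members <- if (inherits(seeds, "seed_set")) seeds$members else seeds
  if (length(intersect(inferred, members))) {
    stop("inferred set and seed set overlap")
  }
  e <- network$edges
  a <- c(e$protein_a, e$protein_b)
  b <- c(e$protein_b, e$protein_a)
  sc <- c(e$score, e$score)
  keep <- a %in% inferred & b %in% members & sc >= min_score
  out <- data.frame(inferred_gene = a[keep], known_gene = b[keep],
                    score = sc[keep], stringsAsFactors = FALSE)
  out <- out[order(out$inferred_gene, out$known_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
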