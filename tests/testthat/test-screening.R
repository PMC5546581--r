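test_that("streamed permutation p-values match the materialized brute force", {
  net <- random_network(40, p_edge = 0.15, rng_seed = 3)
  tm <- build_transition_matrix(net)
  seeds <- make_seed_set(net$nodes[1:4], net)
  real <- rwr_propagate(tm, make_initial_vector(seeds, net), 0.8)
  rg <- select_rwr_genes(real, seeds, 1e-5)
  pv <- permutation_pvalues(tm, real, rg, n_permutations = 40,
                            seed_set_size = 4, rng_seed = 99)
  bf <- permutation_pvalues_bruteforce(tm, real, rg$entries$node_id,
                                       n_perm = 40, seed_set_size = 4,
                                       rng_seed = 99)
  expect_equal(pv, bf)
  # granularity: every p-value is k/n for integer k
  expect_true(all(abs(pv * 40 - round(pv * 40)) < 1e-12))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("permutation p-values are reproducible and seed-sensitive", {
  net <- random_network(30, p_edge = 0.2, rng_seed = 4)
  tm <- build_transition_matrix(net)
  seeds <- make_seed_set(net$nodes[1:3], net)
  real <- rwr_propagate(tm, make_initial_vector(seeds, net), 0.8)
  rg <- select_rwr_genes(real, seeds, 1e-5)
  p1 <- permutation_pvalues(tm, real, rg, 30, 3, rng_seed = 7)
  p2 <- permutation_pvalues(tm, real, rg, 30, 3, rng_seed = 7)
  p3 <- permutation_pvalues(tm, real, rg, 30, 3, rng_seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  # conservative variant shifts by the (theta+1)/(n+1) rule
  pc <- permutation_pvalues(tm, real, rg, 30, 3, rng_seed = 7,
                            conservative = TRUE)
  expect_equal(unname(pc), unname((p1 * 30 + 1) / 31))
  # a failing propagation inside a permutation names the permutation
  expect_error(
    permutation_pvalues(tm, real, rg, 5, 3, rng_seed = 7, max_iter = 1L),
    "permutation 1 failed")
  expect_error(permutation_pvalues(tm, real, rg, 0, 3), "n_permutations")
})

test_that("maximum interaction score picks the best-scoring seed edge", {
  net <- load_string_links(write_network_file(
    c("X P 850", "X Q 910", "Y P 500", "P Q 999")))
  seeds <- make_seed_set(c("P", "Q"), net)
  expect_equal(max_interaction_score("X", seeds, net),
               list(mis = 910, partner = "Q"))
  # no edge to any seed -> empty-max convention
  net2 <- load_string_links(write_network_file(c("X P 850", "Z W 700")))
  expect_equal(max_interaction_score("Z", make_seed_set("P", net2), net2),
               list(mis = 0, partner = NA_character_))
  # score ties resolve to the lexicographically smallest seed
  net3 <- load_string_links(write_network_file(c("X B 900", "X A 900")))
  expect_equal(max_interaction_score("X", make_seed_set(c("B", "A"), net3),
                                     net3)$partner, "A")
  expect_error(mis_table("NOPE", seeds, net), "not in network")
  # bounds on a random instance
  rn <- random_network(25, rng_seed = 6)
  tab <- mis_table(rn$nodes[10:20], make_seed_set(rn$nodes[1:5], rn), rn)
  expect_true(all(tab$mis >= 0 & tab$mis <= 1000))
})

test_that("maximum enrichment score is the best seed cosine", {
  vecs <- list(g = c(1, 1, 0), s1 = c(1, 1, 1), s2 = c(0, 0, 2))
  res <- max_enrichment_score("g", c("s1", "s2"), vecs)
  expect_equal(res$mes, 2 / (sqrt(2) * sqrt(3)), tolerance = 1e-12)
  expect_equal(res$mes, 0.8165, tolerance = 1e-4)
  expect_equal(res$partner, "s1")

  ident <- list(g = c(2, 0, 1), s1 = c(2, 0, 1))
  expect_equal(max_enrichment_score("g", "s1", ident)$mes, 1)

  ortho <- list(g = c(1, 0), s1 = c(0, 1))
  expect_equal(max_enrichment_score("g", "s1", ortho)$mes, 0)

  # zero vector: mes 0 with a warning, never an error
  zv <- list(g = c(0, 0), s1 = c(1, 0))
  expect_warning(r0 <- max_enrichment_score("g", "s1", zv), "annotations")
  expect_equal(r0$mes, 0)
  expect_true(is.na(r0$partner))

  # cosine is invariant to positive rescaling of either vector
  sc <- list(g = 7.3 * c(1, 1, 0), s1 = 0.002 * c(1, 1, 1))
  expect_equal(max_enrichment_score("g", "s1", sc)$mes,
               2 / (sqrt(2) * sqrt(3)), tolerance = 1e-12)
})

test_that("screen boundaries follow the stated strictness", {
  net <- load_string_links(write_network_file(
    c("g1 s 900", "g2 s 999", "g3 s 899")))
  seeds <- make_seed_set("s", net)
  rg <- structure(list(entries = data.frame(
    node_id = c("g1", "g2", "g3"),
    probability = c(2e-5, 3e-5, 4e-5), stringsAsFactors = FALSE),
    threshold = 1e-5), class = "rwr_gene_set")
  pv <- c(g1 = 0.04, g2 = 0.05, g3 = 0.04)
  mis <- mis_table(c("g1", "g2", "g3"), seeds, net)
  mes <- data.frame(node_id = c("g1", "g2", "g3"),
                    mes = c(0.81, 0.95, 0.80),
                    mes_partner = "s", stringsAsFactors = FALSE)
  rec <- apply_screens(rg, pv, mis, mes, screen_thresholds())
  # p = 0.04, MIS = 900 (inclusive), MES = 0.81 -> inferred
  expect_true(rec$inferred[rec$node_id == "g1"])
  # p = 0.05 is not < 0.05 -> fails despite perfect MIS/MES
  expect_false(rec$passed_permutation[rec$node_id == "g2"])
  expect_false(rec$inferred[rec$node_id == "g2"])
  # MES = 0.8 exactly fails the strict > cutoff; MIS 899 fails >= 900
  expect_false(rec$passed_mes[rec$node_id == "g3"])
  expect_false(rec$passed_mis[rec$node_id == "g3"])
  expect_equal(rec$inferred, rec$passed_permutation & rec$passed_mis & rec$passed_mes)
  # a missing score is a consistency error
  expect_error(apply_screens(rg, pv[-1], mis, mes), "missing p-value")
  expect_error(apply_screens(rg, pv, mis[-1, ], mes), "missing MIS")
})

test_that("filtering is monotone: inferred within passers within candidates", {
  spec <- planted_module_spec(n_nodes = 80, n_seeds = 6, rng_seed = 5)
  gen <- generate_planted_network(spec)
  catalog <- prune_empty_terms(generate_planted_annotations(spec, gen$labels))
  tm <- build_transition_matrix(gen$network)
  real <- rwr_propagate(tm, make_initial_vector(gen$seeds, gen$network), 0.8)
  rg <- select_rwr_genes(real, gen$seeds, 1e-5)
  pv <- permutation_pvalues(tm, real, rg, 60, 6, rng_seed = 2)
  ids <- rg$entries$node_id
  fv <- build_feature_matrix(union(ids, gen$seeds$members), catalog)
  rec <- suppressWarnings(apply_screens(
    rg, pv, mis_table(ids, gen$seeds, gen$network),
    mes_table(ids, gen$seeds, fv)))
  expect_true(sum(rec$inferred) <= sum(rec$passed_permutation))
  expect_true(sum(rec$passed_permutation) <= nrow(rec))
  expect_true(all(rec$node_id[rec$inferred] %in%
                  rec$node_id[rec$passed_permutation]))
})
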