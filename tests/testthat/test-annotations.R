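test_that("GMT files parse, merge duplicates, and reject malformed lines", {
  f <- write_gmt_file(c("T1\tdesc\tA\tB", "T2\tdesc\tB\tC"))
  cat1 <- load_gmt(f)
  expect_equal(cat1$terms, c("T1", "T2"))
  expect_setequal(cat1$term_to_genes$T1, c("A", "B"))
  expect_length(unique(unlist(cat1$term_to_genes)), 3L)

  expect_warning(cat2 <- load_gmt(write_gmt_file(
    c("T1\tdesc\tA", "T1\tdesc\tB"))), "merged")
  expect_setequal(cat2$term_to_genes$T1, c("A", "B"))
  expect_length(cat2$terms, 1L)

  expect_error(load_gmt(write_gmt_file(c("T1\tdesc\tA", "T2\tdesc"))),
               "line 2")
  expect_error(load_gmt(write_gmt_file("T1\tdesc\t")), "line 1")

  # independent reader agreement on a clean file
  ref <- fgsea::gmtPathways(f)
  expect_equal(lapply(cat1$term_to_genes, sort), lapply(ref, sort))
})

test_that("catalogs combine by term-dictionary concatenation", {
  a <- load_gmt(write_gmt_file("GO:1\td\tA\tB"), source_kind = "GO")
  b <- load_gmt(write_gmt_file("hsa01\td\tB\tC"), source_kind = "KEGG")
  joint <- combine_catalogs(a, b)
  expect_equal(joint$terms, c("GO:1", "hsa01"))
  expect_equal(joint$source_kind, "mixed")
  dict <- term_dictionary(joint)
  expect_equal(dict$gene_count, c(2L, 2L))
})

test_that("OBO parsing extracts is_a and part_of parents", {
  f <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "",
    "[Term]", "id: GO:0000002", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003",
    "relationship: part_of GO:0000002 ! mid", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000099", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"
  ), f)
  ont <- load_obo(f)
  expect_setequal(ont$`GO:0000003`, c("GO:0000002", "GO:0000001"))
  expect_equal(ont$`GO:0000002`, "GO:0000001")
  expect_length(ont$`GO:0000001`, 0L)
  expect_false("GO:0000099" %in% names(ont))
})

test_that("ancestor propagation equals the brute-force transitive closure", {
  # child gains nothing, parent gains the child's genes
  ont <- list(child = "parent", parent = character(0))
  cat0 <- rwrscreen:::new_annotation_catalog(
    c("child", "parent"), list(child = "A", parent = character(0)))
  out <- propagate_ancestors(cat0, ont)
  expect_equal(out$term_to_genes$parent, "A")
  # a gene on the root only is unchanged
  cat_root <- rwrscreen:::new_annotation_catalog("parent", list(parent = "B"))
  expect_equal(propagate_ancestors(cat_root, ont)$term_to_genes$parent, "B")

  # random DAG: annotate genes to random terms, compare to closure oracle
  set.seed(31)
  for (rep in 1:5) {
    n_terms <- 12
    terms <- sprintf("T%02d", 1:n_terms)
    # edges only from lower to higher index -> acyclic by construction
    ont <- setNames(lapply(1:n_terms, function(i) {
      if (i == n_terms) return(character(0))
      cand <- terms[(i + 1):n_terms]
      cand[runif(length(cand)) < 0.25]
    }), terms)
    sets <- setNames(lapply(terms, function(t) {
      g <- sprintf("g%d", 1:8)
      g[runif(8) < 0.3]
    }), terms)
    out <- propagate_ancestors(
      rwrscreen:::new_annotation_catalog(terms, sets), ont)
    for (t in terms) {
      descendants <- terms[vapply(terms, function(d) {
        d == t || t %in% ancestors_bruteforce(ont, d)
      }, TRUE)]
      expected <- sort(unique(unlist(sets[descendants])))
      expect_equal(sort(out$term_to_genes[[t]]), expected)
      # supersets of the input
      expect_true(all(sets[[t]] %in% out$term_to_genes[[t]]))
    }
  }
  expect_error(propagate_ancestors(cat0, list(a = "b", b = "a")), "cycle")
})

test_that("binary feature vectors mark term membership", {
  cat0 <- rwrscreen:::new_annotation_catalog(
    c("T1", "T2"), list(T1 = c("A", "B"), T2 = "B"))
  expect_equal(unname(build_feature_vector("A", cat0)), c(1, 0))
  expect_equal(unname(build_feature_vector("B", cat0)), c(1, 1))
  expect_equal(unname(build_feature_vector("nobody", cat0)), c(0, 0))
  m <- build_feature_matrix(c("A", "B"), cat0)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(m %in% c(0, 1)))
})

test_that("neighbor-enrichment entries match exact hypergeometric tails", {
  net <- random_network(10, p_edge = 0.4, rng_seed = 8)
  cat0 <- rwrscreen:::new_annotation_catalog(
    c("T1", "T2", "T3"),
    list(T1 = net$nodes[1:4], T2 = net$nodes[c(2, 5, 7)], T3 = net$nodes[9]))
  genes <- net$nodes[c(1, 3, 6)]
  m <- build_feature_matrix(genes, cat0, encoding = "neighbor_enrichment",
                            network = net)
  e <- net$edges
  for (g in genes) {
    nbr <- unique(c(e$protein_b[e$protein_a == g], e$protein_a[e$protein_b == g]))
    for (t in cat0$terms) {
      tg <- cat0$term_to_genes[[t]]
      k <- sum(nbr %in% tg)
      p <- hyper_tail_bruteforce(k, length(tg), 10 - length(tg), length(nbr))
      expect_equal(m[g, t], max(0, -log10(p)), tolerance = 1e-10)
    }
  }
  expect_error(build_feature_matrix(genes, cat0, "neighbor_enrichment"),
               "network")
})

test_that("ancestor propagation cannot lower the enrichment cosine for nested annotations", {
  # gene g's terms are a subset of seed s's; both annotate into a small tree
  ont <- list(leaf1 = "mid", leaf2 = "mid", mid = "root",
              root = character(0))
  cat0 <- rwrscreen:::new_annotation_catalog(
    c("leaf1", "leaf2", "mid", "root"),
    list(leaf1 = c("g", "s"), leaf2 = "s", mid = character(0),
         root = character(0)))
  before <- suppressWarnings(
    max_enrichment_score("g", "s", build_feature_matrix(c("g", "s"), cat0)))
  after_cat <- propagate_ancestors(cat0, ont)
  after <- suppressWarnings(
    max_enrichment_score("g", "s", build_feature_matrix(c("g", "s"), after_cat)))
  expect_gte(after$mes, before$mes)
})

test_that("empty terms prune away without changing cosines", {
  cat0 <- rwrscreen:::new_annotation_catalog(
    c("T1", "Tempty", "T2"),
    list(T1 = c("A", "B"), Tempty = character(0), T2 = "A"))
  pruned <- prune_empty_terms(cat0)
  expect_equal(pruned$terms, c("T1", "T2"))
  m1 <- build_feature_matrix(c("A", "B"), cat0)
  m2 <- build_feature_matrix(c("A", "B"), pruned)
  cos <- function(m) sum(m[1, ] * m[2, ]) /
    (sqrt(sum(m[1, ]^2)) * sqrt(sum(m[2, ]^2)))
  expect_equal(cos(m1), cos(m2))
})
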