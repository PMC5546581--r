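#' Load a GMT gene-set file
#'
#' One term per line: term id, description, then tab-separated gene
#' identifiers. Duplicate term ids are merged by union with a warning; a
#' line with fewer than three fields (i.e. no genes after the description)
#' is a parse error reported with its line number.
#'
#' @param path Path to a GMT file.
#' @param source_kind Label for the catalog origin: \code{"GO"},
#'   \code{"KEGG"} or \code{"mixed"}.
#' @return An \code{annotation_catalog}: list with \code{terms} (ordered
#'   term ids — the fixed vector-dimension dictionary), \code{term_to_genes}
#'   (named list of character vectors), \code{source_kind}, and
#'   \code{ontology} (\code{NULL} until [propagate_ancestors()]).
#' @export
load_gmt <- function(path, source_kind = c("mixed", "GO", "KEGG")) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 3L | vapply(fields, function(f) all(!nzchar(f[-(1:2)])), TRUE)
  if (any(bad)) {
    stop("malformed GMT line ", line_no[which(bad)[1L]],
         ": expected term, description and >= 1 gene")
  }
  term_ids <- vapply(fields, `[[`, "", 1L)
  gene_sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (anyDuplicated(term_ids)) {
    warning("duplicate term id(s) merged by union: ",
            paste(unique(term_ids[duplicated(term_ids)]), collapse = ", "))
    gene_sets <- lapply(split(gene_sets, factor(term_ids, levels = unique(term_ids))),
                        function(gs) unique(unlist(gs)))
    term_ids <- unique(term_ids)
  } else {
    names(gene_sets) <- term_ids
  }
  new_annotation_catalog(term_ids, gene_sets, source_kind)
}

new_annotation_catalog <- function(terms, term_to_genes, source_kind = "mixed",
                                   ontology = NULL) {
  names(term_to_genes) <- terms
  structure(list(terms = terms, term_to_genes = term_to_genes,
                 source_kind = source_kind, ontology = ontology),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog (", x$source_kind, "):", length(x$terms), "terms,",
      length(unique(unlist(x$term_to_genes))), "genes\n")
  invisible(x)
}

#' Combine annotation catalogs
#'
#' Concatenates the term dictionaries of several catalogs (e.g. a GO and a
#' KEGG catalog) into one joint catalog so one feature vector spans both
#' sources. Duplicate term ids across catalogs are merged by union.
#'
#' @param ... \code{annotation_catalog} objects.
#' @return A single \code{annotation_catalog} with \code{source_kind}
#'   \code{"mixed"} unless all inputs agree.
#' @export
combine_catalogs <- function(...) {
  cats <- list(...)
  stopifnot(length(cats) >= 1L,
            all(vapply(cats, inherits, TRUE, "annotation_catalog")))
  if (length(cats) == 1L) return(cats[[1L]])
  terms <- unlist(lapply(cats, `[[`, "terms"), use.names = FALSE)
  sets <- unlist(lapply(cats, `[[`, "term_to_genes"), recursive = FALSE)
  if (anyDuplicated(terms)) {
    sets <- lapply(split(sets, factor(terms, levels = unique(terms))),
                   function(gs) unique(unlist(gs)))
    terms <- unique(terms)
  }
  kinds <- unique(vapply(cats, `[[`, "", "source_kind"))
  new_annotation_catalog(terms, sets,
                         if (length(kinds) == 1L) kinds else "mixed")
}

#' Parse a (minimal) OBO ontology into a parent graph
#'
#' Reads \code{[Term]} stanzas and returns, for every non-obsolete term, its
#' direct parents along \code{is_a} and \code{relationship: part_of} edges.
#'
#' @param path Path to an OBO file.
#' @return Named list: term id -> character vector of parent term ids. Terms
#'   without parents map to \code{character(0)}.
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path)
  parents <- list()
  id <- NULL
  obsolete <- FALSE
  flush <- function() {
    if (!is.null(id) && !obsolete && is.null(parents[[id]])) {
      parents[[id]] <<- character(0)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); id <- NULL; obsolete <- FALSE
    } else if (startsWith(ln, "[")) {
      flush(); id <- NULL  # [Typedef] etc.
    } else if (startsWith(ln, "id: ")) {
      id <- sub("^id: *", "", ln)
    } else if (startsWith(ln, "is_obsolete: true")) {
      obsolete <- TRUE
      if (!is.null(id)) parents[[id]] <- NULL
    } else if (!is.null(id) && !obsolete && startsWith(ln, "is_a: ")) {
      p <- sub("^is_a: *([^ !]+).*$", "\\1", ln)
      parents[[id]] <- c(parents[[id]], p)
    } else if (!is.null(id) && !obsolete &&
               grepl("^relationship: *part_of ", ln)) {
      p <- sub("^relationship: *part_of *([^ !]+).*$", "\\1", ln)
      parents[[id]] <- c(parents[[id]], p)
    }
  }
  flush()
  parents
}

topo_order_terms <- function(ontology) {
  # children before parents; errors on cycles
  terms <- union(names(ontology), unlist(ontology, use.names = FALSE))
  parent_of <- lapply(ontology, unique)
  indeg <- setNames(integer(length(terms)), terms)  # number of unprocessed children... use Kahn on child->parent edges
  for (p in unlist(parent_of, use.names = FALSE)) indeg[p] <- indeg[p] + 1L
  # Kahn: repeatedly remove nodes with no incoming child->parent edge (leaves first)
  order_out <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    v <- ready[[1L]]; ready <- ready[-1L]
    order_out <- c(order_out, v)
    for (p in parent_of[[v]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) ready <- c(ready, p)
    }
  }
  if (length(order_out) != length(terms)) stop("cycle detected in ontology")
  order_out
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' Every gene annotated to a term becomes annotated to all that term's
#' ancestors along \code{is_a}/\code{part_of}, so parent-term gene sets are
#' supersets of their descendants'. Catalog terms absent from the ontology
#' are kept unchanged; ancestor terms not in the catalog are appended.
#'
#' @param catalog An \code{annotation_catalog}.
#' @param ontology Parent graph from [load_obo()] (term -> direct parents).
#' @return A new \code{annotation_catalog}; each gene set is a superset of
#'   the input's.
#' @export
propagate_ancestors <- function(catalog, ontology) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  ord <- topo_order_terms(ontology)  # children before parents; checks acyclicity
  sets <- catalog$term_to_genes
  for (term in ord) {
    genes <- sets[[term]]
    if (is.null(genes) || !length(genes)) next
    for (p in ontology[[term]]) {
      sets[[p]] <- union(sets[[p]], genes)
    }
  }
  terms <- union(catalog$terms, names(sets)[lengths(sets) > 0L])
  sets <- sets[terms]
  sets[vapply(sets, is.null, TRUE)] <- list(character(0))
  new_annotation_catalog(terms, sets, catalog$source_kind, ontology = ontology)
}

#' Drop terms that annotate no gene
#'
#' Empty terms only pad the feature-vector dimension; removing them leaves
#' every cosine unchanged.
#'
#' @param catalog An \code{annotation_catalog}.
#' @return The pruned catalog.
#' @export
prune_empty_terms <- function(catalog) {
  keep <- lengths(catalog$term_to_genes) > 0L
  new_annotation_catalog(catalog$terms[keep], catalog$term_to_genes[keep],
                         catalog$source_kind, catalog$ontology)
}

#' Annotation feature vectors for a set of genes
#'
#' Encodes each gene's relationship to the catalog's terms as a numeric
#' vector aligned to the catalog's fixed term order. Two encodings:
#' \describe{
#'   \item{\code{binary}}{entry t is 1 iff the gene is annotated to term t
#'     (the default: deterministic and annotation-release-independent).}
#'   \item{\code{neighbor_enrichment}}{entry t is
#'     \eqn{\max(0, -\log_{10} p)} where p is the hypergeometric upper-tail
#'     probability of the overlap between the gene's direct network
#'     neighbors and term t's gene set, drawn against the universe of all
#'     network nodes.}
#' }
#' Genes with no annotation (and, under \code{neighbor_enrichment}, no
#' neighbors) get zero vectors and are screened downstream as mes = 0.
#'
#' @param genes Character vector of gene identifiers.
#' @param catalog An \code{annotation_catalog}.
#' @param encoding \code{"binary"} or \code{"neighbor_enrichment"}.
#' @param network A \code{ppi_network}; required for
#'   \code{neighbor_enrichment}.
#' @return Dense numeric matrix, genes x terms, with dimnames.
#' @export
build_feature_matrix <- function(genes, catalog,
                                 encoding = c("binary", "neighbor_enrichment"),
                                 network = NULL) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  encoding <- match.arg(encoding)
  terms <- catalog$terms
  m <- matrix(0, nrow = length(genes), ncol = length(terms),
              dimnames = list(genes, terms))
  if (encoding == "binary") {
    for (t in seq_along(terms)) {
      m[, t] <- as.numeric(genes %in% catalog$term_to_genes[[t]])
    }
  } else {
    if (is.null(network)) stop("neighbor_enrichment requires the network")
    nbrs <- neighbor_sets(network, genes)
    n_univ <- length(network$nodes)
    for (t in seq_along(terms)) {
      term_genes <- intersect(catalog$term_to_genes[[t]], network$nodes)
      k_term <- length(term_genes)
      if (!k_term) next
      for (g in seq_along(genes)) {
        ng <- nbrs[[genes[g]]]
        if (!length(ng)) next
        overlap <- sum(ng %in% term_genes)
        # P(X >= overlap), X ~ Hypergeom(n_univ, k_term, |neighbors|)
        p <- stats::phyper(overlap - 1L, k_term, n_univ - k_term,
                           length(ng), lower.tail = FALSE)
        m[g, t] <- max(0, -log10(p))
      }
    }
  }
  m
}

#' Feature vector of one gene
#'
#' @inheritParams build_feature_matrix
#' @param gene A single gene identifier.
#' @return Named numeric vector over the catalog's terms.
#' @export
build_feature_vector <- function(gene, catalog, encoding = "binary",
                                 network = NULL) {
  build_feature_matrix(gene, catalog, encoding, network)[1L, ]
}

neighbor_sets <- function(network, genes) {
  e <- network$edges
  a <- c(e$protein_a, e$protein_b)
  b <- c(e$protein_b, e$protein_a)
  keep <- a %in% genes
  sp <- split(b[keep], a[keep])
  out <- setNames(vector("list", length(genes)), genes)
  for (g in genes) out[[g]] <- unique(sp[[g]]) %||% character(0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Term dictionary of a catalog
#'
#' @param catalog An \code{annotation_catalog}.
#' @return data.frame \code{term_index}, \code{term_id}, \code{gene_count} —
#'   the fixed dimension dictionary of the feature vectors.
#' @export
term_dictionary <- function(catalog) {
  data.frame(term_index = seq_along(catalog$terms),
             term_id = catalog$terms,
             gene_count = unname(lengths(catalog$term_to_genes)),
             stringsAsFactors = FALSE)
}
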