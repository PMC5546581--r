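#' Load a STRING-style weighted edge list
#'
#' Reads a whitespace-separated interaction file in the STRING
#' \code{protein.links} dialect (columns \code{protein1 protein2
#' combined_score}, integer score in (0, 1000], optional single header line
#' starting with \code{"protein1"}, optionally gzip-compressed) and builds a
#' weighted undirected protein-protein interaction network.
#'
#' STRING lists every interaction twice (once per direction); the two
#' directed records are collapsed into one undirected edge. If the two
#' directions carry different scores the file is treated as corrupt and an
#' error is raised. Self-loops are dropped with a warning. When
#' \code{species_prefix} is given (e.g. \code{"9606."} for human), only
#' records where both identifiers carry the prefix are kept, and the prefix
#' is stripped, so seeds can be supplied as bare identifiers.
#'
#' @param path Path to the edge-list file (plain or \code{.gz}).
#' @param species_prefix Optional identifier prefix used to filter and strip
#'   records, e.g. \code{"9606."}.
#' @return A \code{ppi_network} object: list with \code{nodes} (identifiers
#'   in order of first appearance), \code{edges} (data.frame
#'   \code{protein_a}, \code{protein_b}, \code{score}, one row per
#'   undirected edge), \code{node_index} (named integer positions) and
#'   \code{n_directed_records} (count of directed records before collapsing,
#'   the convention under which STRING reports its interaction totals).
#' @seealso [build_transition_matrix()], [write_string_links()]
#' @export
load_string_links <- function(path, species_prefix = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("network file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  line_no <- seq_along(lines)

  blank <- !nzchar(trimws(lines))
  lines <- lines[!blank]
  line_no <- line_no[!blank]
  if (length(lines) && grepl("^protein1\\b", lines[[1L]])) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  if (!length(lines)) stop("no interaction records in ", path)

  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- line_no[which(nf < 3L)[1L]]
    stop("malformed line ", bad, ": expected >= 3 whitespace-separated fields")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  s_chr <- vapply(fields, `[[`, "", 3L)
  score <- suppressWarnings(as.integer(s_chr))
  if (anyNA(score) || any(as.numeric(s_chr) != score)) {
    bad <- line_no[which(is.na(score) | as.numeric(s_chr) != score)[1L]]
    stop("malformed line ", bad, ": non-integer combined_score")
  }
  if (any(score <= 0L | score > 1000L)) {
    bad <- line_no[which(score <= 0L | score > 1000L)[1L]]
    stop("malformed line ", bad, ": combined_score outside (0, 1000]")
  }

  if (!is.null(species_prefix)) {
    keep <- startsWith(a, species_prefix) & startsWith(b, species_prefix)
    a <- substring(a[keep], nchar(species_prefix) + 1L)
    b <- substring(b[keep], nchar(species_prefix) + 1L)
    score <- score[keep]
    if (!length(a)) stop("no records match species prefix '", species_prefix, "'")
  }

  # node set = every distinct identifier in the (filtered) record list, in
  # order of first appearance, including ids seen only in dropped self-loops
  # (they become isolated nodes with dangling transition columns)
  all_ids <- unique(as.vector(rbind(a, b)))
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop record(s) dropped")
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }
  if (!length(a)) stop("no edges remain after filtering")

  n_directed <- length(a)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  ref_score <- score[first][match(key, key[first])]
  if (any(score != ref_score)) {
    i <- which(score != ref_score)[1L]
    stop("conflicting scores for pair ", lo[i], " - ", hi[i],
         " (", ref_score[i], " vs ", score[i], ")")
  }

  nodes <- all_ids
  edges <- data.frame(protein_a = a[first], protein_b = b[first],
                      score = score[first], stringsAsFactors = FALSE)
  new_ppi_network(nodes, edges, n_directed_records = n_directed)
}

new_ppi_network <- function(nodes, edges, n_directed_records = 2L * nrow(edges)) {
  node_index <- seq_along(nodes)
  names(node_index) <- nodes
  structure(
    list(nodes = nodes, edges = edges, node_index = node_index,
         n_directed_records = n_directed_records),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "undirected edges (", x$n_directed_records, "directed records )\n")
  invisible(x)
}

#' Write a network back to the canonical edge-list dialect
#'
#' Writes one line per undirected edge as \code{node_a node_b score} with
#' \code{node_a < node_b} lexicographically, preceded by a
#' \code{protein1 protein2 combined_score} header, so a written network
#' round-trips through [load_string_links()].
#'
#' @param network A \code{ppi_network}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_string_links <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges
  lo <- pmin(e$protein_a, e$protein_b)
  hi <- pmax(e$protein_a, e$protein_b)
  ord <- order(lo, hi)
  lines <- c("protein1 protein2 combined_score",
             paste(lo[ord], hi[ord], e$score[ord]))
  writeLines(lines, path)
  invisible(path)
}

#' Column-normalized transition operator of a PPI network
#'
#' Builds the sparse column-stochastic matrix T with entry
#' \eqn{T_{vu} = S(u,v) / \sum_x S(u,x)}: the probability that a walker at
#' node \eqn{u} steps to neighbor \eqn{v}, proportional to the edge weight.
#' Isolated nodes (zero total weight) yield all-zero columns and are
#' reported as dangling nodes; their walk mass is handled at propagation
#' time by restart re-injection.
#'
#' @param network A \code{ppi_network}.
#' @return A \code{transition_matrix} object: list with \code{matrix}
#'   (\code{dgCMatrix}, N x N), \code{nodes}, and \code{dangling_nodes}
#'   (integer positions of zero-weight columns).
#' @export
build_transition_matrix <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  n <- length(network$nodes)
  if (n == 0L) stop("empty network")
  e <- network$edges
  ia <- network$node_index[e$protein_a]
  ib <- network$node_index[e$protein_b]
  w <- Matrix::sparseMatrix(
    i = c(ia, ib), j = c(ib, ia), x = as.numeric(c(e$score, e$score)),
    dims = c(n, n)
  )
  colsum <- Matrix::colSums(w)
  dangling <- which(colsum == 0)
  inv <- ifelse(colsum > 0, 1 / colsum, 0)
  tm <- w %*% Matrix::Diagonal(n, inv)
  structure(
    list(matrix = methods::as(tm, "CsparseMatrix"),
         nodes = network$nodes,
         dangling_nodes = as.integer(dangling)),
    class = "transition_matrix"
  )
}
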