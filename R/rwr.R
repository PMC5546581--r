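#' Map requested seed genes onto a network
#'
#' Seeds absent from the network are dropped with a warning; the remaining
#' members define the restart distribution. At least one seed must map.
#'
#' @param seed_ids Character vector of requested seed node identifiers.
#' @param network A \code{ppi_network}.
#' @return A \code{seed_set}: list with \code{members} (mapped, unique,
#'   input order), \code{requested} and \code{dropped}.
#' @export
make_seed_set <- function(seed_ids, network) {
  stopifnot(is.character(seed_ids), inherits(network, "ppi_network"))
  requested <- seed_ids
  seed_ids <- unique(seed_ids)
  present <- seed_ids %in% network$nodes
  dropped <- seed_ids[!present]
  members <- seed_ids[present]
  if (length(dropped)) {
    warning(length(dropped), " seed(s) not in the network were dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  if (!length(members)) stop("no seed maps onto the network")
  structure(list(members = members, requested = requested, dropped = dropped),
            class = "seed_set")
}

#' Restart distribution for a seed set
#'
#' Uniform mass 1/|seeds| on each mapped seed node, zero elsewhere; with the
#' full set of 106 mapped seeds each component is 1/106.
#'
#' @param seeds A \code{seed_set} (or character vector of node ids already in
#'   the network).
#' @param network A \code{ppi_network}.
#' @return Numeric vector of length N summing to 1.
#' @export
make_initial_vector <- function(seeds, network) {
  members <- if (inherits(seeds, "seed_set")) seeds$members else seeds
  stopifnot(inherits(network, "ppi_network"))
  if (!length(members)) stop("empty seed set")
  idx <- network$node_index[members]
  if (anyNA(idx)) stop("seed(s) not in network: ",
                       paste(members[is.na(idx)], collapse = ", "))
  p0 <- numeric(length(network$nodes))
  p0[idx] <- 1 / length(members)
  p0
}

#' Random walk with restart to convergence
#'
#' Iterates \eqn{P_{i+1} = (1 - c) T P_i + c P_0} until the norm of the
#' update falls below \code{tolerance}. \eqn{T} is the column-normalized
#' transition operator, so mass moves from each node to its neighbors in
#' proportion to edge weight; \eqn{c} is the restart probability. Mass that
#' would be lost at dangling (zero-weight) columns is re-injected through
#' the restart distribution, so \eqn{\sum P_i = 1} at every iteration.
#'
#' @param transition A \code{transition_matrix}.
#' @param p0 Initial/restart probability vector (sums to 1).
#' @param restart_prob Restart probability \eqn{c} in (0, 1]; default 0.8.
#' @param tolerance Convergence tolerance on the update norm; default 1e-6.
#' @param max_iter Iteration cap; exceeding it is an error, not a silent
#'   truncation.
#' @param norm Which norm of \eqn{P_{i+1} - P_i} to monitor: \code{"l1"}
#'   (default, standard in the network-propagation literature), \code{"l2"}
#'   or \code{"max"}.
#' @param trace_mass If \code{TRUE}, record \eqn{\sum P_i} after every
#'   iteration in the result's \code{mass_trace} (conservation diagnostic).
#' @return A \code{propagation_result}: list with \code{probabilities}
#'   (named by node), \code{iterations}, \code{final_delta},
#'   \code{restart_prob}, \code{converged}, and \code{mass_trace} when
#'   requested.
#' @export
rwr_propagate <- function(transition, p0, restart_prob = 0.8,
                          tolerance = 1e-6, max_iter = 10000L,
                          norm = c("l1", "l2", "max"), trace_mass = FALSE) {
  stopifnot(inherits(transition, "transition_matrix"))
  norm <- match.arg(norm)
  n <- length(transition$nodes)
  if (length(p0) != n) stop("p0 length does not match network size")
  if (abs(sum(p0) - 1) > 1e-9) stop("p0 must sum to 1")
  if (!(restart_prob > 0 && restart_prob <= 1)) stop("restart_prob must be in (0, 1]")
  if (tolerance <= 0) stop("tolerance must be positive")

  tm <- transition$matrix
  dangling <- transition$dangling_nodes
  delta_of <- switch(norm,
    l1  = function(d) sum(abs(d)),
    l2  = function(d) sqrt(sum(d * d)),
    max = function(d) max(abs(d))
  )

  p <- p0
  it <- 0L
  delta <- Inf
  mass <- if (trace_mass) numeric(0) else NULL
  repeat {
    stepped <- as.numeric(tm %*% p)
    lost <- if (length(dangling)) sum(p[dangling]) else 0
    p_new <- (1 - restart_prob) * stepped +
      (restart_prob + (1 - restart_prob) * lost) * p0
    it <- it + 1L
    delta <- delta_of(p_new - p)
    p <- p_new
    if (trace_mass) mass <- c(mass, sum(p))
    if (delta < tolerance) break
    if (it >= max_iter) {
      stop("RWR did not converge in ", max_iter,
           " iterations (last delta = ", format(delta), ")")
    }
  }
  names(p) <- transition$nodes
  structure(
    list(probabilities = p, iterations = it, final_delta = delta,
         restart_prob = restart_prob, converged = TRUE, mass_trace = mass),
    class = "propagation_result"
  )
}

#' Select propagated (RWR) genes above a probability threshold
#'
#' Non-seed nodes whose steady-state probability is strictly greater than
#' \code{threshold} (default 1e-5), sorted by probability descending with
#' ties broken by node identifier. Seed nodes are excluded: they are the
#' known genes, not novel candidates.
#'
#' @param result A converged \code{propagation_result}.
#' @param seeds A \code{seed_set}.
#' @param threshold Probability cutoff (strict); default 1e-5.
#' @return An \code{rwr_gene_set}: list with \code{entries} (data.frame
#'   \code{node_id}, \code{probability}) and \code{threshold}.
#' @export
select_rwr_genes <- function(result, seeds, threshold = 1e-5) {
  stopifnot(inherits(result, "propagation_result"))
  if (!isTRUE(result$converged)) stop("propagation result not converged")
  members <- if (inherits(seeds, "seed_set")) seeds$members else seeds
  p <- result$probabilities
  keep <- !(names(p) %in% members) & p > threshold
  df <- data.frame(node_id = names(p)[keep], probability = unname(p[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$probability, df$node_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(entries = df, threshold = threshold), class = "rwr_gene_set")
}

#' Ranked RWR output table
#'
#' All nodes ranked by probability (descending, ties by id), with a seed
#' flag — the structure of a full per-gene propagation report.
#'
#' @param result A \code{propagation_result}.
#' @param seeds A \code{seed_set}.
#' @return data.frame with columns \code{rank}, \code{node_id},
#'   \code{probability}, \code{is_seed}.
#' @export
rwr_rank_table <- function(result, seeds) {
  members <- if (inherits(seeds, "seed_set")) seeds$members else seeds
  p <- result$probabilities
  df <- data.frame(node_id = names(p), probability = unname(p),
                   is_seed = names(p) %in% members, stringsAsFactors = FALSE)
  df <- df[order(-df$probability, df$node_id), , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}
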