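#' Markov Cluster Algorithm parameters
#'
#' @param inflation Entrywise power applied each iteration; higher values
#'   sharpen the flow and yield finer clusters. Must exceed 1; default 3.
#' @param expansion Matrix-power applied each iteration (random-walk
#'   spreading); integer >= 2, default 2.
#' @param self_loop_weight Weight of the self-loop added to every node
#'   before column normalization; default 1.
#' @param prune_threshold Entries below this value are zeroed (with column
#'   renormalization) after each inflation; default 1e-5.
#' @param max_iterations Iteration cap; default 100.
#' @param convergence_tol Maximum absolute entry change at which the flow
#'   is declared converged; default 1e-8.
#' @return An `mcl_params` list.
#' @export
mcl_params <- function(inflation = 3, expansion = 2, self_loop_weight = 1,
                       prune_threshold = 1e-5, max_iterations = 100,
                       convergence_tol = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2, expansion == as.integer(expansion),
            self_loop_weight >= 0, prune_threshold >= 0,
            max_iterations >= 1, convergence_tol > 0)
  structure(
    list(inflation = inflation, expansion = as.integer(expansion),
         self_loop_weight = self_loop_weight,
         prune_threshold = prune_threshold,
         max_iterations = as.integer(max_iterations),
         convergence_tol = convergence_tol),
    class = "mcl_params"
  )
}

#' Cluster a network with the Markov Cluster Algorithm
#'
#' Simulates a stochastic flow on the undirected simple-graph view:
#' the adjacency matrix (plus self-loops) is column-normalized to a
#' column-stochastic matrix, then expansion (matrix power), inflation
#' (entrywise power with column renormalization), and pruning alternate
#' until the matrix stops changing. Clusters are read off the attractor
#' rows of the limit matrix; attractor systems are merged, and a node
#' claimed by several clusters is deterministically assigned to the
#' largest one (ties broken by the lexicographically smallest member
#' symbol). Dense matrices are used throughout -- the curated networks
#' this targets stay well under a few hundred nodes.
#'
#' @param net A `species_network` or undirected igraph with >= 1 node.
#' @param params An [mcl_params()] object.
#' @param weighted Use edge scores as flow capacities when available
#'   (default `FALSE`: unweighted adjacency).
#' @return A `cluster_partition` list: `clusters` (list of sorted symbol
#'   vectors, all sizes, ordered by size descending then first member),
#'   `singletons` (members of size-1 clusters), `n_iterations`,
#'   `converged`, `membership` (named cluster index per node).
#' @export
mcl_cluster <- function(net, params = mcl_params(), weighted = FALSE) {
  g <- as_undirected_view(net)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  if (n == 0L) stop("empty network")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    w <- rep(1, nrow(el))
    if (weighted && inherits(net, "species_network") &&
        any(!is.na(net$edges$score))) {
      for (i in seq_len(nrow(el))) {
        sel <- (net$edges$source == el[i, 1] & net$edges$target == el[i, 2]) |
               (net$edges$source == el[i, 2] & net$edges$target == el[i, 1])
        sc <- net$edges$score[sel]
        if (any(!is.na(sc))) w[i] <- max(sc, na.rm = TRUE)
      }
    }
    A[cbind(el[, 1], el[, 2])] <- w
    A[cbind(el[, 2], el[, 1])] <- w
  }
  diag(A) <- params$self_loop_weight
  M <- col_normalize(A)

  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(params$max_iterations)) {
    M_prev <- M
    # expansion: e-th matrix power
    Me <- M
    for (j in seq_len(params$expansion - 1L)) Me <- Me %*% M
    # inflation with renormalization
    Mi <- col_normalize(Me^params$inflation)
    # pruning with renormalization
    Mi[Mi < params$prune_threshold] <- 0
    M <- col_normalize(Mi)
    if (max(abs(M - M_prev)) < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", params$max_iterations,
            " iterations")
  }
  part <- interpret_mcl_matrix(M, nodes)
  part$n_iterations <- iter
  part$converged <- converged
  part
}

col_normalize <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

# Read clusters off the limit matrix: rows with positive diagonal mass are
# attractors; an attractor's cluster is the set of columns it attracts.
# Attractors attracting one another are merged into one attractor system;
# remaining multiply-claimed nodes go to the largest cluster (ties by
# lexicographically smallest member).
interpret_mcl_matrix <- function(M, nodes, eps = 1e-9) {
  n <- length(nodes)
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n) # degenerate fallback
  claims <- lapply(attractors, function(i) which(M[i, ] > eps))
  names(claims) <- as.character(attractors)

  # union attractor systems: attractors that claim each other share a cluster
  parent <- seq_along(attractors)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ai in seq_along(attractors)) {
    for (aj in seq_along(attractors)) {
      if (aj > ai && (attractors[aj] %in% claims[[ai]] ||
                      attractors[ai] %in% claims[[aj]])) {
        ri <- find(ai); rj <- find(aj)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_along(attractors), find, integer(1))
  systems <- split(seq_along(attractors), roots)
  clusters <- lapply(systems, function(ix) sort(unique(unlist(claims[ix]))))

  # deterministic resolution of multiply-claimed nodes: the pre-resolution
  # largest cluster wins, ties broken by the lexicographically smallest
  # member list
  claimed_by <- lapply(seq_len(n), function(j)
    which(vapply(clusters, function(cl) j %in% cl, logical(1))))
  sizes <- lengths(clusters)
  member_key <- vapply(clusters, function(cl)
    paste(sort(nodes[cl]), collapse = ","), character(1))
  for (j in seq_len(n)) {
    cb <- claimed_by[[j]]
    if (length(cb) > 1) {
      ord <- cb[order(-sizes[cb], member_key[cb])]
      keep <- ord[1]
      for (drop in setdiff(cb, keep)) {
        clusters[[drop]] <- setdiff(clusters[[drop]], j)
      }
    } else if (length(cb) == 0) {
      # not claimed by any attractor row (non-converged edge case):
      # follow the column's strongest flow
      best <- which.max(M[, j])
      owner <- which(vapply(clusters, function(cl) best %in% cl, logical(1)))
      if (length(owner)) clusters[[owner[1]]] <- sort(c(clusters[[owner[1]]], j))
      else clusters <- c(clusters, list(j))
    }
  }
  clusters <- unname(Filter(length, clusters))
  clusters <- lapply(clusters, function(cl) sort(nodes[cl]))
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1), 1))
  clusters <- clusters[ord]
  membership <- integer(0)
  for (i in seq_along(clusters)) membership[clusters[[i]]] <- i
  singles <- unlist(clusters[lengths(clusters) == 1])
  structure(
    list(
      clusters = clusters,
      singletons = if (is.null(singles)) character(0) else sort(singles),
      membership = membership[nodes],
      n_iterations = NA_integer_,
      converged = NA
    ),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf(
    "MCL partition: %d cluster(s) (%d singleton(s)), %s after %d iteration(s)\n",
    length(x$clusters), length(x$singletons),
    if (isTRUE(x$converged)) "converged" else "NOT converged",
    x$n_iterations
  ))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  [%d] n=%d: %s\n", i, length(cl),
                paste(utils::head(cl, 8), collapse = ", ")))
    if (length(cl) > 8) cat("      ...\n")
  }
  invisible(x)
}

#' Per-cluster quality statistics
#'
#' For each cluster: size, internal edge count, boundary edge count, and
#' conductance = boundary / min(cluster volume, complement volume), where a
#' set's volume is the sum of its members' degrees. A cluster with no
#' boundary edges has conductance 0.
#'
#' @param partition A `cluster_partition`.
#' @param net The clustered `species_network` (or undirected igraph).
#' @return Data frame `cluster`, `size`, `internal_edges`,
#'   `boundary_edges`, `conductance`.
#' @export
cluster_quality <- function(partition, net) {
  g <- as_undirected_view(net)
  deg <- igraph::degree(g)
  total_vol <- sum(deg)
  el <- igraph::as_edgelist(g)
  out <- lapply(seq_along(partition$clusters), function(i) {
    cl <- partition$clusters[[i]]
    inside <- el[, 1] %in% cl & el[, 2] %in% cl
    cross <- xor(el[, 1] %in% cl, el[, 2] %in% cl)
    vol <- sum(deg[cl])
    boundary <- sum(cross)
    cond <- if (boundary == 0) 0 else {
      boundary / min(vol, total_vol - vol)
    }
    data.frame(cluster = i, size = length(cl),
               internal_edges = sum(inside), boundary_edges = boundary,
               conductance = cond)
  })
  do.call(rbind, out)
}

#' Write a cluster report
#'
#' One row per cluster: id, size, conductance, pipe-separated members.
#'
#' @param partition A `cluster_partition`.
#' @param net The clustered network.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_cluster_table <- function(partition, net, path) {
  q <- cluster_quality(partition, net)
  q$members <- vapply(partition$clusters, paste, character(1),
                      collapse = "|")
  write_tsv(q[, c("cluster", "size", "internal_edges", "boundary_edges",
                  "conductance", "members")], path)
}
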