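# Independent brute-force oracles used across the suite. These deliberately
# avoid igraph and the package's own code paths: BFS over adjacency lists,
# triangle enumeration, naive set arithmetic.

# random undirected simple graph as a symmetric 0/1 adjacency matrix
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && runif(1) < p) A[i, j] <- A[j, i] <- 1L
  }
  dimnames(A) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  A
}

adjacency_to_network <- function(A) {
  nodes <- rownames(A)
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  k <- nrow(idx)
  edges <- data.frame(
    source = nodes[idx[, 1]], target = nodes[idx[, 2]],
    link_type = rep("physical", k), effect = rep("unspecified", k),
    species = rep("m", k), stage = rep("embryo", k),
    reference = rep("fix", k), origin = rep("literature", k),
    score = rep(NA_real_, k), cycle = rep(NA_integer_, k),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  structure(
    list(label = "fixture", species = "m", stages = "embryo",
         edges = edges,
         nodes = nodes, graph = g, self_loops = character(0),
         node_origin = NULL, cycle_index = NULL),
    class = "species_network"
  )
}

# single-source BFS distances over an adjacency matrix
bfs_distances <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] == 1L)
      new <- nb[dist[nb] == Inf]
      dist[new] <- dist[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  dist
}

# all nine topology parameters by brute force
oracle_topology <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(A) / 2
  D <- t(vapply(seq_len(n), function(s) bfs_distances(A, s), numeric(n)))
  ut <- D[upper.tri(D)]
  fin <- ut[is.finite(ut)]
  # components by repeated BFS
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (is.na(comp[s])) {
      cid <- cid + 1L
      comp[is.finite(D[s, ])] <- cid
    }
  }
  sizes <- tabulate(comp)
  big <- which.max(sizes)
  members <- which(comp == big)
  radius <- if (length(members) > 1) {
    min(vapply(members, function(v) max(D[v, members]), numeric(1)))
  } else 0
  # mean local clustering via triangle enumeration, degree<2 contributes 0
  local_cc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) < 2) return(0)
    links <- 0L
    for (i in seq_along(nb)) for (j in seq_along(nb)) {
      if (j > i && A[nb[i], nb[j]] == 1L) links <- links + 1L
    }
    links / choose(length(nb), 2)
  }, numeric(1))
  list(
    n_nodes = n, n_edges = m,
    avg_neighbors = if (n) 2 * m / n else 0,
    diameter = if (length(fin)) max(fin) else 0,
    radius = radius,
    characteristic_path_length = if (length(fin)) mean(fin) else 0,
    clustering_coefficient = mean(local_cc),
    density = if (n > 1) m / choose(n, 2) else 0,
    n_connected_components = cid
  )
}

# high-precision MCL flow simulation without pruning; clusters read off the
# attractor rows of the limit matrix: attractor systems merged, each
# multiply-claimed node given to the pre-resolution largest cluster (ties by
# lexicographically smallest member list)
oracle_mcl <- function(A, inflation = 3, expansion = 2,
                       self_loop = 1, iterations = 500, tol = 1e-12) {
  nodes <- rownames(A)
  M <- A * 1.0
  diag(M) <- self_loop
  norm <- function(X) sweep(X, 2, pmax(colSums(X), .Machine$double.eps), "/")
  M <- norm(M)
  for (it in seq_len(iterations)) {
    Mp <- M
    Me <- M
    for (j in seq_len(expansion - 1)) Me <- Me %*% M
    M <- norm(Me^inflation)
    if (max(abs(M - Mp)) < tol) break
  }
  eps <- 1e-8
  attractors <- which(diag(M) > eps)
  claims <- lapply(attractors, function(i) which(M[i, ] > eps))
  # merge attractor systems by naive repeated sweeps
  repeat {
    merged <- FALSE
    for (i in seq_along(claims)) {
      if (i > length(claims)) break
      for (j in seq_along(claims)) {
        if (j <= i || j > length(claims)) next
        if (attractors[j] %in% claims[[i]] ||
            attractors[i] %in% claims[[j]] ) {
          claims[[i]] <- sort(unique(c(claims[[i]], claims[[j]])))
          claims <- claims[-j]
          attractors <- attractors[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sizes <- lengths(claims)
  keys <- vapply(claims, function(cl) paste(sort(nodes[cl]), collapse = ","),
                 character(1))
  for (v in seq_len(nrow(A))) {
    cb <- which(vapply(claims, function(cl) v %in% cl, logical(1)))
    if (length(cb) > 1) {
      win <- cb[order(-sizes[cb], keys[cb])][1]
      for (d in setdiff(cb, win)) claims[[d]] <- setdiff(claims[[d]], v)
    }
  }
  claims <- Filter(length, claims)
  unname(lapply(claims, function(cl) sort(nodes[cl])))
}

# canonical form for comparing partitions as sets of sets
canonical_partition <- function(clusters) {
  lst <- lapply(unname(clusters), function(cl) sort(as.character(cl)))
  lst[order(vapply(lst, `[`, character(1), 1))]
}

# small interaction-record data frame builder
records_df <- function(src, tgt, species = "m", stage = "embryo",
                       link = "physical") {
  n <- length(src)
  as_interaction_collection(data.frame(
    source = src, target = tgt,
    link_type = rep_len(link, n), species = rep_len(species, n),
    stage = rep_len(stage, n),
    reference = sprintf("r%02d", seq_len(n)),
    stringsAsFactors = FALSE
  ))
}

# brute-force BH step-up rejection set
bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i / m * alpha) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}
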