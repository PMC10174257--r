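test_that("disconnected components never merge; trivial inputs converge", {
  # two disjoint triangles
  A <- matrix(0L, 6, 6, dimnames = list(sprintf("N%d", 1:6),
                                        sprintf("N%d", 1:6)))
  for (tr in list(1:3, 4:6)) {
    for (i in tr) for (j in tr) if (i != j) A[i, j] <- 1L
  }
  part <- mcl_cluster(adjacency_to_network(A))
  expect_true(part$converged)
  expect_equal(canonical_partition(part$clusters),
               canonical_partition(list(c("N1", "N2", "N3"),
                                        c("N4", "N5", "N6"))))

  single <- adjacency_to_network(random_adjacency(1, 0, seed = 1))
  p1 <- mcl_cluster(single)
  expect_equal(length(p1$clusters), 1)
  expect_equal(p1$singletons, "N01")
  expect_lte(p1$n_iterations, 2)
})

test_that("two 5-cliques joined by a bridge split at the bridge", {
  A <- matrix(0L, 10, 10, dimnames = list(sprintf("C%02d", 1:10),
                                          sprintf("C%02d", 1:10)))
  for (blk in list(1:5, 6:10)) {
    for (i in blk) for (j in blk) if (i != j) A[i, j] <- 1L
  }
  A[5, 6] <- A[6, 5] <- 1L
  part <- mcl_cluster(adjacency_to_network(A), mcl_params(inflation = 3))
  want <- oracle_mcl(A, inflation = 3) # high-precision, no pruning
  expect_equal(canonical_partition(part$clusters), canonical_partition(want))
  expect_equal(length(part$clusters), 2)
})

test_that("high-precision flow agrees with the independent simulation oracle on small graphs", {
  hp <- mcl_params(prune_threshold = 0, convergence_tol = 1e-12,
                   max_iterations = 500)
  for (case in 1:120) {
    n <- 3 + (case %% 10) # 3..12 nodes
    p <- c(0.2, 0.35, 0.5, 0.7)[1 + (case %% 4)]
    A <- random_adjacency(n, p, seed = 5000 + case)
    part <- mcl_cluster(adjacency_to_network(A), hp)
    want <- oracle_mcl(A)
    expect_equal(canonical_partition(part$clusters),
                 canonical_partition(want),
                 info = sprintf("case %d", case))
  }
})

test_that("partition structure is valid and cluster count bounds component count", {
  for (case in 1:60) {
    n <- 4 + (case %% 9)
    A <- random_adjacency(n, 0.25, seed = 6000 + case)
    net <- adjacency_to_network(A)
    part <- mcl_cluster(net)
    members <- unlist(part$clusters)
    expect_equal(sort(members), sort(net$nodes)) # disjoint cover
    expect_true(all(lengths(part$clusters) >= 1))
    comp <- oracle_topology(A)$n_connected_components
    expect_gte(length(part$clusters), comp)
  }
})

test_that("higher inflation yields at least as many clusters on average", {
  n_clusters <- function(r) {
    vapply(1:50, function(s) {
      set.seed(8000 + s)
      g <- igraph::sample_pa(30, m = 2, directed = FALSE)
      igraph::V(g)$name <- sprintf("P%02d", 1:30)
      length(mcl_cluster(g, mcl_params(inflation = r))$clusters)
    }, numeric(1))
  }
  expect_gte(mean(n_clusters(5)), mean(n_clusters(1.5)))
})

test_that("MCL at inflation 3 recovers planted partitions (ARI >= 0.9)", {
  skip_if_not_installed("mclust")
  hits <- 0
  for (s in 1:100) {
    c_communities <- c(2, 3, 4)[1 + (s %% 3)]
    set.seed(9000 + s)
    n <- 8 * c_communities
    truth <- rep(seq_len(c_communities), each = 8)
    g <- igraph::sample_sbm(
      n,
      pref.matrix = matrix(0.02, c_communities, c_communities) +
        diag(0.8 - 0.02, c_communities),
      block.sizes = rep(8, c_communities)
    )
    igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
    part <- mcl_cluster(g, mcl_params(inflation = 3))
    got <- part$membership[sprintf("V%02d", seq_len(n))]
    if (mclust::adjustedRandIndex(got, truth) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("conductance matches brute-force edge counting", {
  # isolated triangle next to a disjoint edge: conductance 0
  A <- matrix(0L, 5, 5, dimnames = list(sprintf("N%d", 1:5),
                                        sprintf("N%d", 1:5)))
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- A[1, 3] <- A[3, 1] <- 1L
  A[4, 5] <- A[5, 4] <- 1L
  net <- adjacency_to_network(A)
  part <- structure(list(clusters = list(c("N1", "N2", "N3"),
                                         c("N4", "N5"))),
                    class = "cluster_partition")
  q <- cluster_quality(part, net)
  expect_equal(q$conductance, c(0, 0))
  expect_equal(q$internal_edges, c(3, 1))

  # singleton attached by one edge in a 10-node graph: conductance 1
  B <- random_adjacency(10, 0.4, seed = 11)
  B[1, ] <- B[, 1] <- 0L
  B[1, 2] <- B[2, 1] <- 1L
  netB <- adjacency_to_network(B)
  partB <- structure(list(clusters = list("N01",
                                          sprintf("N%02d", 2:10))),
                     class = "cluster_partition")
  qB <- cluster_quality(partB, netB)
  expect_equal(qB$conductance[1], 1)

  # random bipartitions: equality with naive counting
  for (s in 1:20) {
    C <- random_adjacency(9, 0.35, seed = 1200 + s)
    netC <- adjacency_to_network(C)
    set.seed(s)
    side <- sample(c(TRUE, FALSE), 9, replace = TRUE)
    if (!any(side) || all(side)) next
    cl <- list(rownames(C)[side], rownames(C)[!side])
    q <- cluster_quality(structure(list(clusters = cl),
                                   class = "cluster_partition"), netC)
    deg <- rowSums(C)
    for (i in 1:2) {
      inside <- cl[[i]]
      boundary <- sum(C[inside, setdiff(rownames(C), inside)])
      vol <- sum(deg[inside])
      want <- if (boundary == 0) 0 else boundary / min(vol, sum(deg) - vol)
      expect_equal(q$conductance[i], want)
    }
  }
})
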