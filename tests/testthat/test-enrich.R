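test_that("hypergeometric p-values equal exhaustive draw enumeration for N <= 12", {
  for (N in 2:12) {
    for (K in 0:N) {
      for (n in 0:N) {
        draws <- utils::combn(N, max(n, 1))
        for (k in 0:min(n, K)) {
          got <- hypergeometric_test(k, n, K, N)
          want <- if (n == 0) as.numeric(k == 0) else {
            # universe 1..N, annotated 1..K; enumerate all C(N, n) draws
            mean(colSums(draws <= K) >= k)
          }
          expect_equal(got, want, tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric boundary cases and parameter validation", {
  expect_equal(hypergeometric_test(0, 5, 3, 20), 1)
  expect_equal(hypergeometric_test(4, 4, 4, 4), 1)
  # N=20, K=5, n=5, k=4: [C(5,4)C(15,1) + C(5,5)C(15,0)] / C(20,5)
  expect_equal(hypergeometric_test(4, 5, 5, 20),
               (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5))
  expect_error(hypergeometric_test(6, 5, 5, 20), "invalid")
  expect_error(hypergeometric_test(2, 5, 25, 20), "invalid")
})

test_that("BH q-values reproduce the brute-force step-up procedure", {
  for (s in 1:50) {
    set.seed(400 + s)
    m <- sample(3:25, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- p.adjust(p, method = "BH") # used by enrich_terms
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in p-rank
    for (alpha in c(0.01, 0.05, 0.2)) {
      expect_equal(q < alpha, bh_reject(p, alpha))
    }
  }
})

test_that("a fully-recovered term ranks first; foreign queries give empty results", {
  terms <- list(
    HIT = list(name = "hit", category = "pathway",
               macro_category = "nervous system",
               members = sprintf("G%02d", 1:8)),
    OTHER = list(name = "other", category = "pathway",
                 macro_category = "endocrine system",
                 members = sprintf("G%02d", 40:49))
  )
  ann <- annotation_collection(terms, universe = sprintf("G%02d", 1:80))
  res <- enrich_terms(sprintf("G%02d", 1:8), ann)
  expect_equal(res$term_id[1], "HIT")
  expect_true(res$significant[1])
  expect_equal(res$overlap[1], 8)

  expect_warning(res0 <- enrich_terms("ZZZ", ann), "empty effective query")
  expect_equal(nrow(res0), 0)
})

test_that("planted terms are recovered with high power at effect 0.8", {
  hits <- 0
  for (s in 1:100) {
    cfg <- synthetic_config(seed = 5000 + s, effect = 0.8, term_size = 10,
                            universe_size = 200)
    ann <- generate_annotations(cfg)
    res <- enrich_terms(ann$query, ann$annotations)
    sig <- res$term_id[res$significant]
    if (all(ann$planted_terms %in% sig)) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.95)
})

test_that("type-I error of the planted term is controlled under the null", {
  rejections <- 0
  for (s in 1:200) {
    cfg <- synthetic_config(seed = 20000 + s, effect = 0)
    ann <- generate_annotations(cfg)
    res <- enrich_terms(ann$query, ann$annotations)
    pr <- res$p_value[res$term_id == ann$planted_terms]
    if (length(pr) && pr < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / 200
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.12)
})

test_that("scored-source reader autodetects the 0-1000 scale and rejects self-pairs", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tscore", "X\tY\t900", "Y\tZ\t350"), tf)
  src <- read_scored_source(tf)
  expect_equal(sort(src$score), c(0.35, 0.9))
  expect_error(scored_source(data.frame(a = "X", b = "X", score = 0.5)),
               "self-pairs")
  expect_error(scored_source(data.frame(a = "X", b = "Y", score = -0.2)),
               "0, 1")
})

test_that("expansion honors the cutoff and records frontier growth cycles", {
  base <- build_network(records_df("A", "B"))
  src <- data.frame(a = c("A", "A"), b = c("C", "D"),
                    score = c(0.9, 0.3))
  en <- expand_network(base, src, cutoff = 0.4)
  expect_setequal(en$nodes, c("A", "B", "C"))
  expect_equal(unname(en$node_origin["C"]), "enriched")

  chain <- data.frame(a = c("A", "B2", "C2"), b = c("B2", "C2", "D2"),
                      score = 0.9)
  en2 <- expand_network(build_network(records_df("A", "A0")), chain,
                        cutoff = 0.4, cycles = 3, per_cycle = 1)
  expect_equal(unname(en2$cycle_index[c("B2", "C2", "D2")]), c(1L, 2L, 3L))
})

test_that("expansion is invariant to source-row order and monotone in the cutoff", {
  for (s in 1:100) {
    cfg <- synthetic_config(seed = 3000 + s, n_background_pairs = 120)
    coll <- generate_collection(cfg)
    base <- build_network(coll$records, species = "g")
    sc <- generate_scored_source(cfg, base)$source
    en1 <- expand_network(base, sc, cycles = 2, per_cycle = 5)
    if (s <= 20) { # permutation check on a subset (result must be identical)
      set.seed(s)
      perm <- sc[sample(nrow(sc)), ]
      en2 <- expand_network(base, perm, cycles = 2, per_cycle = 5)
      expect_identical(en1$nodes, en2$nodes)
      expect_identical(en1$cycle_index, en2$cycle_index)
      expect_equal(en1$edges[order(en1$edges$source, en1$edges$target), ],
                   en2$edges[order(en2$edges$source, en2$edges$target), ],
                   ignore_attr = TRUE)
    }
    # raising the cutoff never admits more nodes at the first cycle
    lo <- expand_network(base, sc, cutoff = 0.3, cycles = 1,
                         per_cycle = 10000)
    hi <- expand_network(base, sc, cutoff = 0.6, cycles = 1,
                         per_cycle = 10000)
    expect_true(all(hi$nodes %in% lo$nodes))
  }
})

test_that("expanded node additions equal a brute-force rank-and-add simulation", {
  cfg <- synthetic_config(seed = 99, n_background_pairs = 150)
  coll <- generate_collection(cfg)
  base <- build_network(coll$records, species = "e")
  hubs <- identify_hubs(base)
  seed_nodes <- hubs$hubs$symbol
  sc <- generate_scored_source(cfg, base)$source
  cutoff <- 0.4; per_cycle <- 4; cycles <- 3
  # independent simulation of the documented ranking rule
  current <- sort(unique(base$nodes))
  expected_added <- list()
  qual <- sc[sc$score >= cutoff, ]
  for (cyc in 1:cycles) {
    cand <- list()
    for (i in seq_len(nrow(qual))) {
      a <- qual$a[i]; b <- qual$b[i]
      if (a %in% current && !b %in% current) {
        cand[[b]] <- c(cand[[b]], qual$score[i])
      } else if (b %in% current && !a %in% current) {
        cand[[a]] <- c(cand[[a]], qual$score[i])
      }
    }
    if (!length(cand)) break
    df <- data.frame(sym = names(cand), links = lengths(cand),
                     ssum = vapply(cand, sum, numeric(1)))
    df <- df[order(-df$links, -df$ssum, df$sym), ]
    take <- head(df$sym, per_cycle)
    expected_added[[cyc]] <- take
    current <- c(current, take)
  }
  en <- expand_network(base, sc, cutoff = cutoff, cycles = cycles,
                       per_cycle = per_cycle)
  got_added <- split(names(en$cycle_index), en$cycle_index)
  for (cyc in seq_along(expected_added)) {
    expect_setequal(got_added[[as.character(cyc)]], expected_added[[cyc]])
  }
})

test_that("macro-category roll-up counts distinct significant terms", {
  terms <- list(
    T1 = list(name = "t1", category = "pathway",
              macro_category = "nervous system", members = c("A", "B", "C")),
    T2 = list(name = "t2", category = "pathway",
              macro_category = "nervous system", members = c("D", "E", "F")),
    T3 = list(name = "t3", category = "pathway",
              macro_category = "endocrine system", members = c("G", "H"))
  )
  ann <- annotation_collection(terms)
  fake <- function(ids) data.frame(term_id = ids,
                                   significant = rep(TRUE, length(ids)))
  mc <- macro_category_counts(fake(c("T1", "T2", "T3")), ann)
  expect_equal(unname(mc$per_network["nervous system", 1]), 2L)
  expect_equal(unname(mc$per_network["endocrine system", 1]), 1L)
  expect_equal(unname(mc$unique_totals), 3L)

  mc0 <- macro_category_counts(fake(character(0)), ann)
  expect_true(all(mc0$per_network == 0))
  expect_equal(mc0$pooled_total, 0)

  # enriched superset yields a strictly larger unique total
  mc2 <- macro_category_counts(list(lit = fake("T1"),
                                    enr = fake(c("T1", "T2", "T3"))), ann)
  expect_gt(mc2$unique_totals[["enr"]], mc2$unique_totals[["lit"]])
  expect_equal(mc2$pooled_total, 3)
})
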