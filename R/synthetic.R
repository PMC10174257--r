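# Seeded generators emulating the structure of the curated interaction
# collection, so every pipeline stage is testable offline. A single base
# seed is forked into independent sub-streams by fixed labels, so adding
# one generator never shifts another's output.

#' Default per-species interaction composition
#'
#' The per-species interaction counts and embryo/prepubertal split of the
#' curated literature collection (mouse 71/74, rat 0/28, human 9/0, horse
#' 3/25, cattle 0/2, chicken 68/2, zebrafish 4/0), which the synthetic
#' generators emulate by default.
#'
#' @return Integer matrix, species codes as rows (`m, r, h, e, b, g, d`)
#'   and stages as columns (`embryo`, `prepubertal`).
#' @export
default_interaction_counts <- function() {
  m <- matrix(
    c(71, 74,
      0, 28,
      9, 0,
      3, 25,
      0, 2,
      68, 2,
      4, 0),
    nrow = 7, byrow = TRUE,
    dimnames = list(SPECIES_CODES, STAGE_LEVELS)
  )
  storage.mode(m) <- "integer"
  m
}

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the structure of the curated collection: the
#' per-species and per-stage interaction counts, a 52:23:24
#' upstream:TF:downstream layer mixture, and preferential-attachment
#' topology (so generated networks carry the scale-free degree structure
#' the downstream power-law assessment expects). Scored-source scores are
#' Beta-distributed with the true-pair mean above and the background mean
#' below the 0.400 confidence cutoff.
#'
#' @param seed Base seed; with the same config and seed every output is
#'   byte-identical.
#' @param interaction_counts Integer species x stage matrix (rows `m, r,
#'   h, e, b, g, d`; columns `embryo`, `prepubertal`).
#' @param layer_props Mixture proportions for `upstream`, `TF`,
#'   `downstream` node layers.
#' @param topology `"preferential_attachment"`, `"planted_partition"`, or
#'   `"erdos_renyi"`.
#' @param pa_m Preferential-attachment edges per step (1 or 2).
#' @param er_p Edge probability for the Erdos-Renyi generator.
#' @param n_communities,community_size,p_intra,p_inter Planted-partition
#'   parameters.
#' @param physical_prob Probability that a generated interaction is a
#'   physical (vs functional) link.
#' @param conserved_core Number of shared "core" symbols injected into
#'   `conserved_species`, enabling cross-species conservation tests.
#' @param conserved_species Species codes receiving the conserved core.
#' @param universe_size,n_terms,term_size Annotation-collection shape.
#' @param n_planted Number of planted over-represented terms.
#' @param effect Fraction of a planted term's members forced into the
#'   emitted query set.
#' @param background_rate Probability that a non-planted universe symbol
#'   enters the query set.
#' @param true_partners_per_node Novel high-confidence partners per base
#'   node in the scored source.
#' @param n_background_pairs Background (low-score) pairs in the scored
#'   source.
#' @param high_shape,low_shape Beta shape pairs for true and background
#'   scores (defaults mean 0.8 and 0.2).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    interaction_counts = default_interaction_counts(),
    layer_props = c(upstream = 52, TF = 23, downstream = 24) / 99,
    topology = c("preferential_attachment", "planted_partition",
                 "erdos_renyi"),
    pa_m = 1L,
    er_p = 0.1,
    n_communities = 3L, community_size = 8L, p_intra = 0.8, p_inter = 0.02,
    physical_prob = 0.5,
    conserved_core = 0L,
    conserved_species = c("m", "e", "g", "r"),
    universe_size = 200L, n_terms = 40L, term_size = 10L,
    n_planted = 1L, effect = 0.8, background_rate = 0.05,
    true_partners_per_node = 2L, n_background_pairs = 200L,
    high_shape = c(8, 2), low_shape = c(2, 8)) {
  topology <- match.arg(topology)
  stopifnot(
    all(interaction_counts >= 0),
    abs(sum(layer_props) - 1) < 1e-8,
    physical_prob >= 0, physical_prob <= 1,
    effect >= 0, effect <= 1,
    background_rate >= 0, background_rate <= 1
  )
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic interaction collection with layer annotations
#'
#' For every species with a positive requested count, a species network of
#' the configured topology is generated with exactly the requested number
#' of distinct directed interactions, then each interaction is assigned a
#' developmental stage so the per-(species, stage) cell counts equal the
#' configuration exactly (not merely in expectation). Node symbols are
#' synthetic but stable under the seed; an optional conserved core of
#' shared symbols is injected into selected species.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (an `interaction_collection`) and
#'   `layers` (layer-annotation data frame covering every generated
#'   symbol).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  counts <- config$interaction_counts
  all_records <- list()
  all_symbols <- character(0)
  for (sp in rownames(counts)) {
    total <- sum(counts[sp, ])
    if (total == 0L) next
    set.seed(fork_seed(config$seed, paste0("collection/", sp)))
    pairs <- synth_edge_pairs(config, total)
    n_nodes <- max(pairs)
    symbols <- sprintf("%sT%03d", toupper(sp), seq_len(n_nodes))
    if (config$conserved_core > 0L && sp %in% config$conserved_species) {
      core <- sprintf("CORE%03d", seq_len(min(config$conserved_core,
                                              n_nodes)))
      symbols[seq_along(core)] <- core
    }
    flip <- stats::runif(total) < 0.5
    src <- ifelse(flip, symbols[pairs[, 1]], symbols[pairs[, 2]])
    tgt <- ifelse(flip, symbols[pairs[, 2]], symbols[pairs[, 1]])
    stage <- sample(rep(STAGE_LEVELS, counts[sp, ]))
    rec <- data.frame(
      source = src, target = tgt,
      link_type = ifelse(stats::runif(total) < config$physical_prob,
                         "physical", "functional"),
      effect = "unspecified",
      species = sp, stage = stage,
      reference = sprintf("synthref-%s-%03d", sp, seq_len(total)),
      stringsAsFactors = FALSE
    )
    all_records[[sp]] <- rec
    all_symbols <- c(all_symbols, symbols)
  }
  records <- if (length(all_records)) {
    as_interaction_collection(do.call(rbind, all_records))
  } else {
    as_interaction_collection(data.frame(
      source = character(0), target = character(0),
      link_type = character(0), species = character(0),
      stage = character(0), reference = character(0)
    ))
  }
  all_symbols <- unique(all_symbols)
  set.seed(fork_seed(config$seed, "layers"))
  layers <- data.frame(
    symbol = all_symbols,
    layer = if (length(all_symbols)) {
      sample(names(config$layer_props), length(all_symbols), replace = TRUE,
             prob = config$layer_props)
    } else character(0),
    origin = rep("literature", length(all_symbols)),
    stringsAsFactors = FALSE
  )
  list(records = records, layers = layers)
}

# Distinct undirected node-index pairs realizing `total` edges under the
# configured topology. RNG state is assumed seeded by the caller.
synth_edge_pairs <- function(config, total) {
  g <- switch(config$topology,
    preferential_attachment = {
      # with m edges per arriving vertex, n vertices give ~m*(n-1) edges;
      # generate a little extra and keep the first `total`
      n <- ceiling(total / config$pa_m) + 2L
      igraph::sample_pa(n, m = config$pa_m, directed = FALSE)
    },
    planted_partition = {
      nc <- config$n_communities
      igraph::sample_sbm(
        nc * config$community_size,
        pref.matrix = matrix(config$p_inter, nc, nc) +
          diag(config$p_intra - config$p_inter, nc),
        block.sizes = rep(config$community_size, nc)
      )
    },
    erdos_renyi = {
      n <- max(4L, ceiling(sqrt(2 * total / config$er_p)))
      igraph::sample_gnp(n, config$er_p)
    }
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  if (config$topology != "preferential_attachment") {
    # top up with extra vertices if the random draw fell short
    guard <- 0L
    while (nrow(el) < total && guard < 50L) {
      extra <- cbind(max(el, igraph::vcount(g)) + guard + 1L,
                     sample(max(el), 1L))
      el <- rbind(el, extra)
      guard <- guard + 1L
    }
  }
  if (nrow(el) < total) {
    stop("infeasible interaction count: requested ", total,
         " distinct edges but only ", nrow(el), " realizable")
  }
  el[seq_len(total), , drop = FALSE]
}

#' Generate a synthetic annotation collection with a planted query
#'
#' Terms are partitioned across the four macro-categories; `n_planted`
#' terms are over-represented in the emitted query set (a fraction
#' `effect` of each planted term's members is forced into the query),
#' while every other universe symbol enters at `background_rate`.
#'
#' @param config A [synthetic_config()].
#' @param symbols Optional molecule symbols to embed in the universe (for
#'   example, the node set of a generated collection), so annotation terms
#'   cover the molecules a pipeline run will query; the universe is padded
#'   with synthetic filler symbols up to `universe_size`.
#' @return A list with `annotations` (an `annotation_collection`),
#'   `planted_terms` (term ids), and `query` (character vector).
#' @export
generate_annotations <- function(config, symbols = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(fork_seed(config$seed, "annotations"))
  universe <- sort(unique(normalize_symbol(symbols %||% character(0))))
  n_fill <- max(0L, config$universe_size - length(universe))
  universe <- c(universe, sprintf("SYM%04d", seq_len(n_fill)))
  terms <- list()
  for (i in seq_len(config$n_terms)) {
    id <- sprintf("T%03d", i)
    terms[[id]] <- list(
      name = paste0("synthetic pathway ", i),
      category = "pathway",
      macro_category = MACRO_CATEGORIES[((i - 1L) %% 4L) + 1L],
      members = sample(universe, config$term_size)
    )
  }
  ann <- annotation_collection(terms, universe = universe)
  planted <- names(terms)[seq_len(config$n_planted)]
  forced <- unlist(lapply(planted, function(id) {
    mem <- terms[[id]]$members
    n_take <- round(config$effect * length(mem))
    if (n_take) sample(mem, n_take) else character(0)
  }))
  rest <- setdiff(universe, forced)
  background <- rest[stats::runif(length(rest)) < config$background_rate]
  list(annotations = ann, planted_terms = planted,
       query = sort(unique(c(forced, background))))
}

#' Generate a synthetic scored interaction source
#'
#' Emulates a combined-score interaction table: each base-network node is
#' linked to fresh "novel" partner symbols with scores from the
#' high-score Beta distribution (mean above the 0.400 cutoff), and
#' `n_background_pairs` random pairs get scores from the low-score
#' distribution (mean below the cutoff). No self-pairs are emitted. With
#' an empty base network only background pairs are produced.
#'
#' @param config A [synthetic_config()].
#' @param base_net A `species_network` whose nodes seed the true pairs
#'   (may be empty).
#' @return A list with `source` (a `scored_source`), `true_pairs`, and
#'   `novel_symbols`.
#' @export
generate_scored_source <- function(config, base_net) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(fork_seed(config$seed, "scored"))
  base_nodes <- if (inherits(base_net, "species_network")) base_net$nodes
                else unique(normalize_symbol(base_net))
  novel <- character(0)
  true_pairs <- data.frame(a = character(0), b = character(0),
                           score = numeric(0))
  if (length(base_nodes)) {
    k <- config$true_partners_per_node
    novel <- sprintf("NOVEL%04d", seq_len(k * length(base_nodes)))
    true_pairs <- data.frame(
      a = rep(base_nodes, each = k),
      b = novel,
      score = stats::rbeta(k * length(base_nodes), config$high_shape[1],
                           config$high_shape[2]),
      stringsAsFactors = FALSE
    )
  }
  pool <- c(base_nodes, novel,
            sprintf("BG%04d", seq_len(max(20L, config$n_background_pairs %/% 4L))))
  bg_a <- sample(pool, config$n_background_pairs, replace = TRUE)
  bg_b <- sample(pool, config$n_background_pairs, replace = TRUE)
  keep <- bg_a != bg_b
  bg_a <- bg_a[keep]; bg_b <- bg_b[keep]
  # one score draw per distinct unordered pair, so the emitted background
  # scores follow the low-score distribution exactly
  dup <- duplicated(paste(pmin(bg_a, bg_b), pmax(bg_a, bg_b)))
  bg_a <- bg_a[!dup]; bg_b <- bg_b[!dup]
  background <- data.frame(
    a = bg_a, b = bg_b,
    score = stats::rbeta(length(bg_a), config$low_shape[1],
                         config$low_shape[2]),
    stringsAsFactors = FALSE
  )
  # background never overrides a true pair's score
  tp_key <- paste(pmin(true_pairs$a, true_pairs$b),
                  pmax(true_pairs$a, true_pairs$b))
  bg_key <- paste(pmin(background$a, background$b),
                  pmax(background$a, background$b))
  background <- background[!bg_key %in% tp_key, , drop = FALSE]
  src <- scored_source(rbind(true_pairs, background))
  list(source = src, true_pairs = true_pairs, novel_symbols = novel)
}

#' Write a canonical synthetic fixture directory
#'
#' Materializes `collection.tsv`, `layers.tsv`, `annotations.tsv`, and
#' `scored_source.tsv` generated from one configuration, in the same TSV
#' dialects the parsers read.
#'
#' @param dir Output directory (created if needed).
#' @param config A [synthetic_config()].
#' @return The directory path, invisibly.
#' @export
make_fixtures <- function(dir, config = synthetic_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coll <- generate_collection(config)
  write_collection(coll$records, file.path(dir, "collection.tsv"))
  write_tsv(coll$layers, file.path(dir, "layers.tsv"))
  base <- build_network(coll$records, species = "m", label = "mNET")
  hs <- identify_hubs(base)
  hub_net <- new_species_network(
    label = "mNET.hubs", species = "m", stages = base$stages,
    edges = base$edges[base$edges$source %in% hs$hubs$symbol &
                       base$edges$target %in% hs$hubs$symbol, ,
                       drop = FALSE],
    extra_nodes = hs$hubs$symbol
  )
  sc <- generate_scored_source(config, hub_net)
  write_tsv(as.data.frame(sc$source), file.path(dir, "scored_source.tsv"))
  ann <- generate_annotations(
    config,
    symbols = c(coll$layers$symbol, sc$novel_symbols)
  )
  ann_df <- data.frame(
    term_id = names(ann$annotations$terms),
    name = vapply(ann$annotations$terms, `[[`, character(1), "name"),
    category = vapply(ann$annotations$terms, `[[`, character(1), "category"),
    macro_category = vapply(ann$annotations$terms, `[[`, character(1),
                            "macro_category"),
    members = vapply(ann$annotations$terms, function(t)
      paste(t$members, collapse = "|"), character(1)),
    stringsAsFactors = FALSE
  )
  write_tsv(ann_df, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
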