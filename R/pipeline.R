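#' Pipeline configuration
#'
#' Gathers input paths and the analysis constants: hub SD multiplier 1,
#' MCL inflation 3, confidence cutoff 0.400, FDR alpha 0.05, and three
#' expansion cycles. Stage-specific networks are built for every species
#' with at least `min_stage_records` interactions in each developmental
#' stage (default 10), which restricts the stage split to richly sampled
#' species.
#'
#' @param collection,layers,annotations,scored_source Input file paths
#'   (layers/annotations/scored_source may be `NULL` to skip the
#'   dependent stages).
#' @param species Species codes to analyze; default all seven.
#' @param hub_k Hub SD multiplier.
#' @param inflation MCL inflation.
#' @param cutoff Combined-score confidence cutoff.
#' @param alpha FDR significance level.
#' @param cycles Expansion cycles.
#' @param per_cycle Interactors admitted per cycle.
#' @param min_stage_records Minimum records per stage for a stage split.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(collection, layers = NULL, annotations = NULL,
                            scored_source = NULL,
                            species = SPECIES_CODES,
                            hub_k = 1, inflation = 3, cutoff = 0.400,
                            alpha = 0.05, cycles = 3, per_cycle = 10,
                            min_stage_records = 10, seed = 1L) {
  cfg <- list(
    collection = collection, layers = layers, annotations = annotations,
    scored_source = scored_source, species = species, hub_k = hub_k,
    inflation = inflation, cutoff = cutoff, alpha = alpha, cycles = cycles,
    per_cycle = per_cycle, min_stage_records = min_stage_records,
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; keys match the arguments of [pipeline_config()].
#' Values passed through `overrides` take precedence over the file, which
#' takes precedence over the defaults.
#'
#' @param path YAML file path.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full comparative network pipeline
#'
#' Executes, in order: collection parsing and validation; per-species
#' network construction (plus per-stage networks for species passing the
#' stage-split rule); topology, power-law assessment, and hub
#' identification per network; MCL clustering; hub-seeded network
#' expansion against the scored source; topology and hubs of the enriched
#' networks; term over-representation with macro-category roll-up for
#' literature and enriched node sets; layer stratification and stage
#' comparisons. One TSV per report plus a JSON run manifest (constants,
#' seed, input checksums, package version) are written to `out_dir`.
#' Reruns with identical inputs and configuration produce byte-identical
#' bundles.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `summary`,
#'   `networks`, `stage_networks`, `topology`, `hubs`, `clusters`,
#'   `enriched`, `enrichment`, `stratification`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(format(Sys.time(), "%H:%M:%S"), " [", name, "]")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("parse", parse_collection(config$collection))
  layers <- if (!is.null(config$layers)) {
    stage("layers", parse_layer_annotations(config$layers))
  }
  report <- stage("validate", validate_collection(records, layers))
  message("  records: ", report$n_records,
          " (duplicate groups: ", report$n_duplicate_groups,
          ", self-interactions: ", report$n_self_interactions, ")")

  summary <- stage("summarize", summarize_collection(records))
  comp_df <- data.frame(
    species = rownames(summary$counts),
    total = summary$species_totals,
    embryo = summary$counts[, "embryo"],
    prepubertal = summary$counts[, "prepubertal"],
    share_pct = summary$species_share_display
  )
  write_tsv(comp_df, file.path(out_dir, "composition.tsv"))

  present <- intersect(config$species,
                       rownames(summary$counts)[summary$species_totals > 0])
  networks <- stage("build", {
    nets <- lapply(present, function(sp) {
      build_network(records, species = sp, label = paste0(sp, "NET"))
    })
    stats::setNames(nets, present)
  })
  stage_species <- present[apply(
    summary$counts[present, , drop = FALSE] >= config$min_stage_records,
    1, all
  )]
  stage_networks <- stage("build-stages", {
    out <- list()
    for (sp in stage_species) {
      for (st in STAGE_LEVELS) {
        lbl <- paste0(sp, "NET.", st)
        out[[lbl]] <- build_network(records, species = sp, stage = st,
                                    label = lbl)
      }
    }
    out
  })
  all_nets <- c(networks, stage_networks)

  topo <- stage("topology", lapply(all_nets, function(net) {
    if (length(net$nodes)) compute_topology(net) else NULL
  }))
  write_topology_table(Filter(Negate(is.null), topo),
                       file.path(out_dir, "topology.tsv"))
  pl_fits <- lapply(Filter(Negate(is.null), topo), function(t) {
    fit_power_law(t$degree_distribution)
  })

  hubs <- stage("hubs", lapply(all_nets, function(net) {
    if (length(net$nodes) >= 2) identify_hubs(net, k = config$hub_k)
  }))
  hubs <- Filter(Negate(is.null), hubs)
  write_hub_table(hubs, file.path(out_dir, "hubs.tsv"), layers)
  if (length(hubs) >= 2) {
    write_tsv(shared_hub_table(hubs), file.path(out_dir, "shared_hubs.tsv"))
  }

  params <- mcl_params(inflation = config$inflation)
  clusters <- stage("mcl", lapply(all_nets, function(net) {
    if (length(net$nodes)) mcl_cluster(net, params)
  }))
  clusters <- Filter(Negate(is.null), clusters)
  for (lbl in names(clusters)) {
    write_cluster_table(clusters[[lbl]], all_nets[[lbl]],
                        file.path(out_dir, paste0("clusters_", lbl, ".tsv")))
  }

  enriched <- list()
  if (!is.null(config$scored_source)) {
    source <- stage("scored-source", read_scored_source(config$scored_source))
    enriched <- stage("expand", {
      out <- list()
      for (sp in names(networks)) {
        net <- networks[[sp]]
        if (!length(net$nodes)) next
        # hub-seeded expansion; species with too few nodes for the SD rule
        # seed with all nodes
        seed_nodes <- if (length(net$nodes) >= 2 &&
                          nrow(hubs[[sp]]$hubs %||% data.frame())) {
          hubs[[sp]]$hubs$symbol
        } else net$nodes
        seed_net <- subset_network(net, seed_nodes,
                                   label = paste0(sp, "NET.seed"))
        exp <- expand_network(seed_net, source, cutoff = config$cutoff,
                              cycles = config$cycles,
                              per_cycle = config$per_cycle)
        out[[sp]] <- merge_enriched(
          net,
          exp$edges[exp$edges$origin == "predicted",
                    c("source", "target", "score", "cycle")] |>
            stats::setNames(c("a", "b", "score", "cycle")),
          cutoff = config$cutoff
        )
      }
      out
    })
    enr_topo <- lapply(enriched, compute_topology)
    write_topology_table(enr_topo,
                         file.path(out_dir, "topology_enriched.tsv"))
    enr_hubs <- lapply(enriched, function(net) {
      if (length(net$nodes) >= 2) identify_hubs(net, k = config$hub_k)
    })
    write_hub_table(Filter(Negate(is.null), enr_hubs),
                    file.path(out_dir, "hubs_enriched.tsv"), layers)
  }

  enrichment <- list()
  if (!is.null(config$annotations)) {
    ann <- stage("annotations", read_annotations(config$annotations))
    enrichment <- stage("enrich", {
      res <- list()
      for (sp in names(networks)) {
        if (!length(networks[[sp]]$nodes)) next
        res[[paste0(sp, "NET")]] <- suppressMessages(
          enrich_terms(networks[[sp]]$nodes, ann, alpha = config$alpha)
        )
        if (sp %in% names(enriched)) {
          res[[paste0(sp, "NET.enriched")]] <- suppressMessages(
            enrich_terms(enriched[[sp]]$nodes, ann, alpha = config$alpha)
          )
        }
      }
      res
    })
    if (length(enrichment)) {
      all_res <- do.call(rbind, Map(function(lbl, df) {
        if (nrow(df)) cbind(network = lbl, df) else NULL
      }, names(enrichment), enrichment))
      if (!is.null(all_res)) {
        write_tsv(all_res, file.path(out_dir, "enrichment.tsv"))
      }
      mc <- macro_category_counts(enrichment, ann)
      mc_df <- data.frame(macro_category = rownames(mc$per_network),
                          mc$per_network, check.names = FALSE)
      write_tsv(mc_df, file.path(out_dir, "macro_categories.tsv"))
    }
  }

  stratification <- NULL
  if (!is.null(layers) && length(enriched)) {
    stratification <- stage("stratify", {
      out <- list()
      for (sp in names(enriched)) {
        out[[sp]] <- suppressMessages(
          stratify(enriched[[sp]]$nodes, layers,
                   origin = enriched[[sp]]$node_origin)
        )
      }
      out
    })
    strat_df <- do.call(rbind, Map(function(sp, s) {
      cbind(network = paste0(sp, "NET.enriched"), s$table)
    }, names(stratification), stratification))
    write_tsv(strat_df, file.path(out_dir, "stratification.tsv"))
  }

  comparisons <- NULL
  if (length(stage_networks)) {
    comparisons <- stage("compare", {
      out <- list()
      for (sp in stage_species) {
        a <- stage_networks[[paste0(sp, "NET.embryo")]]
        b <- stage_networks[[paste0(sp, "NET.prepubertal")]]
        v <- venn(a$nodes, b$nodes,
                  labels = paste0(sp, c(".embryo", ".prepubertal")))
        out[[sp]] <- v
      }
      out
    })
    venn_df <- do.call(rbind, lapply(comparisons, function(v) {
      data.frame(set_a = v$labels[1], set_b = v$labels[2],
                 size_a = v$size_a, size_b = v$size_b, shared = v$shared,
                 union = v$union, overlap_percent = v$overlap_percent)
    }))
    write_tsv(venn_df, file.path(out_dir, "stage_overlap.tsv"))
  }

  manifest <- list(
    package = "tenosig",
    version = as.character(utils::packageVersion("tenosig")),
    seed = config$seed,
    constants = list(
      hub_k = config$hub_k, inflation = config$inflation,
      cutoff = config$cutoff, alpha = config$alpha,
      cycles = config$cycles, per_cycle = config$per_cycle,
      min_stage_records = config$min_stage_records
    ),
    inputs = {
      paths <- Filter(Negate(is.null),
                      config[c("collection", "layers", "annotations",
                               "scored_source")])
      lapply(paths, function(p) unname(tools::md5sum(p)))
    },
    species = present,
    stage_split_species = stage_species
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    summary = summary, validation = report, networks = networks,
    stage_networks = stage_networks, topology = topo,
    power_law = pl_fits, hubs = hubs, clusters = clusters,
    enriched = enriched, enrichment = enrichment,
    stratification = stratification, comparisons = comparisons,
    manifest = manifest
  ))
}

# Induced subnetwork on a node set (used to seed expansion with hubs).
subset_network <- function(net, nodes, label = net$label) {
  edges <- net$edges[net$edges$source %in% nodes &
                     net$edges$target %in% nodes, , drop = FALSE]
  new_species_network(label = label, species = net$species,
                      stages = net$stages, edges = edges,
                      extra_nodes = nodes)
}
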