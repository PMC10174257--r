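#' Build a species-/stage-specific signaling network
#'
#' Filters an interaction collection by species and stage and assembles a
#' directed network whose edges are the distinct (source, target, link_type)
#' triples of the filtered records. An undirected simple-graph view --
#' antiparallel and parallel edges collapsed to one unordered pair,
#' self-loops excluded -- is derived for all topology, hub, and clustering
#' computations; direction and link type are retained as edge metadata.
#'
#' @param records An `interaction_collection`.
#' @param species Character vector of species codes to keep; `NULL` keeps
#'   all.
#' @param stage Character vector of stages to keep; `NULL` keeps all.
#' @param label Network label (e.g. `"mNET"`); autogenerated when `NULL`.
#' @return A `species_network` list: `label`, `species`, `stages`, `edges`
#'   (directed edge data frame with `source`, `target`, `link_type`,
#'   `origin`, `score`, `cycle`), `nodes`, `graph` (the undirected simple
#'   igraph view), `self_loops` (symbols with a self-interaction).
#' @export
build_network <- function(records, species = NULL, stage = NULL,
                          label = NULL) {
  records <- as.data.frame(records)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(species)) keep <- keep & records$species %in% species
  if (!is.null(stage)) keep <- keep & records$stage %in% stage
  sub <- records[keep, , drop = FALSE]
  if (is.null(label)) {
    label <- paste0(paste(sort(unique(sub$species)), collapse = ""), "NET")
    if (!is.null(stage)) label <- paste(label, paste(stage, collapse = "+"),
                                        sep = ".")
  }
  edges <- unique(sub[, c("source", "target", "link_type"), drop = FALSE])
  rownames(edges) <- NULL
  if (nrow(edges)) {
    edges$origin <- "literature"
    edges$score <- NA_real_
    edges$cycle <- NA_integer_
  } else {
    edges$origin <- character(0)
    edges$score <- numeric(0)
    edges$cycle <- integer(0)
  }
  net <- new_species_network(
    label = label,
    species = sort(unique(sub$species)),
    stages = sort(unique(sub$stage)),
    edges = edges
  )
  if (nrow(sub) == 0L) {
    message("filter produced an empty network for label '", label, "'")
  }
  net
}

# Internal constructor: derives node set, undirected simple view, and
# self-loop list from a directed edge table.
new_species_network <- function(label, species, stages, edges,
                                extra_nodes = character(0),
                                node_origin = NULL, cycle_index = NULL,
                                class = "species_network") {
  nodes <- sort(unique(c(edges$source, edges$target, extra_nodes)))
  loops <- sort(unique(edges$source[edges$source == edges$target]))
  nonloop <- edges[edges$source != edges$target, , drop = FALSE]
  if (nrow(nonloop)) {
    pair <- unique(data.frame(
      a = pmin(nonloop$source, nonloop$target),
      b = pmax(nonloop$source, nonloop$target),
      stringsAsFactors = FALSE
    ))
    pair <- pair[order(pair$a, pair$b), , drop = FALSE]
    g <- igraph::graph_from_data_frame(pair, directed = FALSE,
                                       vertices = data.frame(name = nodes))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE)
    if (length(nodes)) g <- igraph::add_vertices(g, length(nodes),
                                                 name = nodes)
  }
  structure(
    list(
      label = label, species = species, stages = stages,
      edges = edges, nodes = nodes, graph = g, self_loops = loops,
      node_origin = node_origin, cycle_index = cycle_index
    ),
    class = unique(c(class, "species_network"))
  )
}

#' @export
print.species_network <- function(x, ...) {
  cat(sprintf(
    "<%s> %s: %d nodes, %d directed edges, %d undirected pairs, %d self-loop(s)\n",
    class(x)[1], x$label, length(x$nodes), nrow(x$edges),
    igraph::ecount(x$graph), length(x$self_loops)
  ))
  if (!is.null(x$node_origin)) {
    tab <- table(x$node_origin)
    cat("  node origin:", paste(names(tab), as.integer(tab), sep = "=",
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of undirected pairs in the simple-graph view
#' @param net A `species_network`.
#' @return Integer edge count of the undirected simple view.
#' @export
n_undirected_edges <- function(net) igraph::ecount(net$graph)

#' Merge predicted interactions into an enriched network
#'
#' Combines a literature network with a table of predicted scored
#' interactions (for example, candidates admitted by [expand_network()]).
#' Predicted edges below the confidence cutoff are rejected and logged.
#' Each node is flagged `literature` (literature only), `common` (present
#' in both the literature network and the predicted pair set), or
#' `enriched` (introduced by prediction only); enriched nodes also carry
#' the expansion cycle at which they entered. Literature edges are never
#' overwritten by predicted duplicates.
#'
#' @param base A `species_network` built from literature records.
#' @param predicted Data frame with columns `a`, `b`, `score`, and
#'   optionally `cycle` (defaults to 1).
#' @param cutoff Minimum combined score for a predicted edge (default
#'   0.400, the medium-confidence threshold).
#' @return An `enriched_network` (subclass of `species_network`) with
#'   `node_origin`, `cycle_index`, and `origin_counts`.
#' @export
merge_enriched <- function(base, predicted, cutoff = 0.400) {
  predicted <- as.data.frame(predicted)
  if (nrow(predicted) && !"cycle" %in% names(predicted)) predicted$cycle <- 1L
  if (nrow(predicted)) {
    predicted$a <- normalize_symbol(predicted$a)
    predicted$b <- normalize_symbol(predicted$b)
    low <- predicted$score < cutoff
    if (any(low)) {
      message(sum(low), " predicted edge(s) below cutoff ", cutoff,
              " rejected")
      predicted <- predicted[!low, , drop = FALSE]
    }
  }
  lit_nodes <- base$nodes
  pred_nodes <- sort(unique(c(predicted$a, predicted$b)))
  new_nodes <- setdiff(pred_nodes, lit_nodes)

  # drop predicted duplicates of existing undirected literature pairs
  lit_pairs <- paste(pmin(base$edges$source, base$edges$target),
                     pmax(base$edges$source, base$edges$target))
  if (nrow(predicted)) {
    pred_pair <- paste(pmin(predicted$a, predicted$b),
                       pmax(predicted$a, predicted$b))
    predicted <- predicted[!pred_pair %in% lit_pairs, , drop = FALSE]
    predicted <- predicted[!duplicated(paste(pmin(predicted$a, predicted$b),
                                             pmax(predicted$a, predicted$b))),
                           , drop = FALSE]
  }
  pred_edges <- data.frame(
    source = predicted$a, target = predicted$b,
    link_type = rep("functional", nrow(predicted)),
    origin = rep("predicted", nrow(predicted)),
    score = predicted$score,
    cycle = as.integer(predicted$cycle),
    stringsAsFactors = FALSE
  )
  edges <- rbind(base$edges, pred_edges)
  rownames(edges) <- NULL

  origin <- stats::setNames(rep("literature", length(lit_nodes)), lit_nodes)
  origin[intersect(lit_nodes, pred_nodes)] <- "common"
  origin[new_nodes] <- "enriched"

  cycle_index <- integer(0)
  if (length(new_nodes) && nrow(predicted)) {
    for (s in new_nodes) {
      cyc <- predicted$cycle[predicted$a == s | predicted$b == s]
      cycle_index[s] <- as.integer(min(cyc))
    }
  }
  net <- new_species_network(
    label = paste0(base$label, ".enriched"),
    species = base$species, stages = base$stages, edges = edges,
    extra_nodes = lit_nodes,
    node_origin = origin[sort(names(origin))],
    cycle_index = cycle_index,
    class = "enriched_network"
  )
  net$origin_counts <- c(
    literature = sum(origin == "literature"),
    common = sum(origin == "common"),
    enriched = sum(origin == "enriched")
  )
  net
}

#' Export a network to a standard graph format
#'
#' Formats: `"sif"` writes one `source<TAB>link_type<TAB>target` line per
#' directed edge; `"graphml"` writes GraphML 1.0 with node attributes
#' `origin`/`layer` and edge attributes `link_type`/`score`; `"edge-tsv"`
#' writes the directed edge table in the canonical TSV dialect
#' (re-importable with [import_edge_tsv()]).
#'
#' @param net A `species_network`.
#' @param format One of `"sif"`, `"graphml"`, `"edge-tsv"`.
#' @param path Output path.
#' @param layers Optional layer-annotation data frame used for GraphML node
#'   attributes.
#' @return The path, invisibly.
#' @export
export_graph <- function(net, format = c("sif", "graphml", "edge-tsv"),
                         path, layers = NULL) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$link_type,
                     net$edges$target)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else if (format == "edge-tsv") {
    write_tsv(net$edges[, c("source", "target", "link_type", "origin",
                            "score", "cycle")], path)
  } else {
    write_graphml(net, path, layers)
  }
  invisible(path)
}

write_graphml <- function(net, path, layers = NULL) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keydef <- function(id, dom, name, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom,
                        `attr.name` = name, `attr.type` = type)
  }
  keydef("d_origin", "node", "origin", "string")
  keydef("d_layer", "node", "layer", "string")
  keydef("d_link", "edge", "link_type", "string")
  keydef("d_score", "edge", "score", "double")
  graph <- xml2::xml_add_child(doc, "graph", id = net$label,
                               edgedefault = "directed")
  layer_of <- if (!is.null(layers)) {
    stats::setNames(layers$layer, layers$symbol)
  } else c()
  for (v in net$nodes) {
    nd <- xml2::xml_add_child(graph, "node", id = v)
    org <- if (!is.null(net$node_origin)) net$node_origin[[v]] %||% "literature"
           else "literature"
    d <- xml2::xml_add_child(nd, "data", key = "d_origin")
    xml2::xml_text(d) <- org
    if (v %in% names(layer_of)) {
      d <- xml2::xml_add_child(nd, "data", key = "d_layer")
      xml2::xml_text(d) <- unname(layer_of[v])
    }
  }
  for (i in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(graph, "edge",
                              source = net$edges$source[i],
                              target = net$edges$target[i])
    d <- xml2::xml_add_child(ed, "data", key = "d_link")
    xml2::xml_text(d) <- net$edges$link_type[i]
    if (!is.na(net$edges$score[i])) {
      d <- xml2::xml_add_child(ed, "data", key = "d_score")
      xml2::xml_text(d) <- format(net$edges$score[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-import a directed edge table written by [export_graph()]
#'
#' @param path Path to an edge-TSV file.
#' @param label Label for the reconstructed network.
#' @return A `species_network` with the same directed edge set.
#' @export
import_edge_tsv <- function(path, label = "imported") {
  df <- read_delim_auto(path, "\t")
  df$score <- suppressWarnings(as.numeric(df$score))
  df$cycle <- suppressWarnings(as.integer(df$cycle))
  new_species_network(label = label, species = character(0),
                      stages = character(0), edges = df)
}
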