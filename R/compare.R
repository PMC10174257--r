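#' Two-set Venn comparison
#'
#' Computes set sizes, shared and union counts, and the overlap percentage
#' defined as 100 * |A intersect B| / |A union B| (Jaccard index as a
#' percentage), rounded to the nearest integer with exact halves rounded
#' down.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @param labels Length-2 character vector of set labels.
#' @return A `venn_result` list: `labels`, `size_a`, `size_b`, `shared`,
#'   `union`, `overlap_percent`, and `members` (lists `a_only`, `shared`,
#'   `b_only`).
#' @export
venn <- function(set_a, set_b, labels = c("A", "B")) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  shared <- intersect(a, b)
  uni <- union(a, b)
  structure(
    list(
      labels = labels,
      size_a = length(a), size_b = length(b),
      shared = length(shared), union = length(uni),
      overlap_percent = if (length(uni)) {
        round_half_down(100 * length(shared) / length(uni))
      } else 0,
      members = list(a_only = sort(setdiff(a, b)), shared = sort(shared),
                     b_only = sort(setdiff(b, a)))
    ),
    class = "venn_result"
  )
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf(
    "Venn %s vs %s: |A|=%d |B|=%d shared=%d union=%d overlap=%d%%\n",
    x$labels[1], x$labels[2], x$size_a, x$size_b, x$shared, x$union,
    x$overlap_percent
  ))
  invisible(x)
}

#' Stratify nodes into signaling layers
#'
#' Summarizes a node set over the three-tier signaling stratification
#' (upstream ligands/receptors/transducers, transcription factors,
#' downstream effectors): per-layer totals, counts of newly enriched
#' molecules (origin `"enriched"`), and the percentage of new molecules
#' per layer (nearest integer, exact halves rounded down). Nodes without
#' a layer annotation are reported in `uncovered` and excluded from the
#' totals.
#'
#' @param nodes Character vector of molecule symbols.
#' @param layers Layer-annotation data frame (`symbol`, `layer`), see
#'   [parse_layer_annotations()].
#' @param origin Named character vector symbol -> origin
#'   (`literature`/`common`/`enriched`), e.g. the `node_origin` field of
#'   an `enriched_network`. Missing symbols count as literature.
#' @return A `layer_summary` list with `table` (data frame `layer`,
#'   `total`, `new`, `percent_new`) and `uncovered`.
#' @export
stratify <- function(nodes, layers, origin = NULL) {
  nodes <- unique(normalize_symbol(nodes))
  layer_of <- stats::setNames(layers$layer, normalize_symbol(layers$symbol))
  if (!is.null(origin)) names(origin) <- normalize_symbol(names(origin))
  covered <- nodes[nodes %in% names(layer_of)]
  uncovered <- sort(setdiff(nodes, covered))
  if (length(uncovered)) {
    message(length(uncovered), " node(s) without layer annotation excluded")
  }
  is_new <- if (is.null(origin)) {
    stats::setNames(rep(FALSE, length(covered)), covered)
  } else {
    stats::setNames(unname(origin[covered]) == "enriched", covered)
  }
  is_new[is.na(is_new)] <- FALSE
  tab <- data.frame(layer = LAYER_LEVELS, total = 0L, new = 0L,
                    percent_new = 0, stringsAsFactors = FALSE)
  for (i in seq_along(LAYER_LEVELS)) {
    in_layer <- covered[layer_of[covered] == LAYER_LEVELS[i]]
    tab$total[i] <- length(in_layer)
    tab$new[i] <- sum(is_new[in_layer])
    tab$percent_new[i] <- if (tab$total[i]) {
      round_half_down(100 * tab$new[i] / tab$total[i])
    } else 0
  }
  structure(list(table = tab, uncovered = uncovered),
            class = "layer_summary")
}

#' @export
print.layer_summary <- function(x, ...) {
  cat("Signaling-layer stratification\n")
  print(x$table, row.names = FALSE)
  if (length(x$uncovered)) {
    cat("  uncovered:", length(x$uncovered), "node(s)\n")
  }
  invisible(x)
}

#' Cross-tabulate shared nodes between two cluster partitions
#'
#' For each shared node, reports its cluster index in each partition
#' (e.g. the embryo- and prepubertal-stage networks) and whether its
#' cluster context differs. Shared nodes missing from a partition are
#' flagged.
#'
#' @param partition_a,partition_b `cluster_partition` objects.
#' @param shared Character vector of shared node symbols.
#' @param labels Length-2 labels for the two partitions.
#' @return Data frame `node`, `<label_a>`, `<label_b>`, `flagged`, with an
#'   attribute `n_changed` counting nodes whose co-members differ between
#'   the two partitions.
#' @export
stage_cluster_crosstab <- function(partition_a, partition_b, shared,
                                   labels = c("A", "B")) {
  shared <- unique(normalize_symbol(shared))
  get <- function(p, s) {
    if (s %in% names(p$membership)) p$membership[[s]] else NA_integer_
  }
  rows <- lapply(shared, function(s) {
    ca <- get(partition_a, s)
    cb <- get(partition_b, s)
    data.frame(node = s, a = ca, b = cb, flagged = is.na(ca) || is.na(cb),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(0), a = integer(0), b = integer(0),
               flagged = logical(0))
  names(df)[2:3] <- labels
  # context change: the node's cluster co-membership (restricted to shared
  # nodes) differs between the partitions
  n_changed <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$flagged[i]) next
    s <- df$node[i]
    co_a <- intersect(partition_a$clusters[[df[[labels[1]]][i]]], shared)
    co_b <- intersect(partition_b$clusters[[df[[labels[2]]][i]]], shared)
    if (!setequal(co_a, co_b)) n_changed <- n_changed + 1L
  }
  attr(df, "n_changed") <- n_changed
  df
}
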