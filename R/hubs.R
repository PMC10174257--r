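#' Identify hub nodes by the mean-plus-k-SD degree rule
#'
#' A hub is a hyperconnected node: its degree (on the undirected simple
#' view) is at least `k` standard deviations above the network's mean
#' degree. The boundary is inclusive -- a node whose degree equals the
#' threshold is a hub -- and the default standard deviation is the
#' population SD of the degree list; sample SD is available because it
#' shifts borderline memberships.
#'
#' @param net A `species_network` or undirected igraph with at least two
#'   nodes.
#' @param k Non-negative SD multiplier (default 1).
#' @param sd_kind `"population"` (default) or `"sample"`.
#' @return A `hub_set` list: `label`, `degree_mean`, `degree_sd`, `k`,
#'   `threshold`, `hubs` (data frame `symbol`, `degree` sorted by degree
#'   descending, ties lexicographic).
#' @export
identify_hubs <- function(net, k = 1, sd_kind = c("population", "sample")) {
  sd_kind <- match.arg(sd_kind)
  stopifnot(k >= 0)
  g <- as_undirected_view(net)
  deg <- igraph::degree(g)
  if (length(deg) < 2) stop("hub identification needs >= 2 nodes (SD undefined)")
  mu <- mean(deg)
  sdv <- if (sd_kind == "sample") stats::sd(deg) else {
    sqrt(mean((deg - mu)^2))
  }
  thr <- mu + k * sdv
  tab <- degree_table(g)
  hubs <- tab[tab$degree >= thr, , drop = FALSE]
  rownames(hubs) <- NULL
  structure(
    list(
      label = if (inherits(net, "species_network")) net$label else NA,
      degree_mean = mu, degree_sd = sdv, k = k, threshold = thr,
      hubs = hubs
    ),
    class = "hub_set"
  )
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf(
    "Hub set%s: mean degree %.3f, SD %.3f, threshold %.3f (k = %g)\n",
    if (!is.na(x$label)) paste0(" (", x$label, ")") else "",
    x$degree_mean, x$degree_sd, x$threshold, x$k
  ))
  if (nrow(x$hubs)) print(x$hubs, row.names = FALSE) else cat("  no hubs\n")
  invisible(x)
}

#' Cross-network hub conservation table
#'
#' Lists, for every symbol that is a hub anywhere, the networks in which it
#' is a hub, ordered by how widely it is shared (then by symbol). This is
#' the cross-species conservation view used to spot regulators that hub in
#' several model organisms.
#'
#' @param hubsets A named list of `hub_set` objects (names default to each
#'   set's label).
#' @return Data frame `symbol`, `n_networks`, `networks`
#'   (comma-separated labels), sorted by `n_networks` descending then
#'   `symbol`.
#' @export
shared_hub_table <- function(hubsets) {
  if (length(hubsets) < 2) stop("need at least 2 hub sets")
  labels <- names(hubsets)
  if (is.null(labels)) labels <- rep(NA_character_, length(hubsets))
  labels <- ifelse(is.na(labels) | !nzchar(labels),
                   vapply(hubsets, function(h) as.character(h$label),
                          character(1)),
                   labels)
  membership <- list()
  for (i in seq_along(hubsets)) {
    for (s in hubsets[[i]]$hubs$symbol) {
      membership[[s]] <- c(membership[[s]], labels[i])
    }
  }
  if (!length(membership)) {
    return(data.frame(symbol = character(0), n_networks = integer(0),
                      networks = character(0)))
  }
  df <- data.frame(
    symbol = names(membership),
    n_networks = lengths(membership),
    networks = vapply(membership, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$n_networks, df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a hub report
#'
#' One row per hub: network label, symbol, degree, and signaling layer
#' when annotations are supplied.
#'
#' @param hubsets List of `hub_set` objects.
#' @param path Output TSV path.
#' @param layers Optional layer-annotation data frame.
#' @return The path, invisibly.
#' @export
write_hub_table <- function(hubsets, path, layers = NULL) {
  layer_of <- if (!is.null(layers)) stats::setNames(layers$layer,
                                                    layers$symbol) else c()
  rows <- lapply(hubsets, function(h) {
    if (!nrow(h$hubs)) return(NULL)
    data.frame(
      network = as.character(h$label), symbol = h$hubs$symbol,
      degree = h$hubs$degree,
      layer = ifelse(h$hubs$symbol %in% names(layer_of),
                     layer_of[h$hubs$symbol], "NA"),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(network = character(0),
                                    symbol = character(0),
                                    degree = integer(0),
                                    layer = character(0))
  write_tsv(df, path)
}
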