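#' Compute the topological parameter suite of a network
#'
#' All quantities are computed on the undirected simple-graph view
#' (self-loops and parallel/antiparallel edges excluded). Path statistics
#' are taken over connected node pairs only, so disconnected networks get
#' finite values; the radius is the minimum eccentricity within the largest
#' connected component. The clustering coefficient is the unweighted mean
#' of local clustering coefficients, with nodes of degree below 2
#' contributing 0.
#'
#' @param net A `species_network` or an undirected igraph.
#' @return A `topology_report` list: `n_nodes`, `n_edges` (undirected
#'   pairs), `avg_neighbors`, `diameter`, `radius`,
#'   `characteristic_path_length`, `clustering_coefficient`, `density`,
#'   `n_connected_components`, `degree_distribution` (named integer vector,
#'   degree -> node count).
#' @export
compute_topology <- function(net) {
  g <- as_undirected_view(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network")
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)

  d <- igraph::distances(g)
  ut <- d[upper.tri(d)]
  connected_pairs <- ut[is.finite(ut)]
  diameter <- if (length(connected_pairs)) max(connected_pairs) else 0
  cpl <- if (length(connected_pairs)) mean(connected_pairs) else 0

  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  radius <- if (length(members) > 1) {
    ecc <- apply(d[members, members, drop = FALSE], 1, max)
    min(ecc)
  } else 0

  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[is.nan(local_cc)] <- 0 # degree-1 nodes
  cc <- if (n) mean(local_cc) else 0

  dd <- table(deg)
  structure(
    list(
      label = if (inherits(net, "species_network")) net$label else NA,
      n_nodes = n,
      n_edges = m,
      avg_neighbors = if (n) 2 * m / n else 0,
      diameter = diameter,
      radius = radius,
      characteristic_path_length = cpl,
      clustering_coefficient = cc,
      density = if (n > 1) m / choose(n, 2) else 0,
      n_connected_components = comp$no,
      degree_distribution = stats::setNames(as.integer(dd), names(dd))
    ),
    class = "topology_report"
  )
}

as_undirected_view <- function(net) {
  if (inherits(net, "species_network")) net$graph
  else if (inherits(net, "igraph")) {
    igraph::simplify(igraph::as_undirected(net, mode = "collapse"))
  } else stop("expected a species_network or igraph object")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Topology report", if (!is.na(x$label)) paste0("(", x$label, ")"), "\n")
  for (f in c("n_nodes", "n_edges", "avg_neighbors", "diameter", "radius",
              "characteristic_path_length", "clustering_coefficient",
              "density", "n_connected_components")) {
    cat(sprintf("  %-27s %s\n", f, format(x[[f]], digits = 4)))
  }
  invisible(x)
}

#' Write a one-row-per-network topology table
#'
#' @param reports A list of `topology_report` objects.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_topology_table <- function(reports, path) {
  fields <- c("n_nodes", "n_edges", "avg_neighbors", "diameter", "radius",
              "characteristic_path_length", "clustering_coefficient",
              "density", "n_connected_components")
  df <- data.frame(network = vapply(reports, function(r)
    as.character(r$label %||% ""), character(1)))
  for (f in fields) df[[f]] <- vapply(reports, function(r) r[[f]], numeric(1))
  write_tsv(df, path)
}

#' Rank nodes by degree
#'
#' Degrees are counted on the undirected simple view; ties are broken
#' lexicographically by symbol.
#'
#' @param net A `species_network` or undirected igraph.
#' @return Data frame `symbol`, `degree`, sorted by degree descending.
#' @export
degree_table <- function(net) {
  g <- as_undirected_view(net)
  deg <- igraph::degree(g)
  df <- data.frame(symbol = names(deg), degree = as.integer(deg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assess scale-free structure of a degree distribution
#'
#' Ordinary least squares on (log10 k, log10 P(k)) over the observed
#' degrees k >= 1, following the Barabasi-Albert expectation that the
#' degree distribution of a scale-free network is approximately a power
#' law P(k) ~ k^-gamma. The network is flagged scale-free when the fit's
#' R-squared reaches `r2_threshold` and gamma falls inside `gamma_band`.
#' The fit is declined (flag `FALSE`, reason recorded) with fewer than
#' three distinct degrees.
#'
#' @param degree_distribution Named vector (degree -> node count), e.g.
#'   the `degree_distribution` field of [compute_topology()].
#' @param r2_threshold Minimum R-squared (default 0.8).
#' @param gamma_band Admissible gamma range (default `c(1, 4)`).
#' @return A `power_law_fit` list: `gamma`, `r_squared`,
#'   `n_distinct_degrees`, `scale_free`, `reason`.
#' @export
fit_power_law <- function(degree_distribution, r2_threshold = 0.8,
                          gamma_band = c(1, 4)) {
  k <- as.numeric(names(degree_distribution))
  cnt <- as.numeric(degree_distribution)
  keep <- k >= 1 & cnt > 0
  k <- k[keep]; cnt <- cnt[keep]
  out <- list(gamma = NA_real_, r_squared = NA_real_,
              n_distinct_degrees = length(k), scale_free = FALSE,
              reason = NULL)
  if (length(k) < 3) {
    out$reason <- "fewer than 3 distinct degrees; fit declined"
    class(out) <- "power_law_fit"
    return(out)
  }
  p <- cnt / sum(cnt)
  fit <- stats::lm(log10(p) ~ log10(k))
  out$gamma <- abs(unname(stats::coef(fit)[2]))
  # summary.lm warns on numerically perfect fits; the R^2 is still exact
  out$r_squared <- suppressWarnings(summary(fit)$r.squared)
  out$scale_free <- out$r_squared >= r2_threshold &&
    out$gamma >= gamma_band[1] && out$gamma <= gamma_band[2]
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("Power-law fit declined:", x$reason, "\n")
  } else {
    cat(sprintf(
      "Power-law fit: gamma = %.3f, R^2 = %.3f over %d distinct degrees (%s)\n",
      x$gamma, x$r_squared, x$n_distinct_degrees,
      if (x$scale_free) "scale-free" else "not flagged scale-free"
    ))
  }
  invisible(x)
}
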