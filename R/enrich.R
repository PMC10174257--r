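#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of drawing at least `k` annotated molecules when `n` are
#' sampled without replacement from a universe of `N` molecules of which
#' `K` carry the annotation: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap.
#' @param n Query-set size.
#' @param K Term (annotation) size.
#' @param N Universe size.
#' @return The p-value in (0, 1].
#' @export
hypergeometric_test <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 0 ||
      k > min(n, K) || n > N || K > N) {
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K) and n, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build an annotation collection
#'
#' @param terms A list keyed by term id, each element a list with `name`,
#'   `category`, `macro_category`, `members` (character vector of symbols);
#'   or a data frame with those columns plus `term_id` (members
#'   pipe-separated).
#' @param universe Background symbol set; defaults to the union of all
#'   term members.
#' @return An `annotation_collection` list (`terms`, `universe`).
#' @export
annotation_collection <- function(terms, universe = NULL) {
  if (is.data.frame(terms)) {
    lst <- lapply(seq_len(nrow(terms)), function(i) {
      list(
        name = terms$name[i],
        category = terms$category[i] %||% "pathway",
        macro_category = terms$macro_category[i],
        members = normalize_symbol(strsplit(terms$members[i], "|",
                                            fixed = TRUE)[[1]])
      )
    })
    names(lst) <- terms$term_id
    terms <- lst
  }
  for (id in names(terms)) {
    terms[[id]]$members <- unique(normalize_symbol(terms[[id]]$members))
    if (!length(terms[[id]]$members)) stop("term with empty member set: ", id)
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(terms, `[[`, "members"))))
  } else {
    universe <- sort(unique(normalize_symbol(universe)))
    stray <- setdiff(unlist(lapply(terms, `[[`, "members")), universe)
    if (length(stray)) stop("term members outside the universe: ",
                            paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(terms = terms, universe = universe),
            class = "annotation_collection")
}

#' Read an annotation collection from TSV or GMT
#'
#' TSV layout: columns `term_id`, `name`, `category`, `macro_category`,
#' `members` (pipe-separated symbols). GMT layout (detected when the file
#' has no `term_id` header): one term per line, tab-separated
#' `term<TAB>description<TAB>member...`; category and macro-category then
#' default to `"pathway"` and `"unclassified"`.
#'
#' @param path File path.
#' @return An `annotation_collection`.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  header <- strsplit(first, "\t")[[1]]
  if ("term_id" %in% tolower(trimws(header))) {
    df <- read_delim_auto(path, "\t")
    names(df) <- tolower(names(df))
    return(annotation_collection(df))
  }
  lines <- readLines(path)
  terms <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 3) next
    terms[[parts[1]]] <- list(name = parts[2], category = "pathway",
                              macro_category = "unclassified",
                              members = parts[-(1:2)])
  }
  annotation_collection(terms)
}

#' Term over-representation analysis of a query set
#'
#' One upper-tail hypergeometric test per annotation term whose overlap
#' with the query reaches `min_overlap`, followed by Benjamini-Hochberg
#' FDR adjustment across all tested terms. Query symbols absent from the
#' universe are dropped with a message. Background universe defaults to the
#' annotation universe (over-representation convention), not the network.
#'
#' @param query Character vector of molecule symbols.
#' @param annotations An `annotation_collection`.
#' @param alpha FDR significance level (default 0.05).
#' @param min_overlap Minimum query/term overlap for a term to be tested
#'   (default 2, so single-molecule overlaps cannot drive significance).
#' @param universe Optional custom background symbol set.
#' @return Data frame, one row per tested term, sorted by `q_value` then
#'   `term_id`: `term_id`, `name`, `macro_category`, `overlap` (k),
#'   `query_size` (n), `term_size` (K), `universe_size` (N), `p_value`,
#'   `q_value`, `significant`.
#' @export
enrich_terms <- function(query, annotations, alpha = 0.05, min_overlap = 2,
                         universe = NULL) {
  stopifnot(inherits(annotations, "annotation_collection"))
  universe <- if (is.null(universe)) annotations$universe else
    sort(unique(normalize_symbol(universe)))
  query <- unique(normalize_symbol(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(length(dropped), " query symbol(s) outside the universe dropped")
  }
  query <- intersect(query, universe)
  empty <- data.frame(
    term_id = character(0), name = character(0),
    macro_category = character(0), overlap = integer(0),
    query_size = integer(0), term_size = integer(0),
    universe_size = integer(0), p_value = numeric(0), q_value = numeric(0),
    significant = logical(0)
  )
  if (!length(query)) {
    warning("empty effective query; no terms tested")
    return(empty)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotations$terms), function(id) {
    t <- annotations$terms[[id]]
    members <- intersect(t$members, universe)
    k <- length(intersect(query, members))
    if (k < min_overlap) return(NULL)
    data.frame(
      term_id = id, name = t$name, macro_category = t$macro_category,
      overlap = k, query_size = n, term_size = length(members),
      universe_size = N,
      p_value = hypergeometric_test(k, n, length(members), N),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < alpha
  res <- res[order(res$q_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a scored interaction source
#'
#' Three-column table (`node A`, `node B`, combined score). Scores may be
#' on [0, 1] or [0, 1000]; when any score exceeds 1 the whole column is
#' divided by 1000. Self-pairs are rejected; duplicate unordered pairs
#' keep the maximum score.
#'
#' @param path Path to the 3-column TSV (header optional).
#' @return A `scored_source` data frame with columns `a`, `b`, `score`.
#' @export
read_scored_source <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t")[[1]][3])
  ))
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("a", "b", "score")
  scored_source(df)
}

#' Construct a scored interaction source
#'
#' @param df Data frame with columns `a`, `b`, `score`.
#' @return A validated `scored_source` data frame.
#' @export
scored_source <- function(df) {
  df <- as.data.frame(df)[, c("a", "b", "score")]
  df$a <- normalize_symbol(df$a)
  df$b <- normalize_symbol(df$b)
  df$score <- as.numeric(df$score)
  if (any(df$score > 1)) df$score <- df$score / 1000
  if (any(df$score < 0 | df$score > 1)) stop("scores must lie in [0, 1]")
  if (any(df$a == df$b)) stop("self-pairs are not allowed in a scored source")
  lo <- pmin(df$a, df$b); hi <- pmax(df$a, df$b)
  df$a <- lo; df$b <- hi
  df <- df[order(df$a, df$b, -df$score), , drop = FALSE]
  df <- df[!duplicated(paste(df$a, df$b)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scored_source", "data.frame")
  df
}

#' Iteratively expand a network from a scored interaction source
#'
#' Emulates cycle-wise interactor addition: at each cycle the candidate
#' molecules are the non-members linked to the current node set by source
#' pairs with combined score at or above `cutoff`; candidates are ranked
#' by (number of links into the current set, sum of those scores, symbol)
#' and the top `per_cycle` are admitted together with all their qualifying
#' edges. The cycle at which each new node entered is recorded. Expansion
#' stops early when a cycle yields no candidate.
#'
#' @param base Literature `species_network` to expand.
#' @param source A `scored_source` (see [read_scored_source()]).
#' @param cutoff Minimum combined score (default 0.400, medium
#'   confidence).
#' @param cycles Number of expansion cycles (default 3).
#' @param per_cycle Interactors admitted per cycle (default 10).
#' @return An `enriched_network` (see [merge_enriched()]).
#' @export
expand_network <- function(base, source, cutoff = 0.400, cycles = 3,
                           per_cycle = 10) {
  stopifnot(per_cycle >= 1, cycles >= 0)
  source <- scored_source(source)
  qualifying <- source[source$score >= cutoff, , drop = FALSE]
  current <- base$nodes
  added_edges <- list()
  if (cycles >= 1) for (cyc in seq_len(cycles)) {
    touches <- xor(qualifying$a %in% current, qualifying$b %in% current)
    frontier <- qualifying[touches, , drop = FALSE]
    if (!nrow(frontier)) {
      message("no expansion candidates at cycle ", cyc, "; stopping early")
      break
    }
    cand_sym <- ifelse(frontier$a %in% current, frontier$b, frontier$a)
    links <- tapply(rep(1L, nrow(frontier)), cand_sym, sum)
    score_sum <- tapply(frontier$score, cand_sym, sum)
    cand <- data.frame(symbol = names(links),
                       links = as.integer(links),
                       score_sum = as.numeric(score_sum[names(links)]),
                       stringsAsFactors = FALSE)
    cand <- cand[order(-cand$links, -cand$score_sum, cand$symbol), ,
                 drop = FALSE]
    take <- utils::head(cand$symbol, per_cycle)
    for (s in take) {
      inc <- qualifying[(qualifying$a == s & qualifying$b %in% current) |
                        (qualifying$b == s & qualifying$a %in% current), ,
                        drop = FALSE]
      if (nrow(inc)) {
        inc$cycle <- cyc
        added_edges[[length(added_edges) + 1L]] <- inc
      }
      current <- c(current, s)
    }
  }
  predicted <- if (length(added_edges)) do.call(rbind, added_edges) else
    data.frame(a = character(0), b = character(0), score = numeric(0),
               cycle = integer(0))
  merge_enriched(base, predicted, cutoff = cutoff)
}

#' Count significant terms per macro-category
#'
#' Rolls significant enrichment results up to BRITE-style macro-categories:
#' distinct significant terms per macro-category, plus the unique-path
#' total. With a list of result tables (one per network) a per-network
#' count matrix and pooled counts over the union of significant terms are
#' returned. Terms lacking a macro-category are counted under
#' `"unclassified"`.
#'
#' @param results A single [enrich_terms()] result or a named list of
#'   them.
#' @param annotations The `annotation_collection` the results came from.
#' @return A `macro_category_counts` list: `per_network` (matrix
#'   macro-category x network), `pooled` (named vector over the union of
#'   significant terms), `unique_totals` (per network), `pooled_total`.
#' @export
macro_category_counts <- function(results, annotations) {
  if (is.data.frame(results)) results <- list(network = results)
  macro_of <- vapply(annotations$terms, function(t) {
    mc <- t$macro_category
    if (is.null(mc) || is.na(mc) || !nzchar(mc)) "unclassified" else mc
  }, character(1))
  cats <- sort(unique(c(MACRO_CATEGORIES, unname(macro_of))))
  per <- matrix(0L, nrow = length(cats), ncol = length(results),
                dimnames = list(cats, names(results)))
  sig_terms <- lapply(results, function(r) r$term_id[r$significant])
  for (j in seq_along(results)) {
    mc <- macro_of[sig_terms[[j]]]
    mc[is.na(mc)] <- "unclassified"
    tab <- table(mc)
    per[names(tab), j] <- as.integer(tab)
  }
  pooled_terms <- unique(unlist(sig_terms))
  pooled_mc <- macro_of[pooled_terms]
  pooled_mc[is.na(pooled_mc)] <- "unclassified"
  pooled <- stats::setNames(rep(0L, length(cats)), cats)
  if (length(pooled_mc)) {
    tab <- table(pooled_mc)
    pooled[names(tab)] <- as.integer(tab)
  }
  structure(
    list(
      per_network = per,
      pooled = pooled,
      unique_totals = vapply(sig_terms, function(x) length(unique(x)),
                             integer(1)),
      pooled_total = length(pooled_terms)
    ),
    class = "macro_category_counts"
  )
}

#' @export
print.macro_category_counts <- function(x, ...) {
  cat("Significant terms per macro-category\n")
  print(x$per_network)
  cat("Unique path totals:",
      paste(names(x$unique_totals), x$unique_totals, sep = "=",
            collapse = ", "),
      "| pooled:", x$pooled_total, "\n")
  invisible(x)
}
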