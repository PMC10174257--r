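#' Read a curated interaction collection
#'
#' Parses a tab- or comma-delimited table of literature-curated directed
#' molecular interactions. Each row is one interaction: an input molecule
#' that begins the signal, a target molecule that receives it, the link type
#' (physical for direct contact, functional for correlative up/down
#' regulation), the model-organism code, the developmental stage, and a
#' citation key. Symbols are uppercased and stripped of whitespace; the
#' embryo stage includes fetal records.
#'
#' Required columns (case-insensitive): `source`, `target`, `link_type`,
#' `species`, `stage`, `reference`. An `effect` column (`up`/`down`) is
#' optional and defaults to `"unspecified"`.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param delim Field delimiter; auto-detected from the first line when
#'   `NULL`.
#' @return A data frame of class `interaction_collection` with columns
#'   `source`, `target`, `link_type`, `effect`, `species`, `stage`,
#'   `reference`, and `row` (the originating file row, for error reports).
#' @seealso [validate_collection()], [summarize_collection()],
#'   [write_collection()]
#' @export
parse_collection <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_delim_auto(path, delim)
  names(raw) <- tolower(trimws(names(raw)))
  required <- c("source", "target", "link_type", "species", "stage", "reference")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"effect" %in% names(raw)) raw$effect <- "unspecified"
  raw$effect[!nzchar(trimws(raw$effect))] <- "unspecified"

  rec <- data.frame(
    source = normalize_symbol(raw$source),
    target = normalize_symbol(raw$target),
    link_type = tolower(trimws(raw$link_type)),
    effect = tolower(trimws(raw$effect)),
    species = trimws(raw$species),
    stage = tolower(trimws(raw$stage)),
    reference = trimws(raw$reference),
    row = seq_len(nrow(raw)) + 1L, # +1 for the header line
    stringsAsFactors = FALSE
  )
  as_interaction_collection(rec)
}

#' Construct an interaction collection from a data frame
#'
#' Validates field values row by row (enum membership, non-empty symbols)
#' and stamps the `interaction_collection` class. Used by [parse_collection()]
#' and by the synthetic generators.
#'
#' @param df Data frame with columns `source`, `target`, `link_type`,
#'   `species`, `stage`, `reference`; optional `effect` and `row`.
#' @return An `interaction_collection` data frame.
#' @export
as_interaction_collection <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"effect" %in% names(df)) df$effect <- rep("unspecified", nrow(df))
  if (!"row" %in% names(df)) df$row <- seq_len(nrow(df))
  df$source <- normalize_symbol(df$source)
  df$target <- normalize_symbol(df$target)

  err <- character(0)
  bad_row <- function(i, what, tok) {
    sprintf("row %d: %s '%s'", df$row[i], what, tok)
  }
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$source[i]) || !nzchar(df$target[i])) {
      err <- c(err, sprintf("row %d: empty symbol", df$row[i]))
    }
    if (!df$species[i] %in% SPECIES_CODES) {
      err <- c(err, bad_row(i, "unknown species token", df$species[i]))
    }
    if (!df$stage[i] %in% STAGE_LEVELS) {
      err <- c(err, bad_row(i, "unknown stage token", df$stage[i]))
    }
    if (!df$link_type[i] %in% LINK_TYPES) {
      err <- c(err, bad_row(i, "unknown link_type token", df$link_type[i]))
    }
    if (!df$effect[i] %in% EFFECT_LEVELS) {
      err <- c(err, bad_row(i, "unknown effect token", df$effect[i]))
    }
  }
  if (length(err)) stop("invalid interaction record(s):\n  ",
                        paste(err, collapse = "\n  "))
  df <- df[, c("source", "target", "link_type", "effect", "species",
               "stage", "reference", "row")]
  rownames(df) <- NULL
  class(df) <- c("interaction_collection", "data.frame")
  df
}

#' Write an interaction collection to canonical TSV
#'
#' Tab-delimited, LF line endings, UTF-8, header always emitted. A file
#' written here and re-read with [parse_collection()] reproduces the record
#' list field by field.
#'
#' @param records An `interaction_collection`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_collection <- function(records, path) {
  cols <- c("source", "target", "link_type", "effect", "species", "stage",
            "reference")
  write_tsv(as.data.frame(records)[, cols], path)
}

#' Read layer annotations
#'
#' A two-column TSV mapping molecule symbols to signaling layers
#' (`upstream`, `TF`, `downstream`), with an optional `origin` column
#' (`literature` or `enriched`).
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns `symbol`, `layer`, `origin`.
#' @export
parse_layer_annotations <- function(path) {
  raw <- read_delim_auto(path, "\t")
  names(raw) <- tolower(trimws(names(raw)))
  if (!all(c("symbol", "layer") %in% names(raw))) {
    stop("layer annotation file must have columns 'symbol' and 'layer'")
  }
  out <- data.frame(
    symbol = normalize_symbol(raw$symbol),
    layer = ifelse(tolower(trimws(raw$layer)) == "tf", "TF",
                   tolower(trimws(raw$layer))),
    origin = if ("origin" %in% names(raw)) tolower(trimws(raw$origin))
             else "literature",
    stringsAsFactors = FALSE
  )
  bad <- !out$layer %in% LAYER_LEVELS
  if (any(bad)) {
    stop("unknown layer token(s): ", paste(unique(out$layer[bad]),
                                           collapse = ", "))
  }
  dup <- out$symbol[duplicated(out$symbol)]
  if (length(dup)) {
    conflict <- vapply(unique(dup), function(s) {
      length(unique(out$layer[out$symbol == s])) > 1
    }, logical(1))
    if (any(conflict)) {
      stop("symbol(s) mapped to multiple layers: ",
           paste(unique(dup)[conflict], collapse = ", "))
    }
    out <- out[!duplicated(out$symbol), ]
  }
  rownames(out) <- NULL
  out
}

#' Validate an interaction collection
#'
#' Report-only checks: exact duplicate records, self-interactions
#' (source equals target), and symbols mapped to more than one signaling
#' layer when layer annotations are supplied. Records are never mutated.
#'
#' @param records An `interaction_collection` (or compatible data frame).
#' @param layers Optional layer-annotation data frame
#'   (see [parse_layer_annotations()]).
#' @return A `validation_report` list with elements `n_records`,
#'   `duplicate_groups` (list of row-index vectors), `n_duplicate_groups`,
#'   `self_interactions` (row indices), `n_self_interactions`,
#'   `multi_layer_symbols`.
#' @export
validate_collection <- function(records, layers = NULL) {
  records <- as.data.frame(records)
  key_cols <- c("source", "target", "link_type", "effect", "species",
                "stage", "reference")
  if (nrow(records)) {
    key <- do.call(paste, c(records[key_cols], sep = "\r"))
    groups <- split(seq_len(nrow(records)), key)
    dup_groups <- unname(groups[lengths(groups) > 1])
    self <- which(records$source == records$target)
  } else {
    dup_groups <- list()
    self <- integer(0)
  }
  multi <- character(0)
  if (!is.null(layers)) {
    per_sym <- tapply(layers$layer, layers$symbol,
                      function(x) length(unique(x)))
    multi <- names(per_sym)[per_sym > 1]
  }
  structure(
    list(
      n_records = nrow(records),
      duplicate_groups = dup_groups,
      n_duplicate_groups = length(dup_groups),
      self_interactions = self,
      n_self_interactions = length(self),
      multi_layer_symbols = multi
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Interaction collection validation\n")
  cat("  records:            ", x$n_records, "\n")
  cat("  duplicate groups:   ", x$n_duplicate_groups, "\n")
  cat("  self-interactions:  ", x$n_self_interactions, "\n")
  cat("  multi-layer symbols:", length(x$multi_layer_symbols), "\n")
  invisible(x)
}

#' Summarize a collection by species and developmental stage
#'
#' Cross-tabulates interaction counts per (species, stage) cell, per-species
#' totals, grand totals, and each species' percentage share of the grand
#' total. Shares are formatted to the nearest integer at or above 2% and to
#' one decimal below 2%.
#'
#' @param records An `interaction_collection` (or compatible data frame).
#' @return A `collection_summary` list with elements `counts` (species x
#'   stage integer matrix over all seven species codes), `species_totals`,
#'   `grand_total`, `stage_totals`, `species_share_pct` (numeric),
#'   `species_share_display` (formatted), `stage_share_pct`,
#'   `stage_share_display`.
#' @export
summarize_collection <- function(records) {
  records <- as.data.frame(records)
  counts <- matrix(0L, nrow = length(SPECIES_CODES),
                   ncol = length(STAGE_LEVELS),
                   dimnames = list(SPECIES_CODES, STAGE_LEVELS))
  if (nrow(records)) {
    tab <- table(factor(records$species, levels = SPECIES_CODES),
                 factor(records$stage, levels = STAGE_LEVELS))
    counts[] <- as.integer(tab)
  }
  species_totals <- rowSums(counts)
  stage_totals <- colSums(counts)
  grand <- sum(counts)
  share <- if (grand > 0) 100 * species_totals / grand else
    stats::setNames(rep(0, length(SPECIES_CODES)), SPECIES_CODES)
  stage_share <- if (grand > 0) 100 * stage_totals / grand else
    stats::setNames(rep(0, length(STAGE_LEVELS)), STAGE_LEVELS)
  structure(
    list(
      counts = counts,
      species_totals = species_totals,
      stage_totals = stage_totals,
      grand_total = grand,
      species_share_pct = share,
      species_share_display = stats::setNames(format_share(share),
                                              names(share)),
      stage_share_pct = stage_share,
      stage_share_display = stats::setNames(format_share(stage_share),
                                            names(stage_share))
    ),
    class = "collection_summary"
  )
}

#' @export
print.collection_summary <- function(x, ...) {
  df <- data.frame(
    species = rownames(x$counts),
    total = x$species_totals,
    embryo = x$counts[, "embryo"],
    prepubertal = x$counts[, "prepubertal"],
    share = paste0(x$species_share_display, "%")
  )
  cat("Interaction collection composition\n")
  print(df, row.names = FALSE)
  cat(sprintf(
    "Totals: %d interactions (%d embryo / %d prepubertal)\n",
    x$grand_total, x$stage_totals["embryo"], x$stage_totals["prepubertal"]
  ))
  invisible(x)
}
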