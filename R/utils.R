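# Internal helpers shared across modules.

SPECIES_CODES <- c("m", "r", "h", "e", "b", "g", "d")
STAGE_LEVELS <- c("embryo", "prepubertal")
LINK_TYPES <- c("physical", "functional")
EFFECT_LEVELS <- c("up", "down", "unspecified")
LAYER_LEVELS <- c("upstream", "TF", "downstream")
MACRO_CATEGORIES <- c(
  "growth/differentiation/survival",
  "morphogenesis/cell motility",
  "nervous system",
  "endocrine system"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Nearest integer with exact halves rounded down (72.5 -> 72).
#' @keywords internal
round_half_down <- function(x) ceiling(x - 0.5)

# Percentage formatting used in composition summaries: integer at or above
# 2%, one decimal below 2%.
format_share <- function(pct) {
  ifelse(pct >= 2,
    formatC(round_half_up(pct), format = "d"),
    formatC(round_half_up(pct, 1), format = "f", digits = 1)
  )
}

# Deterministic 31-bit seed derived from a base seed and a stream label, so
# each sub-generator owns an independent stream and adding one generator does
# not shift another's output.
fork_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # keep every intermediate below 2^53 so the arithmetic stays exact
  h <- abs(seed) %% 2147483647
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Canonical TSV writer: tab-delimited, LF line endings, UTF-8, header always
# emitted, no quoting (symbols never contain tabs after normalization).
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(lapply(df, as.character), sep = "\t"))
  )
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_delim_auto <- function(path, delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path,
    header = TRUE, sep = delim, quote = "\"",
    stringsAsFactors = FALSE, comment.char = "", check.names = FALSE,
    colClasses = "character"
  )
}

# Uppercase, trim, and drop internal whitespace; identical symbols are the
# same molecule across species (no orthology mapping is attempted).
normalize_symbol <- function(x) {
  gsub("[[:space:]]+", "", toupper(trimws(x)))
}
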