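test_that("parsing a small file yields normalized records and round-trips", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "source\ttarget\tlink_type\tspecies\tstage\treference",
    "scx \tCol1a1\tphysical\tm\tembryo\tref1",
    "Tgfb1\tSMAD 3\tfunctional\tm\tprepubertal\tref2",
    "BMP4\tSIX2\tphysical\tg\tembryo\tref3"
  ), tf)
  rec <- parse_collection(tf)
  expect_s3_class(rec, "interaction_collection")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$source, c("SCX", "TGFB1", "BMP4"))
  expect_equal(rec$target, c("COL1A1", "SMAD3", "SIX2")) # whitespace collapsed
  expect_equal(rec$species, c("m", "m", "g"))
  expect_equal(rec$stage, c("embryo", "prepubertal", "embryo"))
  expect_equal(rec$effect, rep("unspecified", 3)) # column absent

  out <- withr::local_tempfile(fileext = ".tsv")
  write_collection(rec, out)
  rec2 <- parse_collection(out)
  for (col in c("source", "target", "link_type", "effect", "species",
                "stage", "reference")) {
    expect_identical(rec2[[col]], rec[[col]])
  }
})

test_that("schema and token violations are reported with context", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,species,stage,reference",
               "A,B,m,embryo,r1"), tf)
  expect_error(parse_collection(tf), "link_type")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "source\ttarget\tlink_type\tspecies\tstage\treference",
    "A\tB\tphysical\tx\tembryo\tr1"
  ), tf2)
  expect_error(parse_collection(tf2), "row 2.*'x'")

  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "source\ttarget\tlink_type\tspecies\tstage\treference",
    "A\tB\tphysical\tm\tembryo\tr1",
    "A\t \tphysical\tm\tembryo\tr2"
  ), tf3)
  expect_error(parse_collection(tf3), "row 3.*empty symbol")
})

test_that("validation flags duplicates and self-interactions by brute force", {
  expect_equal(validate_collection(records_df(character(0),
                                              character(0)))$n_records, 0)

  rec <- records_df(c("A", "B", "C", "A", "D"),
                    c("B", "C", "D", "B", "D"))
  rec$reference <- c("r1", "r2", "r3", "r1", "r5") # rows 1 and 4 identical
  rep_ <- validate_collection(rec)
  # oracle: brute-force pairwise field equality
  dup_pairs <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    if (all(vapply(c("source", "target", "link_type", "effect", "species",
                     "stage", "reference"),
                   function(f) rec[[f]][i] == rec[[f]][j], logical(1)))) {
      dup_pairs <- dup_pairs + 1
    }
  }
  expect_equal(dup_pairs, 1)
  expect_equal(rep_$n_duplicate_groups, 1)
  expect_equal(sort(rep_$duplicate_groups[[1]]), c(1L, 4L))
  expect_equal(rep_$self_interactions, 5L)

  layers <- data.frame(symbol = c("A", "A", "B"),
                       layer = c("upstream", "TF", "downstream"))
  expect_equal(validate_collection(rec, layers)$multi_layer_symbols, "A")
})

test_that("composition summary reproduces the curated-collection totals and shares", {
  counts <- default_interaction_counts()
  src_i <- 0
  rows <- list()
  for (sp in rownames(counts)) for (st in colnames(counts)) {
    n <- counts[sp, st]
    if (n == 0) next
    rows[[paste(sp, st)]] <- data.frame(
      source = sprintf("S%03d", src_i + seq_len(n)),
      target = sprintf("T%03d", src_i + seq_len(n)),
      link_type = "physical", species = sp, stage = st,
      reference = "r", stringsAsFactors = FALSE
    )
    src_i <- src_i + n
  }
  rec <- as_interaction_collection(do.call(rbind, rows))
  s <- summarize_collection(rec)
  expect_equal(s$grand_total, 286)
  expect_equal(unname(s$stage_totals), c(155, 131))
  expect_equal(unname(s$species_totals),
               c(145, 28, 9, 28, 2, 70, 4), ignore_attr = TRUE)
  expect_equal(unname(s$species_share_display[c("m", "h", "d", "b")]),
               c("51", "3", "1.4", "0.7"))
  expect_equal(unname(s$stage_share_display["embryo"]), "54")
  # permutation invariance
  s2 <- summarize_collection(rec[sample(nrow(rec)), ])
  expect_equal(s2$counts, s$counts)
})

test_that("single-record summary gives one 100% share", {
  s <- summarize_collection(records_df("A", "B", species = "h"))
  expect_equal(s$grand_total, 1)
  expect_equal(unname(s$species_share_pct["h"]), 100)
  expect_equal(unname(s$species_share_display["h"]), "100")
})

test_that("layer annotation reader enforces the one-layer-per-symbol rule", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tlayer\torigin",
               "SCX\ttf\tliterature",
               "TGFB1\tupstream\tenriched"), tf)
  lay <- parse_layer_annotations(tf)
  expect_equal(lay$layer, c("TF", "upstream"))
  expect_equal(lay$origin, c("literature", "enriched"))

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tlayer", "SCX\tTF", "SCX\tupstream"), tf2)
  expect_error(parse_layer_annotations(tf2), "multiple layers")
})
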