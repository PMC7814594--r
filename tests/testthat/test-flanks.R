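test_that("flank coordinates are transcription-relative and hand-check on single genes", {
  idx <- index_from_lengths(c(scf1 = 2000L))
  plus <- make_genes(500, 900, "+")
  f <- extract_flank_coordinates(plus, idx)
  up <- f[f$side == "upstream", ]
  dn <- f[f$side == "downstream", ]
  expect_equal(c(up$start, up$end, up$raw_length), c(1L, 499L, 499L))
  expect_equal(c(dn$start, dn$end, dn$raw_length), c(901L, 2000L, 1100L))

  minus <- make_genes(500, 900, "-")
  fm <- extract_flank_coordinates(minus, idx)
  upm <- fm[fm$side == "upstream", ]
  dnm <- fm[fm$side == "downstream", ]
  expect_equal(c(upm$start, upm$end), c(901L, 2000L))  # upstream at higher coords
  expect_equal(c(dnm$start, dnm$end), c(1L, 499L))
})

test_that("the span between adjacent genes becomes the second gene's upstream flank", {
  idx <- index_from_lengths(c(scf1 = 1000L))
  g <- make_genes(c(100, 205), c(200, 300), "+")
  f <- extract_flank_coordinates(g, idx)
  up2 <- f[f$gene_id == "g2" & f$side == "upstream", ]
  expect_equal(c(up2$start, up2$end, up2$raw_length), c(201L, 204L, 4L))
  # the same span is g1's downstream flank
  dn1 <- f[f$gene_id == "g1" & f$side == "downstream", ]
  expect_equal(c(dn1$start, dn1$end), c(201L, 204L))
})

test_that("trimming keeps the gene-proximal 700 bp and tags statuses at the boundaries", {
  idx <- index_from_lengths(c(scf1 = 2000L))
  g <- make_genes(901, 1500, "+")
  f <- trim_flanks(extract_flank_coordinates(g, idx))
  up <- f[f$side == "upstream", ]
  expect_equal(up$status, "trimmed")
  expect_equal(c(up$start, up$end), c(201L, 900L))  # 700 bp adjacent to the 5' end
  expect_equal(up$end - up$start + 1L, 700L)

  # minus-strand mirror: proximal end is the region start
  gm <- make_genes(200, 800, "-")
  fm <- trim_flanks(extract_flank_coordinates(gm, idx))
  upm <- fm[fm$side == "upstream", ]
  expect_equal(upm$status, "trimmed")
  expect_equal(c(upm$start, upm$end), c(801L, 1500L))

  # boundary raw lengths: 14 -> short, 15 -> ok, 700 -> ok, 701 -> trimmed
  mk <- function(gap) {
    gg <- make_genes(c(100, 200 + gap + 1), c(200, 400 + gap), "+",
                     gene_id = c("a", "b"))
    ff <- trim_flanks(extract_flank_coordinates(
      gg, index_from_lengths(c(scf1 = 5000L))))
    ff[ff$gene_id == "b" & ff$side == "upstream", ]
  }
  expect_equal(mk(14L)$status, "short_ups")
  expect_equal(mk(15L)$status, "ok")
  expect_equal(mk(700L)$status, "ok")
  r701 <- mk(701L)
  expect_equal(r701$status, "trimmed")
  expect_equal(r701$end - r701$start + 1L, 700L)
})

test_that("overlapping or abutting neighbors yield zero-length short-tagged flanks", {
  idx <- index_from_lengths(c(scf1 = 5000L))
  g <- make_genes(c(100, 250), c(300, 600), "+")  # g2 overlaps g1
  f <- trim_flanks(extract_flank_coordinates(g, idx))
  up2 <- f[f$gene_id == "g2" & f$side == "upstream", ]
  expect_equal(up2$raw_length, 0L)
  expect_equal(up2$status, "short_ups")
  dn1 <- f[f$gene_id == "g1" & f$side == "downstream", ]
  expect_equal(dn1$raw_length, 0L)
  expect_equal(dn1$status, "short_dss")
})

test_that("flank sequences are sliced and reverse-complemented per strand", {
  seq <- paste(rep("ACGTACGTACGT", 10), collapse = "")  # 120 bp
  idx <- index_from_seqs(list(scf1 = seq))
  g <- make_genes(31, 60, "+")
  f <- extract_flank_sequences(trim_flanks(extract_flank_coordinates(g, idx)), idx)
  up <- f[f$side == "upstream", ]
  expect_equal(up$sequence, substr(seq, 1, 30))

  gm <- make_genes(31, 60, "-")
  fm <- extract_flank_sequences(trim_flanks(extract_flank_coordinates(gm, idx)), idx)
  dnm <- fm[fm$side == "downstream", ]  # genomic [1,30], minus strand
  expect_equal(dnm$sequence, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seq, 1, 30)))))

  # short-tagged regions carry an empty sequence
  g2 <- make_genes(c(1, 5), c(4, 40), "+", gene_id = c("a", "b"))
  f2 <- extract_flank_sequences(trim_flanks(extract_flank_coordinates(g2, idx)), idx)
  expect_equal(f2$sequence[f2$gene_id == "b" & f2$side == "upstream"], "")

  expect_error(
    extract_flank_sequences(f, index_from_lengths(c(scf1 = 120L))),
    "without sequences")
})

test_that("genes extending beyond their scaftig are skipped with a report", {
  idx <- index_from_lengths(c(scf1 = 1000L))
  g <- make_genes(c(100, 800), c(300, 1200), "+", gene_id = c("ok", "bad"))
  expect_warning(f <- extract_flank_coordinates(g, idx), "skipped")
  expect_false("bad" %in% f$gene_id)
  expect_length(attr(f, "errors"), 1L)
  expect_error(
    extract_flank_coordinates(make_genes(1, 10, "+", scaftig = "nope"), idx),
    "absent from index")
})

test_that("randomized layouts obey the flank invariants and strand-mirror symmetry", {
  set.seed(42)
  for (rep in 1:20) {
    L <- 30000L
    g <- random_gene_table(sample(3:15, 1), scaftig_len = L,
                           allow_overlap = TRUE)
    idx <- index_from_lengths(stats::setNames(L, unique(g$scaftig_id)))
    f <- trim_flanks(extract_flank_coordinates(g, idx))
    len <- f$end - f$start + 1L
    expect_true(all(len <= 700L))
    expect_identical(f$status %in% c("short_ups", "short_dss"),
                     f$raw_length < 15L)
    # no flank overlaps its own gene's coding span
    gm <- g[match(f$gene_id, g$gene_id), ]
    expect_true(all(f$end < gm$start | f$start > gm$end | len <= 0L))

    # mirror the scaftig: flip coordinates and strands
    g2 <- g
    g2$start <- L - g$end + 1L
    g2$end <- L - g$start + 1L
    g2$strand <- ifelse(g$strand == "+", "-", "+")
    g2 <- g2[order(g2$scaftig_id, g2$start, g2$end), ]
    rownames(g2) <- NULL
    f2 <- trim_flanks(extract_flank_coordinates(g2, idx))
    key <- function(x) paste(x$gene_id, x$side)
    f2 <- f2[match(key(f), key(f2)), ]
    expect_equal(f2$raw_length, f$raw_length)
    expect_equal(f2$status, f$status)
    expect_equal(f2$start, L - f$end + 1L)
    expect_equal(f2$end, L - f$start + 1L)
  }
})
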