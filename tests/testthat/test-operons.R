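# A 4-gene plus-strand proximon with small gaps, reused across cases.
four_gene_fixture <- function(strand = "+") {
  genes <- make_genes(c(1000, 1551, 2102, 2653), c(1500, 2051, 2602, 3200),
                      strand)
  list(genes = genes, proximons = call_proximons(genes))
}

test_that("the boundary walk opens at upstream hits and closes at downstream hits", {
  fx <- four_gene_fixture()
  ids <- fx$genes$gene_id

  # upstream hit at gene 1 only, no internal promoter: one operon of four
  ops <- call_operons_igd_promoter(fx$proximons, scan_stub(ids, upstream = "g1"),
                                   fx$genes)
  expect_equal(nrow(ops$operons), 1L)
  expect_equal(ops$operons$gene_ids[[1]], c("g1", "g2", "g3", "g4"))
  expect_equal(ops$operons$mode, "igd_promoter")
  expect_true(is.na(ops$operons$downstream_promoter_pos))  # proximon edge
  expect_length(ops$nonoperonic_genes, 0L)

  # upstream hits at genes 1 and 3: the gene-3 promoter both closes {1,2}
  # and opens {3,4} (single-promoter dual role)
  ops2 <- call_operons_igd_promoter(fx$proximons,
                                    scan_stub(ids, upstream = c("g1", "g3")),
                                    fx$genes)
  expect_equal(lapply(ops2$operons$gene_ids, identity),
               list(c("g1", "g2"), c("g3", "g4")))

  # no promoter anywhere: no operons, every gene reported non-operonic
  ops3 <- call_operons_igd_promoter(fx$proximons, scan_stub(ids), fx$genes)
  expect_equal(nrow(ops3$operons), 0L)
  expect_setequal(ops3$nonoperonic_genes, ids)
})

test_that("a downstream hit closes the running unit and later genes need a new opener", {
  fx <- four_gene_fixture()
  ids <- fx$genes$gene_id
  ops <- call_operons_igd_promoter(
    fx$proximons, scan_stub(ids, upstream = "g1", downstream = "g2"), fx$genes)
  expect_equal(nrow(ops$operons), 1L)
  expect_equal(ops$operons$gene_ids[[1]], c("g1", "g2"))
  expect_setequal(ops$nonoperonic_genes, c("g3", "g4"))

  # trailing single gene after a split is discarded as non-operonic
  ops2 <- call_operons_igd_promoter(
    fx$proximons, scan_stub(ids, upstream = c("g1", "g4")), fx$genes)
  expect_equal(lapply(ops2$operons$gene_ids, identity),
               list(c("g1", "g2", "g3")))
  expect_equal(ops2$nonoperonic_genes, "g4")
})

test_that("minus-strand proximons are walked and reported in transcription order", {
  fx <- four_gene_fixture("-")
  ids <- fx$genes$gene_id  # g1..g4 left to right; transcription right to left
  ops <- call_operons_igd_promoter(fx$proximons,
                                   scan_stub(ids, upstream = c("g4", "g2")),
                                   fx$genes)
  expect_equal(lapply(ops$operons$gene_ids, identity),
               list(c("g2", "g1"), c("g4", "g3")))
  expect_equal(ops$operons$strand, c("-", "-"))
  # envelope is still genomic
  expect_equal(ops$operons$start, c(1000L, 2102L))
  expect_equal(ops$operons$end, c(2051L, 3200L))
})

test_that("promoter-only mode ignores intergenic distance; the distance mode never does", {
  # IGDs 50, 5001, 50 (a 5000 bp physical gap splits the middle pair)
  genes <- make_genes(c(1000, 1550, 7050, 7600),
                      c(1499, 2049, 7549, 8100), "+")
  scan <- scan_stub(genes$gene_id, upstream = "g1")

  po <- call_operons_promoter_only(genes, scan)
  expect_equal(po$operons$gene_ids[[1]], c("g1", "g2", "g3", "g4"))
  expect_equal(po$operons$mode, "promoter_only")

  prox <- call_proximons(genes)
  ig <- call_operons_igd_promoter(prox, scan, genes)
  expect_equal(lapply(ig$operons$gene_ids, identity), list(c("g1", "g2")))
  # no operon ever spans the wide gap in distance mode
  expect_false(any(vapply(ig$operons$gene_ids,
                          function(x) all(c("g2", "g3") %in% x), TRUE)))

  # a strand switch is a boundary in both modes
  genes2 <- make_genes(c(1000, 1550, 2100, 2650),
                       c(1499, 2049, 2599, 3100), c("+", "+", "-", "-"))
  scan2 <- scan_stub(genes2$gene_id, upstream = c("g1", "g4"))
  po2 <- call_operons_promoter_only(genes2, scan2)
  expect_equal(lapply(po2$operons$gene_ids, identity),
               list(c("g1", "g2"), c("g4", "g3")))
})

test_that("every operon is a contiguous sub-run of one proximon and genes are never reused", {
  set.seed(21)
  for (rep in 1:20) {
    g <- random_gene_table(sample(6:20, 1), scaftig_len = 40000L)
    prox <- call_proximons(g)
    if (nrow(prox) == 0L) next
    hits <- sample(g$gene_id, size = max(1, rbinom(1, nrow(g), 0.4)))
    scan <- scan_stub(g$gene_id, upstream = hits)
    ops <- call_operons_igd_promoter(prox, scan, g)
    all_op_genes <- unlist(ops$operons$gene_ids)
    expect_false(anyDuplicated(all_op_genes) > 0)
    expect_true(all(ops$operons$n_genes >= 2L))
    # first transcription-order gene always carries an upstream hit
    firsts <- vapply(ops$operons$gene_ids, `[`, "", 1L)
    expect_true(all(scan$upstream_hit[firsts]))
    for (i in seq_len(nrow(ops$operons))) {
      members <- ops$operons$gene_ids[[i]]
      inside <- vapply(prox$genes, function(p) all(members %in% p), TRUE)
      expect_equal(sum(inside), 1L)
      host <- prox$genes[[which(inside)]]
      pos <- match(members, host)
      expect_equal(sort(pos), min(pos):max(pos))  # contiguous sub-run
    }
    # igd mode never covers more genes than its proximons
    expect_lte(length(all_op_genes), sum(prox$n_genes))
  }
})

test_that("identical inputs give byte-identical written outputs", {
  fx <- four_gene_fixture()
  scan <- scan_stub(fx$genes$gene_id, upstream = c("g1", "g3"))
  ops <- call_operons_igd_promoter(fx$proximons, scan, fx$genes)
  d1 <- tempfile(); d2 <- tempfile()
  write_tables(proximons = fx$proximons, operons = ops, out_dir = d1)
  write_tables(proximons = fx$proximons, operons = ops, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
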