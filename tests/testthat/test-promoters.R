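test_that("oracle backend passes planted hits through, restricted to eligible flanks", {
  g <- make_genes(c(1000, 1500, 1516), c(1400, 1514, 1900), "+",
                  gene_id = c("gA", "gB", "gC"))
  idx <- index_from_lengths(c(scf1 = 5000L))
  fl <- trim_flanks(extract_flank_coordinates(g, idx))
  # gB and gC are squeezed: their shared flanks are short-tagged
  truth <- data.frame(gene_id = c("gA", "gC"), side = "upstream",
                      stringsAsFactors = FALSE)
  scan <- scan_flanks(fl, backend = "oracle", oracle_truth = truth)
  expect_true(scan$upstream_hit[["gA"]])
  expect_false(scan$upstream_hit[["gB"]])
  expect_false(scan$upstream_hit[["gC"]])  # short-tagged region never hits
  expect_false(any(scan$downstream_hit))
})

test_that("a promoter call is attributed by interval containment on the matching strand", {
  g <- make_genes(c(100, 1000), c(150, 1600), "+", gene_id = c("gA", "gB"))
  idx <- index_from_lengths(c(scf1 = 5000L))
  fl <- trim_flanks(extract_flank_coordinates(g, idx))
  # gB upstream flank is [300, 999] after trimming (gene-proximal 700)
  calls <- data.frame(scaftig_id = "scf1", strand = c("+", "-", "+"),
                      position = c(700L, 710L, 2000L),
                      score = c(0.9, 0.95, 0.99), source = "nnpp_file",
                      stringsAsFactors = FALSE)
  scan <- scan_flanks(fl, backend = "nnpp_file", calls = calls)
  expect_true(scan$upstream_hit[["gB"]])   # + call at 700 contained
  expect_false(scan$upstream_hit[["gA"]])
  # the same call in the shared span is also gA's downstream hit
  expect_true(scan$downstream_hit[["gA"]])
  up <- scan$hits[scan$hits$gene_id == "gB" & scan$hits$side == "upstream", ]
  expect_equal(up$position, 700L)
})

test_that("score ties between calls resolve to the gene-proximal position", {
  g <- make_genes(1000, 1600, "+", gene_id = "gB")
  idx <- index_from_lengths(c(scf1 = 5000L))
  fl <- trim_flanks(extract_flank_coordinates(g, idx))
  calls <- data.frame(scaftig_id = "scf1", strand = "+",
                      position = c(400L, 950L), score = c(0.9, 0.9),
                      source = "nnpp_file", stringsAsFactors = FALSE)
  scan <- scan_flanks(fl, backend = "nnpp_file", calls = calls)
  up <- scan$hits[scan$hits$gene_id == "gB" & scan$hits$side == "upstream", ]
  expect_equal(up$position, 950L)  # closer to the gene 5' end at 999
  # higher score beats proximity
  calls$score <- c(0.95, 0.9)
  scan2 <- scan_flanks(fl, backend = "nnpp_file", calls = calls)
  expect_equal(scan2$hits$position[scan2$hits$side == "upstream"], 400L)
})

test_that("PWM consensus scores 1 and dominates every other hexamer", {
  model <- default_pwm_model()
  consensus <- paste0("TTGACA", strrep("G", 17), "TATAAT")
  s <- score_pwm(model, consensus)
  expect_equal(s$score, 1)
  expect_equal(s$minus35_start, 1L)
  expect_equal(s$minus10_end, 29L)

  # exhaustive: no -10 hexamer can beat the consensus TATAAT
  bases <- c("A", "C", "G", "T")
  hexes <- do.call(paste0, expand.grid(rep(list(bases), 6)))
  scores <- vapply(hexes, function(h) {
    score_pwm(model, paste0("TTGACA", strrep("G", 17), h))$score
  }, 0)
  expect_true(all(scores <= s$score + 1e-12))
  expect_equal(sum(abs(scores - s$score) < 1e-12), 1L)  # only TATAAT itself
})

test_that("PWM backend hits regions carrying the motif and maps the position back", {
  set.seed(3)
  motif <- paste0("TTGACA", random_seq(17), "TATAAT")
  left <- random_seq(300)
  scf <- paste0(left, motif, random_seq(40), strrep("A", 500), random_seq(200))
  g <- make_genes(370, 800, "+", gene_id = "gA")  # motif ends 40 bp upstream
  idx <- index_from_seqs(list(scf1 = scf))
  fl <- extract_flank_sequences(
    trim_flanks(extract_flank_coordinates(g, idx)), idx)
  scan <- scan_flanks(fl, backend = "pwm", threshold = 0.8)
  expect_true(scan$upstream_hit[["gA"]])
  up <- scan$hits[scan$hits$side == "upstream" & scan$hits$gene_id == "gA", ]
  expect_equal(up$position, 329L)  # genomic coordinate of the -10 box end
  expect_equal(up$score, 1)

  expect_error(
    scan_flanks(trim_flanks(extract_flank_coordinates(g, idx)),
                backend = "pwm"),
    "sequences")
})

test_that("raising the threshold never increases the number of hits", {
  set.seed(11)
  g <- random_gene_table(10, scaftig_len = 20000L)
  sc <- unique(g$scaftig_id)
  idx <- index_from_seqs(stats::setNames(list(random_seq(20000L)), sc))
  fl <- extract_flank_sequences(
    trim_flanks(extract_flank_coordinates(g, idx)), idx)
  pwm_hits <- vapply(c(0, 0.3, 0.6, 0.9, 1), function(th) {
    nrow(scan_flanks(fl, backend = "pwm", threshold = th)$hits)
  }, 0L)
  expect_true(all(diff(pwm_hits) <= 0L))

  calls <- data.frame(scaftig_id = sc,
                      strand = sample(c("+", "-"), 30, replace = TRUE),
                      position = sample.int(20000L, 30), score = runif(30),
                      source = "nnpp_file", stringsAsFactors = FALSE)
  nnpp_hits <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(th) {
    nrow(scan_flanks(fl, backend = "nnpp_file", calls = calls,
                     threshold = th)$hits)
  }, 0L)
  expect_true(all(diff(nnpp_hits) <= 0L))
})

test_that("short-tagged regions never hit under any backend", {
  g <- make_genes(c(100, 205, 215), c(200, 210, 600), "+",
                  gene_id = c("a", "b", "c"))
  idx <- index_from_seqs(list(scf1 = paste0(
    random_seq(90), "TTGACA", random_seq(17), "TATAAT", random_seq(700))))
  fl <- extract_flank_sequences(
    trim_flanks(extract_flank_coordinates(g, idx)), idx)
  short_genes <- unique(fl$gene_id[fl$status %in% c("short_ups", "short_dss")])
  expect_true(length(short_genes) > 0)
  calls <- data.frame(scaftig_id = "scf1", strand = "+",
                      position = c(202L, 212L), score = 0.99,
                      source = "nnpp_file", stringsAsFactors = FALSE)
  for (args in list(list(backend = "nnpp_file", calls = calls),
                    list(backend = "pwm", threshold = 0),
                    list(backend = "oracle",
                         oracle_truth = data.frame(gene_id = c("b", "b"),
                                                   side = c("upstream",
                                                            "downstream"))))) {
    scan <- do.call(scan_flanks, c(list(regions = fl), args))
    short_fl <- fl[fl$status %in% c("short_ups", "short_dss"), ]
    hit_key <- paste(scan$hits$gene_id, scan$hits$side)
    expect_false(any(paste(short_fl$gene_id, short_fl$side) %in% hit_key))
  }
})
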