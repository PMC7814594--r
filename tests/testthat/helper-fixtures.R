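# Fixture builders and independent oracles used across the suite.

make_genes <- function(start, end, strand, scaftig = "scf1",
                       gene_id = NULL, sort = TRUE) {
  n <- length(start)
  scaftig <- rep_len(scaftig, n)
  g <- data.frame(
    gene_id = if (is.null(gene_id)) sprintf("g%d", seq_len(n)) else gene_id,
    scaftig_id = scaftig,
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n),
    source_tool = "prodigal",
    stringsAsFactors = FALSE
  )
  if (sort) {
    g <- g[order(g$scaftig_id, g$start, g$end), , drop = FALSE]
    rownames(g) <- NULL
  }
  g
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

write_fasta_fixture <- function(seqs, path, width = 60L) {
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  path
}

write_gff_fixture <- function(lines, path) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(scaftig, start, end, strand, attrs = ".", type = "CDS",
                     source = "Prodigal_v2.6.3") {
  paste(scaftig, source, type, start, end, ".", strand, "0", attrs, sep = "\t")
}

# fake scaftig index from lengths only (coordinate-level tests)
index_from_lengths <- function(lengths) {
  idx <- list(lengths = lengths, sequences = NULL)
  class(idx) <- "scaftig_index"
  idx
}

index_from_seqs <- function(seqs) {
  idx <- list(lengths = vapply(seqs, nchar, 0L), sequences = unlist(seqs))
  class(idx) <- "scaftig_index"
  idx
}

# random sorted gene layout on one or more scaftigs; genes may abut/overlap
random_gene_table <- function(n_genes, n_scaftigs = 1L, scaftig_len = 20000L,
                              allow_overlap = FALSE) {
  rows <- list()
  for (s in seq_len(n_scaftigs)) {
    sc <- sprintf("rscf%d", s)
    pos <- 1L
    for (i in seq_len(n_genes)) {
      gap <- sample(0:900, 1L)
      if (allow_overlap && runif(1) < 0.2) gap <- -sample(1:50, 1L)
      start <- max(1L, pos + gap)
      len <- sample(100:800, 1L)
      end <- start + len - 1L
      if (end > scaftig_len - 100L) break
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("%s_g%d", sc, i), scaftig_id = sc,
        start = start, end = end,
        strand = sample(c("+", "-"), 1L), source_tool = "prodigal",
        stringsAsFactors = FALSE)
      pos <- end
    }
  }
  g <- do.call(rbind, rows)
  g <- g[order(g$scaftig_id, g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Independent proximon oracle: maximal window extension, one pair at a time.
brute_proximons <- function(genes, threshold = 601L) {
  res <- list()
  for (sc in unique(genes$scaftig_id)) {
    g <- genes[genes$scaftig_id == sc, , drop = FALSE]
    n <- nrow(g)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n &&
             g$strand[j + 1L] == g$strand[i] &&
             ((g$start[j + 1L] - g$end[j]) + 1L) < threshold) {
        j <- j + 1L
      }
      if (j > i) res[[length(res) + 1L]] <- g$gene_id[i:j]
      i <- j + 1L
    }
  }
  res
}

# Independent configuration classifier: explicit predicate table, applied
# in the documented precedence order.
brute_classify_one <- function(s, ref_sets, ref_ids) {
  overlaps <- vapply(ref_sets, function(r) length(intersect(s, r)), 0L)
  touching <- ref_ids[overlaps > 0L]
  best_frac <- if (length(touching) > 0L) max(overlaps) / length(s) else 0
  is_perfect <- any(vapply(ref_sets[overlaps > 0L],
                           function(r) setequal(s, r), TRUE))
  if (best_frac < 0.5) return("novel")
  if (is_perfect) return("perfect_match")
  if (length(touching) >= 2L) return("bridge1")
  r <- ref_sets[[which(overlaps > 0L)]]
  if (all(r %in% s) && length(s) > length(r)) return("superset")
  "subset"
}

# wrap a bare operon gene-set list as a minimal operon data.frame
operons_from_sets <- function(sets, scaftig = "scf1", strand = "+") {
  n <- length(sets)
  data.frame(
    operon_id = sprintf("p%d", seq_len(n)),
    scaftig_id = rep_len(scaftig, n), strand = rep_len(strand, n),
    gene_ids = I(sets),
    start = rep_len(NA_integer_, n), end = rep_len(NA_integer_, n),
    upstream_promoter_pos = rep_len(NA_integer_, n),
    downstream_promoter_pos = rep_len(NA_integer_, n),
    mode = rep_len("igd_promoter", n),
    stringsAsFactors = FALSE
  )
}

# promoter scan stub with hits given as gene-id character vectors
scan_stub <- function(gene_ids, upstream = character(0),
                      downstream = character(0)) {
  up <- stats::setNames(gene_ids %in% upstream, gene_ids)
  dn <- stats::setNames(gene_ids %in% downstream, gene_ids)
  hits <- rbind(
    if (length(upstream) > 0L)
      data.frame(gene_id = upstream, side = "upstream", position = NA_integer_,
                 score = 1, stringsAsFactors = FALSE),
    if (length(downstream) > 0L)
      data.frame(gene_id = downstream, side = "downstream",
                 position = NA_integer_, score = 1, stringsAsFactors = FALSE)
  )
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(0), side = character(0),
                       position = integer(0), score = numeric(0),
                       stringsAsFactors = FALSE)
  }
  scan <- list(backend = "oracle", threshold = 0.8, hits = hits,
               upstream_hit = up, downstream_hit = dn)
  class(scan) <- "promoter_scan"
  scan
}

# trimmed flank table for a gene table (coordinates only)
flanks_for <- function(genes, lengths) {
  trim_flanks(extract_flank_coordinates(genes, index_from_lengths(lengths)))
}
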