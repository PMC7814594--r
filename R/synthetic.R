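#' Specification for a synthetic prokaryotic genome
#'
#' Bundles and validates all parameters of the synthetic genome generator.
#' The generator plants operons (clusters of co-directional genes with
#' controlled intra-operon spacing and a sigma70 promoter motif upstream of
#' the transcriptionally first gene), separates consecutive transcription
#' units by gaps wide enough that distance clustering cannot join them, and
#' sprinkles non-operonic decoy genes between units so that true negatives
#' exist and specificity is actually exercised.
#'
#' Gap semantics: a gap of g between two features means the next feature
#' starts g bp after the previous one ends (start = end + g; abutting
#' features have gap 1). Under the intergenic-distance convention used
#' throughout this package a planted gap of g corresponds to IGD g + 1, so
#' a gap range of [50, 100] yields IGDs in [51, 101].
#'
#' @param n_scaftigs Number of scaftigs.
#' @param scaftig_length_range Min/max scaftig length in bp.
#' @param n_operons Total operons planted across all scaftigs.
#' @param operon_size_probs Named probability vector over operon sizes
#'   (genes per operon); the default is heavy on sizes 2-4, as in real
#'   microbial genomes where most operons are binary.
#' @param intra_operon_gap_range Physical gap range (bp) between consecutive
#'   genes of one operon; must stay below the clustering threshold after the
#'   +1 IGD shift.
#' @param inter_unit_gap_range Physical gap range (bp) between consecutive
#'   transcription units (and decoys); must exceed the threshold so units
#'   stay separate, and must leave room for the promoter motif.
#' @param strand_switch_probability Probability that a unit flips strand
#'   relative to the previous unit.
#' @param gene_length_range Gene length range in bp.
#' @param decoy_probability Probability of planting a non-operonic decoy
#'   gene before each operon.
#' @param promoter_offset Distance in bp from the gene-proximal end of the
#'   promoter motif to the 5' end of the operon's first gene.
#' @param promoter_spacer Spacer length in bp between the -35 and -10 boxes
#'   of the planted motif (default 17, matched by the default PWM model).
#' @param background_gc GC content of the background sequence.
#' @param seed Mandatory integer seed; the same spec with the same seed
#'   produces byte-identical output files.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_scaftigs = 3L,
                           scaftig_length_range = c(40000L, 50000L),
                           n_operons = 12L,
                           operon_size_probs = c("2" = 0.50, "3" = 0.20,
                                                 "4" = 0.15, "5" = 0.10,
                                                 "6" = 0.05),
                           intra_operon_gap_range = c(20L, 150L),
                           inter_unit_gap_range = c(700L, 1200L),
                           strand_switch_probability = 0.5,
                           gene_length_range = c(300L, 900L),
                           decoy_probability = 0.3,
                           promoter_offset = 40L,
                           promoter_spacer = 17L,
                           background_gc = 0.5,
                           seed) {
  if (missing(seed)) stop("synthetic_spec: a seed is mandatory")
  stopifnot(
    n_scaftigs >= 1L, n_operons >= 1L,
    length(scaftig_length_range) == 2L,
    scaftig_length_range[1L] <= scaftig_length_range[2L],
    length(intra_operon_gap_range) == 2L,
    intra_operon_gap_range[1L] <= intra_operon_gap_range[2L],
    length(inter_unit_gap_range) == 2L,
    inter_unit_gap_range[1L] <= inter_unit_gap_range[2L],
    length(gene_length_range) == 2L,
    gene_length_range[1L] <= gene_length_range[2L],
    strand_switch_probability >= 0, strand_switch_probability <= 1,
    decoy_probability >= 0, decoy_probability <= 1,
    background_gc > 0, background_gc < 1,
    promoter_offset >= 1L, promoter_spacer >= 0L
  )
  if (abs(sum(operon_size_probs) - 1) > 1e-9) {
    stop("operon_size_probs must sum to 1")
  }
  if (any(as.integer(names(operon_size_probs)) < 2L)) {
    stop("operon sizes must be >= 2")
  }
  motif_len <- 12L + promoter_spacer
  if (inter_unit_gap_range[1L] < promoter_offset + motif_len) {
    stop("inter_unit_gap_range too small to hold the promoter motif ",
         "(needs >= ", promoter_offset + motif_len, " bp)")
  }
  spec <- list(
    n_scaftigs = as.integer(n_scaftigs),
    scaftig_length_range = as.integer(scaftig_length_range),
    n_operons = as.integer(n_operons),
    operon_size_probs = operon_size_probs,
    intra_operon_gap_range = as.integer(intra_operon_gap_range),
    inter_unit_gap_range = as.integer(inter_unit_gap_range),
    strand_switch_probability = strand_switch_probability,
    gene_length_range = as.integer(gene_length_range),
    decoy_probability = decoy_probability,
    promoter_offset = as.integer(promoter_offset),
    promoter_spacer = as.integer(promoter_spacer),
    background_gc = background_gc,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic genome with planted operons and ground truth
#'
#' Lays out each scaftig left to right: units (operons or single decoy
#' genes) separated by inter-unit gaps, genes within an operon separated by
#' intra-operon gaps. Each operon's transcriptionally first gene carries a
#' sigma70 promoter motif (TTGACA, spacer, TATAAT) whose gene-proximal end
#' sits `promoter_offset` bp upstream of the gene's 5' end; on minus-strand
#' operons the motif is reverse-complemented and placed at higher genomic
#' coordinates. Gene identifiers follow the prodigal convention
#' `<scaftig>_<ordinal>` in genomic order.
#'
#' Writes four files to `out_dir`: `scaftigs.fasta`, `genes.gff` (prodigal
#' dialect), `truth_operons.tsv` (operon_id, scaftig_id, strand, gene_ids,
#' promoter_pos, plus a `truth_nonoperonic.tsv` side list) and
#' `truth_promoters.tsv` (the oracle backend's input: gene_id, side,
#' scaftig_id, strand, position, score).
#'
#' @param spec A `synthetic_spec`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `paths` (named file paths), `genes`
#'   (gene table), `truth` (list `operons` data.frame with `gene_ids` list
#'   column in transcription order, `nonoperonic_gene_ids`), `promoters`
#'   (oracle table), and `scaftigs` (named character vector of sequences).
#' @export
generate_synthetic_genome <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  set.seed(spec$seed)
  motif_len <- 12L + spec$promoter_spacer
  tail_margin <- spec$promoter_offset + motif_len
  sizes <- as.integer(names(spec$operon_size_probs))

  # spread operons over scaftigs as evenly as possible
  per_scf <- rep(spec$n_operons %/% spec$n_scaftigs, spec$n_scaftigs)
  extra <- spec$n_operons %% spec$n_scaftigs
  if (extra > 0L) per_scf[seq_len(extra)] <- per_scf[seq_len(extra)] + 1L

  rint <- function(range) {
    if (range[1L] == range[2L]) range[1L]
    else sample(range[1L]:range[2L], 1L)
  }
  bases <- c("A", "C", "G", "T")
  p_bg <- c((1 - spec$background_gc) / 2, spec$background_gc / 2,
            spec$background_gc / 2, (1 - spec$background_gc) / 2)

  gene_rows <- list()
  truth_rows <- list()
  prom_rows <- list()
  nonoperonic <- character(0)
  seqs <- character(spec$n_scaftigs)
  scf_ids <- sprintf("scf%d", seq_len(spec$n_scaftigs))

  for (s in seq_len(spec$n_scaftigs)) {
    scf <- scf_ids[s]
    L <- rint(spec$scaftig_length_range)
    cursor <- 0L  # rightmost occupied base so far
    gene_ord <- 0L
    op_ord <- 0L
    strand <- sample(c("+", "-"), 1L)
    motifs <- list()  # (pos, string) overlays on the background

    place_gene <- function(start, len) {
      end <- start + len - 1L
      gene_ord <<- gene_ord + 1L
      id <- sprintf("%s_%d", scf, gene_ord)
      gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
        gene_id = id, scaftig_id = scf, start = start, end = end,
        strand = strand, stringsAsFactors = FALSE)
      list(id = id, start = start, end = end)
    }

    n_units_left <- function() per_scf[s] - op_ord

    while (n_units_left() > 0L) {
      if (stats::runif(1L) < spec$strand_switch_probability) {
        strand <- if (strand == "+") "-" else "+"
      }
      plant_decoy <- stats::runif(1L) < spec$decoy_probability
      if (plant_decoy) {
        gap <- rint(spec$inter_unit_gap_range)
        len <- rint(spec$gene_length_range)
        start <- cursor + gap
        if (start + len - 1L > L - tail_margin) {
          stop("infeasible packing: decoy gene on ", scf,
               " would exceed scaftig length ", L)
        }
        g <- place_gene(start, len)
        nonoperonic <- c(nonoperonic, g$id)
        cursor <- g$end
        if (stats::runif(1L) < spec$strand_switch_probability) {
          strand <- if (strand == "+") "-" else "+"
        }
      }
      k <- sizes[sample.int(length(sizes), 1L, prob = spec$operon_size_probs)]
      gap <- rint(spec$inter_unit_gap_range)
      lens <- vapply(seq_len(k), function(i) rint(spec$gene_length_range), 0L)
      intra <- if (k > 1L) {
        vapply(seq_len(k - 1L), function(i) rint(spec$intra_operon_gap_range), 0L)
      } else integer(0)
      total <- sum(lens) + sum(intra)
      start1 <- cursor + gap
      if (start1 + total - 1L > L - tail_margin) {
        stop("infeasible packing: operon of ", k, " genes on ", scf,
             " would exceed scaftig length ", L)
      }
      members <- vector("list", k)
      pos <- start1
      for (i in seq_len(k)) {
        members[[i]] <- place_gene(pos, lens[i])
        pos <- members[[i]]$end + (if (i < k) intra[i] else 1L)
      }
      cursor <- members[[k]]$end
      op_ord <- op_ord + 1L

      # promoter motif upstream of the transcriptionally first gene
      spacer_seq <- paste(sample(bases, spec$promoter_spacer, replace = TRUE,
                                 prob = p_bg), collapse = "")
      motif_fwd <- paste0("TTGACA", spacer_seq, "TATAAT")
      if (strand == "+") {
        first <- members[[1L]]
        prom_pos <- first$start - spec$promoter_offset
        motifs[[length(motifs) + 1L]] <-
          list(pos = prom_pos - motif_len + 1L, string = motif_fwd)
      } else {
        first <- members[[k]]
        prom_pos <- first$end + spec$promoter_offset
        motifs[[length(motifs) + 1L]] <-
          list(pos = prom_pos, string = revcomp(motif_fwd))
      }
      tx_ids <- vapply(members, `[[`, "", "id")
      if (strand == "-") tx_ids <- rev(tx_ids)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        operon_id = sprintf("top_%s_%d", scf, op_ord),
        scaftig_id = scf, strand = strand,
        gene_ids = I(list(tx_ids)),
        promoter_pos = prom_pos,
        stringsAsFactors = FALSE)
      prom_rows[[length(prom_rows) + 1L]] <- data.frame(
        gene_id = tx_ids[1L], side = "upstream", scaftig_id = scf,
        strand = strand, position = prom_pos, score = 1,
        stringsAsFactors = FALSE)
    }

    seq_chars <- sample(bases, L, replace = TRUE, prob = p_bg)
    for (m in motifs) {
      mc <- strsplit(m$string, "")[[1L]]
      seq_chars[m$pos:(m$pos + length(mc) - 1L)] <- mc
    }
    seqs[s] <- paste(seq_chars, collapse = "")
  }

  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$scaftig_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  truth_operons <- do.call(rbind, truth_rows)
  rownames(truth_operons) <- NULL
  promoters <- do.call(rbind, prom_rows)
  rownames(promoters) <- NULL
  names(seqs) <- scf_ids

  paths <- c(
    fasta = file.path(out_dir, "scaftigs.fasta"),
    gff = file.path(out_dir, "genes.gff"),
    truth = file.path(out_dir, "truth_operons.tsv"),
    nonoperonic = file.path(out_dir, "truth_nonoperonic.tsv"),
    promoters = file.path(out_dir, "truth_promoters.tsv")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), paths[["fasta"]])
  gff <- c("##gff-version 3",
           sprintf("%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;",
                   genes$scaftig_id, genes$start, genes$end, genes$strand,
                   genes$gene_id))
  writeLines(gff, paths[["gff"]])
  utils::write.table(
    data.frame(operon_id = truth_operons$operon_id,
               scaftig_id = truth_operons$scaftig_id,
               strand = truth_operons$strand,
               gene_ids = vapply(truth_operons$gene_ids, paste, "",
                                 collapse = ";"),
               promoter_pos = truth_operons$promoter_pos),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = sort(nonoperonic)),
                     paths[["nonoperonic"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(promoters, paths[["promoters"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(
    paths = paths, genes = genes,
    truth = list(operons = truth_operons,
                 nonoperonic_gene_ids = sort(nonoperonic)),
    promoters = promoters, scaftigs = seqs, spec = spec
  ))
}
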