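#' Compute raw upstream/downstream intergenic flank coordinates
#'
#' For every gene, computes the intergenic region on each side of its coding
#' span. "Upstream" and "downstream" are transcription-relative: for a
#' minus-strand gene the upstream flank lies at higher genomic coordinates.
#' The intergenic boundary on each genomic side is the nearest coding base of
#' any neighboring gene (regardless of the neighbor's strand) or the scaftig
#' edge. Regions squeezed to length zero by abutting or overlapping
#' neighbors get `raw_length = 0` and are tagged short immediately.
#'
#' Coordinates are 1-based inclusive throughout; a zero-length region is
#' represented with `end = start - 1`.
#'
#' @param genes Gene table sorted by `(scaftig_id, start)`.
#' @param index A `scaftig_index` covering every scaftig in `genes`.
#' @return Flank data.frame with one upstream and one downstream row per
#'   gene: `gene_id`, `side`, `scaftig_id`, `strand`, `start`, `end`,
#'   `raw_length`, `status` (`"raw"` until [trim_flanks()] finalizes it),
#'   `sequence` (`NA` until [extract_flank_sequences()]). Genes extending
#'   beyond their scaftig are skipped and reported in the `"errors"`
#'   attribute.
#' @export
extract_flank_coordinates <- function(genes, index) {
  assert_sorted_genes(genes)
  missing_scf <- setdiff(unique(genes$scaftig_id), names(index$lengths))
  if (length(missing_scf) > 0L) {
    stop("scaftig(s) referenced by genes but absent from index: ",
         paste(missing_scf, collapse = ", "))
  }
  errors <- character(0)
  out <- vector("list", length(unique(genes$scaftig_id)))
  k <- 0L
  for (sc in unique(genes$scaftig_id)) {
    g <- genes[genes$scaftig_id == sc, , drop = FALSE]
    L <- unname(index$lengths[[sc]])
    bad <- g$end > L
    if (any(bad)) {
      errors <- c(errors, sprintf("gene %s extends beyond scaftig %s (%d > %d)",
                                  g$gene_id[bad], sc, g$end[bad], L))
      g <- g[!bad, , drop = FALSE]
    }
    n <- nrow(g)
    if (n == 0L) next
    # intergenic bounds against ANY previously-ending / next-starting gene,
    # so nested or overlapping neighbors cannot leak coding bases into flanks
    left_cov <- c(0L, cummax(g$end))[seq_len(n)]
    right_cov <- if (n > 1L) c(rev(cummin(rev(g$start)))[-1L], L + 1L) else L + 1L
    left_start <- left_cov + 1L
    left_end <- g$start - 1L
    right_start <- g$end + 1L
    right_end <- right_cov - 1L
    left_len <- pmax(0L, left_end - left_start + 1L)
    right_len <- pmax(0L, right_end - right_start + 1L)
    # empty interval convention: end = start - 1
    left_start <- pmin(left_start, left_end + 1L)
    right_end <- pmax(right_end, right_start - 1L)

    plus <- g$strand == "+"
    mk <- function(side, s, e, len) {
      data.frame(gene_id = g$gene_id, side = side, scaftig_id = sc,
                 strand = g$strand, start = s, end = e, raw_length = len,
                 status = ifelse(
                   len == 0L,
                   ifelse(side == "upstream", "short_ups", "short_dss"),
                   "raw"),
                 sequence = NA_character_, stringsAsFactors = FALSE)
    }
    ups <- mk("upstream",
              ifelse(plus, left_start, right_start),
              ifelse(plus, left_end, right_end),
              ifelse(plus, left_len, right_len))
    dss <- mk("downstream",
              ifelse(plus, right_start, left_start),
              ifelse(plus, right_end, left_end),
              ifelse(plus, right_len, left_len))
    k <- k + 1L
    out[[k]] <- rbind(ups, dss)
  }
  res <- if (k == 0L) {
    data.frame(gene_id = character(0), side = character(0),
               scaftig_id = character(0), strand = character(0),
               start = integer(0), end = integer(0), raw_length = integer(0),
               status = character(0), sequence = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out[seq_len(k)])
  }
  rownames(res) <- NULL
  if (length(errors) > 0L) {
    warning(length(errors), " gene(s) skipped during flank extraction",
            call. = FALSE)
  }
  attr(res, "errors") <- errors
  res
}

#' Trim flank regions and finalize their status tags
#'
#' Applies the two flank rules: regions longer than `cap` (default 700 bp)
#' are cut to the `cap` bases nearest the gene (the gene-proximal end is
#' kept, since promoter signal concentrates near the transcription start)
#' and tagged `trimmed`; regions shorter than `min_len` (default 15 bp, the
#' minimum span on which a promoter signature can appear) are tagged
#' `short_ups`/`short_dss` and excluded from promoter scanning. Regions of
#' `min_len` up to `cap` bp pass unchanged with status `ok`.
#'
#' @param regions Flank data.frame from [extract_flank_coordinates()].
#' @param cap Maximum retained flank length in bp (default 700).
#' @param min_len Minimum usable flank length in bp (default 15); regions
#'   strictly shorter are short-tagged.
#' @return The flank data.frame with final `start`, `end`, `status`.
#' @export
trim_flanks <- function(regions, cap = 700L, min_len = 15L) {
  if (nrow(regions) == 0L) return(regions)
  stopifnot(cap >= min_len)
  short <- regions$raw_length < min_len
  long <- regions$raw_length > cap
  regions$status <- ifelse(
    short,
    ifelse(regions$side == "upstream", "short_ups", "short_dss"),
    ifelse(long, "trimmed", "ok")
  )
  # a region genomically left of its gene keeps its right (gene-proximal) end
  left_of_gene <- (regions$side == "upstream" & regions$strand == "+") |
    (regions$side == "downstream" & regions$strand == "-")
  cut_right <- long & left_of_gene
  cut_left <- long & !left_of_gene
  regions$start[cut_right] <- regions$end[cut_right] - cap + 1L
  regions$end[cut_left] <- regions$start[cut_left] + cap - 1L
  regions
}

#' Fill flank sequences from the scaftig index
#'
#' Extracts the nucleotide sequence of every `ok`/`trimmed` flank region and
#' orients it 5'-to-3' on the gene's strand (minus-strand regions are
#' reverse-complemented). Short-tagged regions get an empty sequence.
#'
#' @param regions Trimmed flank data.frame from [trim_flanks()].
#' @param index A `scaftig_index` loaded with sequences.
#' @return The flank data.frame with the `sequence` column filled.
#' @export
extract_flank_sequences <- function(regions, index) {
  if (is.null(index$sequences)) {
    stop("scaftig index was built without sequences; ",
         "rerun index_scaftigs() with load_sequences = TRUE")
  }
  if (nrow(regions) == 0L) return(regions)
  fill <- regions$status %in% c("ok", "trimmed")
  regions$sequence <- ""
  if (any(fill)) {
    scf_len <- index$lengths[regions$scaftig_id[fill]]
    if (any(regions$end[fill] > scf_len | regions$start[fill] < 1L)) {
      stop("internal inconsistency: flank coordinates exceed scaftig bounds")
    }
    seqs <- substr(index$sequences[regions$scaftig_id[fill]],
                   regions$start[fill], regions$end[fill])
    minus <- regions$strand[fill] == "-"
    seqs[minus] <- revcomp(seqs[minus])
    regions$sequence[fill] <- seqs
  }
  regions
}
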