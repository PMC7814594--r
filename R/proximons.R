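#' Intergenic distance between two adjacent genes
#'
#' Computes the intergenic distance IGD(G1, G2) = (start(G2) - end(G1)) + 1
#' between two genes on the same scaftig, with G1 preceding G2 in genomic
#' order. Note the +1 offset of this convention: abutting genes (G2 starting
#' immediately after G1 ends) have IGD 2, not 1, and the clustering
#' threshold is interpreted on this same scale. Overlapping genes yield an
#' IGD of zero or less; that is allowed and is itself strong evidence of
#' co-transcription.
#'
#' @param g1,g2 Single-row data.frames (or lists) with `scaftig_id`, `start`
#'   and `end` fields; `g1` must precede `g2`.
#' @return Integer intergenic distance in bp (may be <= 0 for overlaps).
#' @export
compute_igd <- function(g1, g2) {
  if (!identical(as.character(g1$scaftig_id), as.character(g2$scaftig_id))) {
    stop("compute_igd: genes are on different scaftigs")
  }
  if (g1$start > g2$start) {
    stop("compute_igd: g1 must precede g2 in genomic order")
  }
  as.integer(g2$start - g1$end) + 1L
}

#' Cluster co-directional proximal genes into proximons
#'
#' Walks the sorted gene table scaftig by scaftig and chains consecutive
#' genes into one cluster while the strand is unchanged and the intergenic
#' distance between them stays strictly below `max_igd_exclusive`
#' (default 601, i.e. IGD <= 600 clusters). Chains of two or more genes
#' become proximons; singletons are discarded. The threshold is deliberately
#' permissive ("stretchy"): in metagenomic data no single intergenic
#' distance cutoff fits all taxa, so over-inclusive clusters are formed
#' first and refined later by promoter evidence.
#'
#' @param genes Gene table sorted by `(scaftig_id, start)`.
#' @param max_igd_exclusive Exclusive IGD threshold in bp; genes with
#'   IGD >= this value never co-cluster. Default 601.
#' @return Proximon data.frame: `proximon_id` (`prox_<scaftig>_<ordinal>`),
#'   `scaftig_id`, `strand`, `genes` (list column of gene ids in genomic
#'   start order), `igds` (list column, one IGD per adjacent pair),
#'   `n_genes`.
#' @export
call_proximons <- function(genes, max_igd_exclusive = 601L) {
  assert_sorted_genes(genes)
  out <- list()
  for (sc in unique(genes$scaftig_id)) {
    g <- genes[genes$scaftig_id == sc, , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) next
    igd <- (g$start[-1L] - g$end[-n]) + 1L
    new_chain <- c(TRUE, g$strand[-1L] != g$strand[-n] | igd >= max_igd_exclusive)
    chain <- cumsum(new_chain)
    ord <- 0L
    for (ch in unique(chain)) {
      sel <- which(chain == ch)
      if (length(sel) < 2L) next
      ord <- ord + 1L
      out[[length(out) + 1L]] <- data.frame(
        proximon_id = sprintf("prox_%s_%d", sc, ord),
        scaftig_id = sc,
        strand = g$strand[sel[1L]],
        genes = I(list(g$gene_id[sel])),
        igds = I(list(igd[sel[-length(sel)]])),
        n_genes = length(sel),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(proximon_id = character(0), scaftig_id = character(0),
                      strand = character(0), genes = I(list()),
                      igds = I(list()), n_genes = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
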