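# Shared transcription-unit-boundary walk over one co-directional gene run.
#
# Genes are visited in transcription order. A transcription unit opens at a
# gene with an upstream promoter hit; it closes after gene i when gene i has
# a downstream promoter hit, when the next gene has an upstream promoter hit
# (one promoter in the shared intergenic span both ends the running unit and
# starts the next), or when the run ends. Genes seen while no unit is open
# are non-operonic; a hit only ever splits, its absence continues the
# running unit.
walk_boundaries <- function(gene_ids_tx, scan) {
  clusters <- list()
  nonoperonic <- character(0)
  current <- character(0)
  closed_by <- NA_character_
  flush <- function(cl, closer) {
    if (length(cl) >= 2L) {
      clusters[[length(clusters) + 1L]] <<- list(genes = cl, closer = closer)
    } else {
      nonoperonic <<- c(nonoperonic, cl)
    }
  }
  for (g in gene_ids_tx) {
    if (length(current) > 0L && scan$upstream_hit[[g]]) {
      flush(current, g)  # the opener of g doubles as the closer of the run
      current <- character(0)
    }
    if (length(current) > 0L) {
      current <- c(current, g)
    } else if (scan$upstream_hit[[g]]) {
      current <- g
    } else {
      nonoperonic <- c(nonoperonic, g)
      next
    }
    if (scan$downstream_hit[[g]]) {
      flush(current, g)
      current <- character(0)
    }
  }
  flush(current, NA_character_)
  list(clusters = clusters, nonoperonic = nonoperonic)
}

# assemble operon rows from boundary-walk clusters on one run
emit_operons <- function(clusters, genes, scan, scaftig, strand, mode) {
  rows <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    member <- genes[match(cl$genes, genes$gene_id), , drop = FALSE]
    first <- cl$genes[1L]
    last <- cl$genes[length(cl$genes)]
    up <- hit_info(scan, first, "upstream")
    dn <- if (!is.na(cl$closer) && cl$closer == last) {
      hit_info(scan, last, "downstream")
    } else if (!is.na(cl$closer)) {
      # closed by the next unit's opening promoter in the shared span
      hit_info(scan, cl$closer, "upstream")
    } else {
      list(position = NA_integer_, score = NA_real_)
    }
    rows[[k]] <- data.frame(
      operon_id = NA_character_, scaftig_id = scaftig, strand = strand,
      gene_ids = I(list(cl$genes)),
      start = min(member$start), end = max(member$end),
      upstream_promoter_pos = up$position, upstream_promoter_score = up$score,
      downstream_promoter_pos = dn$position, downstream_promoter_score = dn$score,
      mode = mode, n_genes = length(cl$genes),
      stringsAsFactors = FALSE
    )
  }
  rows
}

finalize_operons <- function(rows, nonoperonic, mode) {
  if (length(rows) == 0L) {
    ops <- data.frame(operon_id = character(0), scaftig_id = character(0),
                      strand = character(0), gene_ids = I(list()),
                      start = integer(0), end = integer(0),
                      upstream_promoter_pos = integer(0),
                      upstream_promoter_score = numeric(0),
                      downstream_promoter_pos = integer(0),
                      downstream_promoter_score = numeric(0),
                      mode = character(0), n_genes = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    ops <- do.call(rbind, rows)
    ops <- ops[order(ops$scaftig_id, ops$start), , drop = FALSE]
    ord <- stats::ave(seq_len(nrow(ops)), ops$scaftig_id, FUN = seq_along)
    ops$operon_id <- sprintf("op_%s_%d", ops$scaftig_id, ord)
    rownames(ops) <- NULL
  }
  res <- list(operons = ops, nonoperonic_genes = sort(unique(nonoperonic)),
              mode = mode)
  class(res) <- "operon_calls"
  res
}

#' Refine proximons into operons using promoter evidence
#'
#' Within each proximon, genes are walked in transcription order (for
#' minus-strand proximons that is decreasing genomic coordinate) and split
#' into transcription units at promoter hits: a unit opens at a gene with an
#' upstream promoter and closes at a downstream promoter hit, at the next
#' unit's opening promoter, or at the proximon edge. Units of two or more
#' genes become operons (mode `igd_promoter`); genes left outside any unit,
#' and would-be single-gene units, are reported as non-operonic rather than
#' silently dropped. The last unit of a proximon may legitimately lack a
#' downstream promoter — metagenomic scaftigs truncate operons — and is
#' recorded with an absent downstream boundary.
#'
#' @param proximons Proximon table from [call_proximons()].
#' @param scan A `promoter_scan` covering every proximon gene.
#' @param genes Gene table (for coordinates of the operon envelope).
#' @return An object of class `operon_calls`: list with `operons`
#'   (data.frame; `gene_ids` is a list column in transcription order),
#'   `nonoperonic_genes`, and `mode`.
#' @export
call_operons_igd_promoter <- function(proximons, scan, genes) {
  rows <- list()
  nonop <- character(0)
  for (i in seq_len(nrow(proximons))) {
    px <- proximons[i, ]
    ids <- px$genes[[1L]]
    if (!all(ids %in% names(scan$upstream_hit))) {
      stop("internal inconsistency: promoter scan does not cover proximon ",
           px$proximon_id)
    }
    tx <- if (px$strand == "-") rev(ids) else ids
    w <- walk_boundaries(tx, scan)
    rows <- c(rows, emit_operons(w$clusters, genes, scan, px$scaftig_id,
                                 px$strand, "igd_promoter"))
    nonop <- c(nonop, w$nonoperonic)
  }
  finalize_operons(rows, nonop, "igd_promoter")
}

#' Call operons from promoter evidence alone
#'
#' Applies the same transcription-unit-boundary walk as
#' [call_operons_igd_promoter()], but over maximal co-directional gene runs
#' on each scaftig with no intergenic-distance constraint at all: only a
#' strand switch or a promoter hit introduces a boundary, so arbitrarily
#' distant co-directional genes may end up in one operon (mode
#' `promoter_only`).
#'
#' @param genes Gene table sorted by `(scaftig_id, start)`.
#' @param scan A `promoter_scan` covering every gene.
#' @return An `operon_calls` object with mode `promoter_only`.
#' @export
call_operons_promoter_only <- function(genes, scan) {
  assert_sorted_genes(genes)
  if (!all(genes$gene_id %in% names(scan$upstream_hit))) {
    stop("internal inconsistency: promoter scan does not cover all genes")
  }
  rows <- list()
  nonop <- character(0)
  for (sc in unique(genes$scaftig_id)) {
    g <- genes[genes$scaftig_id == sc, , drop = FALSE]
    run <- cumsum(c(TRUE, g$strand[-1L] != g$strand[-nrow(g)]))
    for (r in unique(run)) {
      sel <- which(run == r)
      strand <- g$strand[sel[1L]]
      ids <- g$gene_id[sel]
      tx <- if (strand == "-") rev(ids) else ids
      w <- walk_boundaries(tx, scan)
      rows <- c(rows, emit_operons(w$clusters, genes, scan, sc, strand,
                                   "promoter_only"))
      nonop <- c(nonop, w$nonoperonic)
    }
  }
  finalize_operons(rows, nonop, "promoter_only")
}

#' @export
print.operon_calls <- function(x, ...) {
  cat("operon_calls (mode ", x$mode, "): ", nrow(x$operons), " operon(s), ",
      sum(x$operons$n_genes), " operonic gene(s), ",
      length(x$nonoperonic_genes), " non-operonic gene(s)\n", sep = "")
  invisible(x)
}
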