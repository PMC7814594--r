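#' Parse a gene-prediction GFF file
#'
#' Reads CDS features from a gene-prediction GFF in either the Prodigal or
#' the MetaGeneMark dialect and returns a gene table. Coordinates are kept
#' exactly as in the file (GFF is 1-based, inclusive at both ends). Features
#' other than CDS are ignored. Records with `end < start`, an invalid strand,
#' or non-numeric coordinates are dropped, collected, and reported via a
#' warning; the surviving records are returned sorted by
#' `(scaftig_id, start)`.
#'
#' Gene identifiers are taken from the attribute column: `ID=` for the
#' prodigal dialect, `gene_id` for the metagenemark dialect. When the
#' attribute is absent a deterministic identifier `<scaftig>_<ordinal>` is
#' synthesized, counting CDS records per scaftig in file order.
#'
#' @param gff_path Path to the GFF file.
#' @param source_tool Dialect of the file, `"prodigal"` or `"metagenemark"`.
#' @return A data.frame with columns `gene_id`, `scaftig_id`, `start`, `end`,
#'   `strand`, `source_tool`, sorted by scaftig then start. Dropped records
#'   are attached as a character vector in the `"errors"` attribute.
#' @export
parse_gene_predictions <- function(gff_path,
                                   source_tool = c("prodigal", "metagenemark")) {
  source_tool <- match.arg(source_tool)
  if (!file.exists(gff_path)) {
    stop("cannot read gene prediction file: ", gff_path)
  }
  lines <- readLines(gff_path, warn = FALSE)
  # a trailing ##FASTA section (some gene callers append one) is not annotation
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at) > 0L) lines <- lines[seq_len(fasta_at[1L] - 1L)]
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]

  errors <- character(0)
  recs <- list()
  ord_counter <- new.env(parent = emptyenv())

  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) {
      errors <- c(errors, sprintf("line %d: fewer than 8 tab-separated fields", i))
      next
    }
    if (f[3L] != "CDS") next  # non-CDS features skipped silently
    scaftig <- f[1L]
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    strand <- f[7L]
    ord <- (if (is.null(ord_counter[[scaftig]])) 0L else ord_counter[[scaftig]]) + 1L
    ord_counter[[scaftig]] <- ord
    if (is.na(start) || is.na(end)) {
      errors <- c(errors, sprintf("line %d: non-numeric coordinates", i))
      next
    }
    if (end < start || start < 1L) {
      errors <- c(errors, sprintf("line %d: invalid span %d-%d", i, start, end))
      next
    }
    if (!strand %in% c("+", "-")) {
      errors <- c(errors, sprintf("line %d: missing or invalid strand '%s'", i, strand))
      next
    }
    attrs <- if (length(f) >= 9L) f[9L] else ""
    id <- extract_gene_id(attrs, source_tool)
    if (is.na(id)) id <- sprintf("%s_%d", scaftig, ord)
    recs[[length(recs) + 1L]] <- list(
      gene_id = id, scaftig_id = scaftig,
      start = start, end = end, strand = strand
    )
  }

  if (length(recs) == 0L) {
    genes <- data.frame(
      gene_id = character(0), scaftig_id = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      source_tool = character(0), stringsAsFactors = FALSE
    )
  } else {
    genes <- data.frame(
      gene_id = vapply(recs, `[[`, "", "gene_id"),
      scaftig_id = vapply(recs, `[[`, "", "scaftig_id"),
      start = vapply(recs, `[[`, 0L, "start"),
      end = vapply(recs, `[[`, 0L, "end"),
      strand = vapply(recs, `[[`, "", "strand"),
      source_tool = source_tool,
      stringsAsFactors = FALSE
    )
    dup <- duplicated(genes$gene_id)
    if (any(dup)) {
      errors <- c(errors, sprintf("duplicate gene_id '%s' dropped", genes$gene_id[dup]))
      genes <- genes[!dup, , drop = FALSE]
    }
    genes <- genes[order(genes$scaftig_id, genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  if (length(errors) > 0L) {
    warning(length(errors), " malformed record(s) dropped from ", gff_path,
            call. = FALSE)
  }
  attr(genes, "errors") <- errors
  genes
}

extract_gene_id <- function(attrs, source_tool) {
  pattern <- switch(source_tool,
    prodigal = "(?:^|;)\\s*ID=([^;]+)",
    metagenemark = "gene_id[ =]+\"?([A-Za-z0-9_.:-]+)\"?"
  )
  m <- regmatches(attrs, regexec(pattern, attrs))[[1L]]
  if (length(m) == 2L && nzchar(m[2L])) m[2L] else NA_character_
}

#' Index a scaftig FASTA file
#'
#' Builds a lookup of scaftig lengths (and optionally sequences) from a
#' multi-record FASTA file. Record names are truncated at the first
#' whitespace. Duplicate scaftig identifiers are fatal because they make the
#' coordinate space of the gene predictions ambiguous.
#'
#' @param fasta_path Path to the FASTA file.
#' @param load_sequences Keep the sequences (needed for flank-sequence
#'   extraction and the PWM promoter backend), or lengths only.
#' @return An object of class `scaftig_index`: a list with `lengths` (named
#'   integer vector) and `sequences` (named character vector, or `NULL`).
#' @export
index_scaftigs <- function(fasta_path, load_sequences = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate scaftig identifier(s) in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(seqs) == 0L) {
    warning("no records in ", fasta_path, "; empty index", call. = FALSE)
  }
  idx <- list(
    lengths = stats::setNames(Biostrings::width(seqs), ids),
    sequences = if (load_sequences) stats::setNames(as.character(seqs), ids) else NULL
  )
  class(idx) <- "scaftig_index"
  idx
}

#' @export
print.scaftig_index <- function(x, ...) {
  cat("scaftig_index:", length(x$lengths), "scaftig(s),",
      sum(as.numeric(x$lengths)), "bp total,",
      if (is.null(x$sequences)) "lengths only" else "sequences loaded", "\n")
  invisible(x)
}

#' Remove short scaftigs and the genes on them
#'
#' Drops every scaftig whose length is less than or equal to `min_length`
#' (the boundary itself is removed), together with all genes located on a
#' removed scaftig.
#'
#' @param index A `scaftig_index`.
#' @param genes Gene table as from [parse_gene_predictions()].
#' @param min_length Length cutoff in bp; scaftigs of this length or shorter
#'   are removed. Default 500.
#' @return A list with the filtered `index` and `genes`.
#' @export
filter_scaftigs <- function(index, genes, min_length = 500L) {
  stopifnot(inherits(index, "scaftig_index"), min_length >= 0L)
  keep <- index$lengths > min_length
  kept_ids <- names(index$lengths)[keep]
  out_index <- list(
    lengths = index$lengths[keep],
    sequences = if (is.null(index$sequences)) NULL else index$sequences[kept_ids]
  )
  class(out_index) <- "scaftig_index"
  gene_keep <- genes$scaftig_id %in% kept_ids
  message(sum(!keep), " scaftig(s) removed (length <= ", min_length, " bp); ",
          sum(!gene_keep), " gene(s) dropped with them")
  list(index = out_index, genes = genes[gene_keep, , drop = FALSE])
}

#' Parse a tabular promoter-call file
#'
#' Reads promoter calls from a whitespace/tab-delimited file with columns
#' `scaftig_id`, `strand`, `position`, `score` (the layout used to interface
#' an external promoter predictor such as NNPP). Lines starting with `#` are
#' comments. Rows with an invalid strand, a non-positive position, or a score
#' outside [0, 1] are skipped, collected, and reported.
#'
#' @param path Path to the promoter file.
#' @return A data.frame with columns `scaftig_id`, `strand`, `position`,
#'   `score`, `source`; skipped rows in the `"errors"` attribute.
#' @export
parse_promoter_file <- function(path) {
  if (!file.exists(path)) stop("cannot read promoter file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  errors <- character(0)
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1L]]
    if (length(f) < 4L) {
      errors <- c(errors, sprintf("row %d: fewer than 4 fields", i))
      next
    }
    pos <- suppressWarnings(as.integer(f[3L]))
    score <- suppressWarnings(as.numeric(f[4L]))
    if (!f[2L] %in% c("+", "-")) {
      errors <- c(errors, sprintf("row %d: invalid strand '%s'", i, f[2L]))
      next
    }
    if (is.na(pos) || pos < 1L) {
      errors <- c(errors, sprintf("row %d: invalid position '%s'", i, f[3L]))
      next
    }
    if (is.na(score) || score < 0 || score > 1) {
      errors <- c(errors, sprintf("row %d: score '%s' outside [0, 1]", i, f[4L]))
      next
    }
    rows[[length(rows) + 1L]] <- list(scaftig_id = f[1L], strand = f[2L],
                                      position = pos, score = score)
  }
  calls <- if (length(rows) == 0L) {
    data.frame(scaftig_id = character(0), strand = character(0),
               position = integer(0), score = numeric(0),
               source = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(
      scaftig_id = vapply(rows, `[[`, "", "scaftig_id"),
      strand = vapply(rows, `[[`, "", "strand"),
      position = vapply(rows, `[[`, 0L, "position"),
      score = vapply(rows, `[[`, 0, "score"),
      source = "nnpp_file",
      stringsAsFactors = FALSE
    )
  }
  if (length(errors) > 0L) {
    warning(length(errors), " malformed promoter row(s) skipped", call. = FALSE)
  }
  if (nrow(calls) == 0L && length(errors) == 0L) {
    warning("promoter file ", path, " contains no calls", call. = FALSE)
  }
  attr(calls, "errors") <- errors
  calls
}

#' Read a reference operon table
#'
#' Reads a reference operon set from a two-column TSV (`operon_id`,
#' `gene_ids` with member genes joined by `;`). Every reference operon must
#' have at least two genes and no gene may belong to two reference operons.
#'
#' @param path Path to the reference TSV.
#' @return An object of class `reference_operons`: list with `operons`
#'   (data.frame with a `gene_ids` list column) and `gene_to_operon`
#'   (named character vector).
#' @export
read_reference_operons <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("operon_id", "gene_ids") %in% names(tab))) {
    stop("reference operon table needs columns operon_id and gene_ids")
  }
  gene_lists <- strsplit(tab$gene_ids, ";", fixed = TRUE)
  as_reference_operons(tab$operon_id, gene_lists)
}

#' Build a reference operon set from R objects
#'
#' @param operon_ids Character vector of operon identifiers.
#' @param gene_lists List of character vectors, each the ordered member genes
#'   of one operon.
#' @return A `reference_operons` object.
#' @export
as_reference_operons <- function(operon_ids, gene_lists) {
  sizes <- lengths(gene_lists)
  if (any(sizes < 2L)) {
    stop("reference operon(s) with fewer than 2 genes: ",
         paste(operon_ids[sizes < 2L], collapse = ", "))
  }
  all_genes <- unlist(gene_lists)
  if (anyDuplicated(all_genes)) {
    stop("gene(s) present in more than one reference operon: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  }
  ref <- list(
    operons = data.frame(operon_id = operon_ids,
                         gene_ids = I(gene_lists),
                         stringsAsFactors = FALSE),
    gene_to_operon = stats::setNames(rep(operon_ids, sizes), all_genes)
  )
  class(ref) <- "reference_operons"
  ref
}

#' Write pipeline result tables
#'
#' Exports proximons, operons, non-operonic genes and flank regions as
#' tab-delimited files, plus FASTA of operon envelope sequences and of
#' upstream/downstream flank sequences when sequences are available.
#' Writing then re-reading with [read_proximon_table()] /
#' [read_operon_table()] round-trips losslessly.
#'
#' @param proximons Proximon table from [call_proximons()] (or `NULL`).
#' @param operons An `operon_calls` object or operon data.frame (or `NULL`).
#' @param flanks Flank table with sequences (or `NULL`).
#' @param out_dir Output directory, created if needed.
#' @param index Optional `scaftig_index` with sequences, for `operons.fasta`.
#' @param nonoperonic Optional character vector of non-operonic gene ids
#'   (taken from `operons` when that is an `operon_calls` object).
#' @return Named character vector of the files written.
#' @export
write_tables <- function(proximons = NULL, operons = NULL, flanks = NULL,
                         out_dir, index = NULL, nonoperonic = NULL) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  if (!is.null(proximons)) {
    p <- file.path(out_dir, "proximons.tsv")
    tab <- data.frame(
      proximon_id = proximons$proximon_id,
      scaftig_id = proximons$scaftig_id,
      strand = proximons$strand,
      gene_ids = vapply(proximons$genes, paste, "", collapse = ";"),
      igds = vapply(proximons$igds, paste, "", collapse = ";"),
      stringsAsFactors = FALSE
    )
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["proximons"] <- p
  }
  if (!is.null(operons)) {
    if (inherits(operons, "operon_calls")) {
      if (is.null(nonoperonic)) nonoperonic <- operons$nonoperonic_genes
      operons <- operons$operons
    }
    p <- file.path(out_dir, "operons.tsv")
    tab <- data.frame(
      operon_id = operons$operon_id,
      scaftig_id = operons$scaftig_id,
      strand = operons$strand,
      gene_ids = vapply(operons$gene_ids, paste, "", collapse = ";"),
      start = operons$start,
      end = operons$end,
      upstream_promoter_pos = operons$upstream_promoter_pos,
      downstream_promoter_pos = operons$downstream_promoter_pos,
      mode = operons$mode,
      stringsAsFactors = FALSE
    )
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["operons"] <- p
    if (!is.null(index) && !is.null(index$sequences) && nrow(operons) > 0L) {
      fa <- file.path(out_dir, "operons.fasta")
      env <- substr(index$sequences[operons$scaftig_id], operons$start, operons$end)
      env[operons$strand == "-"] <- revcomp(env[operons$strand == "-"])
      writeLines(paste0(">", operons$operon_id, "|", operons$scaftig_id, ":",
                        operons$start, "-", operons$end, "(", operons$strand, ")",
                        "\n", env), fa)
      paths["operons_fasta"] <- fa
    }
  }
  if (!is.null(nonoperonic)) {
    p <- file.path(out_dir, "nonoperonic_genes.tsv")
    utils::write.table(data.frame(gene_id = nonoperonic), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["nonoperonic"] <- p
  }
  if (!is.null(flanks)) {
    for (side in c("upstream", "downstream")) {
      sel <- flanks$side == side & flanks$status %in% c("ok", "trimmed") &
        !is.na(flanks$sequence) & nzchar(flanks$sequence)
      if (!any(sel)) next
      fr <- flanks[sel, , drop = FALSE]
      p <- file.path(out_dir, paste0(side, ".fasta"))
      writeLines(paste0(">", fr$gene_id, "|", fr$side, "|", fr$scaftig_id, ":",
                        fr$start, "-", fr$end, "(", fr$strand, ")|", fr$status,
                        "\n", fr$sequence), p)
      paths[paste0(side, "_fasta")] <- p
    }
  }
  paths
}

#' Read back a proximon table written by [write_tables()]
#' @param path Path to `proximons.tsv`.
#' @return Proximon data.frame with `genes` and `igds` list columns.
#' @export
read_proximon_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  data.frame(
    proximon_id = tab$proximon_id,
    scaftig_id = tab$scaftig_id,
    strand = tab$strand,
    genes = I(strsplit(tab$gene_ids, ";", fixed = TRUE)),
    igds = I(lapply(strsplit(tab$igds, ";", fixed = TRUE), as.integer)),
    stringsAsFactors = FALSE
  )
}

#' Read back an operon table written by [write_tables()]
#' @param path Path to `operons.tsv`.
#' @return Operon data.frame with a `gene_ids` list column.
#' @export
read_operon_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  data.frame(
    operon_id = as.character(tab$operon_id),
    scaftig_id = as.character(tab$scaftig_id),
    strand = as.character(tab$strand),
    gene_ids = I(strsplit(as.character(tab$gene_ids), ";", fixed = TRUE)),
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    upstream_promoter_pos = as.integer(tab$upstream_promoter_pos),
    downstream_promoter_pos = as.integer(tab$downstream_promoter_pos),
    mode = as.character(tab$mode),
    stringsAsFactors = FALSE
  )
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# sortedness contract shared by downstream steps
assert_sorted_genes <- function(genes) {
  if (nrow(genes) > 1L) {
    o <- order(genes$scaftig_id, genes$start, genes$end)
    if (!identical(o, seq_len(nrow(genes)))) {
      stop("gene table must be sorted by (scaftig_id, start); ",
           "use parse_gene_predictions() or sort first")
    }
  }
  invisible(genes)
}
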