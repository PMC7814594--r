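#' Run the full operon-prediction pipeline on assembled input
#'
#' Executes the "op" process end to end on pre-assembled scaftigs and gene
#' predictions: scaftig-length filter, flank extraction/trimming, proximon
#' clustering by intergenic distance, promoter scanning with the chosen
#' backend, and operon calling in both modes (distance-plus-promoter and
#' promoter-only). All result tables are written to `out_dir` together with
#' a run manifest recording every parameter, input checksums, and the
#' promoter-backend provenance; any run is reproducible from its manifest.
#'
#' @param scaftigs Path to the scaftig FASTA file.
#' @param gff Path to the gene-prediction GFF.
#' @param gene_tool Gene prediction tool that produced the GFF
#'   (`"prodigal"` or `"metagenemark"`); must be stated explicitly.
#' @param out_dir Output directory.
#' @param promoter_backend `"nnpp_file"`, `"pwm"`, or `"oracle"`.
#' @param promoters Promoter-call file or table (nnpp_file backend).
#' @param oracle_truth Truth file or table (oracle backend).
#' @param pwm A `pwm_model` (pwm backend); defaults to
#'   [default_pwm_model()].
#' @param promoter_threshold Promoter score threshold in [0, 1]
#'   (default 0.8).
#' @param max_igd Exclusive intergenic-distance threshold in bp
#'   (default 601).
#' @param flank_cap Maximum flank length in bp (default 700).
#' @param flank_min Minimum usable flank length in bp (default 15).
#' @param min_scaftig_len Scaftigs of this length or shorter are removed
#'   (default 500).
#' @param write_outputs Write tables/FASTA/manifest to `out_dir`.
#' @return A list with every intermediate and final result: `genes`,
#'   `index`, `flanks`, `proximons`, `scan`, `operons_igd`
#'   (`operon_calls`), `operons_promoter_only` (`operon_calls`), `paths`.
#' @export
run_operon_pipeline <- function(scaftigs, gff, gene_tool, out_dir = NULL,
                                promoter_backend = c("pwm", "nnpp_file", "oracle"),
                                promoters = NULL, oracle_truth = NULL,
                                pwm = NULL, promoter_threshold = 0.8,
                                max_igd = 601L, flank_cap = 700L,
                                flank_min = 15L, min_scaftig_len = 500L,
                                write_outputs = !is.null(out_dir)) {
  if (missing(gene_tool)) {
    stop("the gene prediction tool must be specified ",
         "('prodigal' or 'metagenemark')")
  }
  gene_tool <- match.arg(gene_tool, c("prodigal", "metagenemark"))
  promoter_backend <- match.arg(promoter_backend)
  if (write_outputs && is.null(out_dir)) stop("out_dir is required to write outputs")

  genes <- parse_gene_predictions(gff, gene_tool)
  index <- index_scaftigs(scaftigs, load_sequences = TRUE)
  message(nrow(genes), " gene(s) parsed on ", length(index$lengths),
          " scaftig(s)")
  filt <- filter_scaftigs(index, genes, min_length = min_scaftig_len)
  index <- filt$index
  genes <- filt$genes

  flanks <- extract_flank_coordinates(genes, index)
  flanks <- trim_flanks(flanks, cap = flank_cap, min_len = flank_min)
  flanks <- extract_flank_sequences(flanks, index)

  proximons <- call_proximons(genes, max_igd_exclusive = max_igd)
  message(nrow(proximons), " proximon(s) covering ",
          sum(proximons$n_genes), " gene(s)")

  scan <- scan_flanks(flanks, backend = promoter_backend,
                      threshold = promoter_threshold, calls = promoters,
                      pwm = pwm, oracle_truth = oracle_truth)
  operons_igd <- call_operons_igd_promoter(proximons, scan, genes)
  operons_po <- call_operons_promoter_only(genes, scan)
  message(nrow(operons_igd$operons), " operon(s) [igd_promoter], ",
          nrow(operons_po$operons), " operon(s) [promoter_only], ",
          length(operons_igd$nonoperonic_genes), " non-operonic gene(s)")

  paths <- character(0)
  if (write_outputs) {
    paths <- write_tables(proximons = proximons, operons = operons_igd,
                          flanks = flanks, out_dir = out_dir, index = index)
    po_dir <- file.path(out_dir, "promoter_only")
    paths_po <- write_tables(operons = operons_po, out_dir = po_dir)
    names(paths_po) <- paste0("promoter_only_", names(paths_po))
    paths <- c(paths, paths_po)
    paths["manifest"] <- write_manifest(
      file.path(out_dir, "manifest.txt"),
      params = list(process = "op", gene_tool = gene_tool,
                    promoter_backend = promoter_backend,
                    promoter_threshold = promoter_threshold,
                    max_igd = max_igd, flank_cap = flank_cap,
                    flank_min = flank_min,
                    min_scaftig_len = min_scaftig_len),
      inputs = c(scaftigs = scaftigs, gff = gff,
                 if (is.character(promoters)) c(promoters = promoters),
                 if (is.character(oracle_truth)) c(oracle_truth = oracle_truth))
    )
  }
  list(genes = genes, index = index, flanks = flanks, proximons = proximons,
       scan = scan, operons_igd = operons_igd,
       operons_promoter_only = operons_po, paths = paths)
}

write_manifest <- function(path, params, inputs) {
  sums <- tools::md5sum(inputs)
  lines <- c(
    paste0("package=operonr ", as.character(utils::packageVersion("operonr"))),
    vapply(names(params), function(k) paste0(k, "=", params[[k]]), ""),
    vapply(seq_along(inputs),
           function(i) paste0("input.", names(inputs)[i], "=", inputs[i],
                              " md5=", sums[i]), "")
  )
  writeLines(lines, path)
  path
}

#' Assemble and gene-call raw reads, then predict operons ("ago" process)
#'
#' Orchestration-only entry point for the raw-reads route: shells out to an
#' external assembler (idba_ud) and gene caller (prodigal), then continues
#' exactly as [run_operon_pipeline()]. Neither external tool is
#' reimplemented or bundled; a missing binary is a clear error naming it.
#'
#' @param reads Path to the input reads (FASTA, as the assembler expects).
#' @param out_dir Output directory.
#' @param assembler,gene_caller Names of the external binaries to invoke.
#' @param ... Passed on to [run_operon_pipeline()] (`gene_tool` defaults to
#'   `"prodigal"` to match the gene caller).
#' @return As [run_operon_pipeline()].
#' @export
run_ago_pipeline <- function(reads, out_dir, assembler = "idba_ud",
                             gene_caller = "prodigal", ...) {
  for (bin in c(assembler, gene_caller)) {
    if (Sys.which(bin) == "") {
      stop("external binary '", bin, "' not found on PATH; the ago process ",
           "only orchestrates external assembly/gene prediction")
    }
  }
  asm_dir <- file.path(out_dir, "assembly")
  dir.create(asm_dir, recursive = TRUE, showWarnings = FALSE)
  status <- system2(assembler, c("-r", shQuote(reads), "-o", shQuote(asm_dir)))
  if (status != 0L) stop(assembler, " exited with status ", status)
  scaftigs <- file.path(asm_dir, "scaffold.fa")
  if (!file.exists(scaftigs)) scaftigs <- file.path(asm_dir, "contig.fa")
  gff <- file.path(out_dir, "genes.gff")
  status <- system2(gene_caller, c("-i", shQuote(scaftigs), "-f", "gff",
                                   "-o", shQuote(gff), "-p", "meta"))
  if (status != 0L) stop(gene_caller, " exited with status ", status)
  run_operon_pipeline(scaftigs = scaftigs, gff = gff, gene_tool = "prodigal",
                      out_dir = out_dir, ...)
}
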