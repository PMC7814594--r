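#' Pair-level evaluation of predicted operons against a reference
#'
#' Scores a prediction over the universe of all adjacent co-directional
#' same-scaftig gene pairs (consecutive genes in genomic order sharing a
#' strand). A pair is positive in the reference when both genes belong to
#' the same reference operon, and positive in the prediction when both genes
#' belong to the same predicted operon; true/false positives and negatives
#' are counted accordingly. The units of sensitivity, specificity and
#' accuracy therefore are gene pairs, the standard convention in operon
#' benchmarking; numbers are comparable across tools only under the same
#' convention.
#'
#' @param predicted An `operon_calls` object or operon data.frame with a
#'   `gene_ids` list column.
#' @param reference A `reference_operons` object.
#' @param genes Gene table sorted by `(scaftig_id, start)` defining the
#'   pair universe.
#' @return An object of class `eval_report`: counts `tp`, `fp`, `tn`, `fn`,
#'   metrics `sensitivity`, `specificity`, `accuracy` (`NA` when the
#'   denominator is empty), `n_pairs`, and the per-pair table `pairs`.
#' @export
evaluate_pairs <- function(predicted, reference, genes) {
  assert_sorted_genes(genes)
  if (inherits(predicted, "operon_calls")) predicted <- predicted$operons
  stopifnot(inherits(reference, "reference_operons"))

  pred_sizes <- lengths(predicted$gene_ids)
  pred_map <- stats::setNames(rep(predicted$operon_id, pred_sizes),
                              unlist(predicted$gene_ids))
  ref_map <- reference$gene_to_operon

  n <- nrow(genes)
  same_pair <- if (n > 1L) {
    genes$scaftig_id[-1L] == genes$scaftig_id[-n] &
      genes$strand[-1L] == genes$strand[-n]
  } else {
    logical(0)
  }
  i <- which(same_pair)
  pairs <- data.frame(
    gene_a = genes$gene_id[i], gene_b = genes$gene_id[i + 1L],
    stringsAsFactors = FALSE
  )
  in_same <- function(map, a, b) {
    oa <- map[a]; ob <- map[b]
    !is.na(oa) & !is.na(ob) & oa == ob
  }
  pairs$ref_positive <- in_same(ref_map, pairs$gene_a, pairs$gene_b)
  pairs$pred_positive <- in_same(pred_map, pairs$gene_a, pairs$gene_b)

  tp <- sum(pairs$ref_positive & pairs$pred_positive)
  fp <- sum(!pairs$ref_positive & pairs$pred_positive)
  fn <- sum(pairs$ref_positive & !pairs$pred_positive)
  tn <- sum(!pairs$ref_positive & !pairs$pred_positive)
  safe_div <- function(num, den) if (den > 0L) num / den else NA_real_
  if (nrow(pairs) == 0L) {
    warning("no adjacent co-directional gene pairs: metrics undefined",
            call. = FALSE)
  }
  rep <- list(
    tp = tp, fp = fp, tn = tn, fn = fn, n_pairs = nrow(pairs),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, tp + fp + tn + fn),
    pairs = pairs
  )
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report over", x$n_pairs, "adjacent co-directional gene pairs\n")
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity=%.3f specificity=%.3f accuracy=%.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Classify predicted operons into the six-way configuration taxonomy
#'
#' Labels every predicted operon by how its gene set S relates to the
#' reference operons: `novel` when S shares less than half of its genes
#' with its best-matching reference operon (including no overlap at all);
#' `perfect_match` when S equals one reference operon exactly; `bridge1`
#' when S intersects two or more reference operons; `superset` when S
#' properly contains its single matched reference operon; `subset`
#' otherwise (S properly contained in, or staggered against, one reference
#' operon — boundary-shifted single-reference matches are grouped here,
#' since a subset formation reflects a differing transcription unit
#' boundary). Precedence is applied in that order, so every operon gets
#' exactly one label. The complementary reference-side condition — one
#' reference operon split over two or more predictions (`bridge-2`) — is a
#' property of the reference operon, and is reported as a separate table
#' rather than as a predicted-operon label.
#'
#' @param predicted An `operon_calls` object or operon data.frame.
#' @param reference A `reference_operons` object.
#' @return An object of class `configuration_report`: list with `labels`
#'   (data.frame `operon_id`, `label`, `matched_reference_ids` joined by
#'   `;`) and `bridge2` (data.frame `reference_id`, `predicted_ids`).
#' @export
classify_configurations <- function(predicted, reference) {
  if (inherits(predicted, "operon_calls")) predicted <- predicted$operons
  stopifnot(inherits(reference, "reference_operons"))
  ref_sets <- reference$operons$gene_ids
  ref_ids <- reference$operons$operon_id

  n <- nrow(predicted)
  label <- character(n)
  matched <- character(n)
  for (i in seq_len(n)) {
    s <- predicted$gene_ids[[i]]
    ov <- vapply(ref_sets, function(r) length(intersect(s, r)), 0L)
    inter <- which(ov > 0L)
    frac <- if (length(inter) > 0L) max(ov) / length(s) else 0
    matched[i] <- paste(ref_ids[inter], collapse = ";")
    if (frac < 0.5) {
      label[i] <- "novel"
    } else if (any(vapply(ref_sets[inter],
                          function(r) setequal(s, r), TRUE))) {
      label[i] <- "perfect_match"
    } else if (length(inter) >= 2L) {
      label[i] <- "bridge1"
    } else {
      r <- ref_sets[[inter]]
      label[i] <- if (all(r %in% s)) "superset" else "subset"
    }
  }
  labels <- data.frame(operon_id = predicted$operon_id, label = label,
                       matched_reference_ids = matched,
                       stringsAsFactors = FALSE)

  # reference-side bridge-2: one reference operon split across >= 2 predictions
  b2 <- list()
  for (j in seq_along(ref_ids)) {
    r <- ref_sets[[j]]
    hits <- predicted$operon_id[vapply(predicted$gene_ids,
                                       function(s) length(intersect(s, r)) > 0L,
                                       TRUE)]
    if (length(hits) >= 2L) {
      b2[[length(b2) + 1L]] <- data.frame(
        reference_id = ref_ids[j],
        predicted_ids = paste(hits, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  bridge2 <- if (length(b2) > 0L) do.call(rbind, b2) else
    data.frame(reference_id = character(0), predicted_ids = character(0),
               stringsAsFactors = FALSE)
  res <- list(labels = labels, bridge2 = bridge2)
  class(res) <- "configuration_report"
  res
}

#' @export
print.configuration_report <- function(x, ...) {
  cat("configuration_report:", nrow(x$labels), "predicted operon(s)\n")
  if (nrow(x$labels) > 0L) print(table(x$labels$label))
  cat(nrow(x$bridge2), "reference operon(s) in bridge-2 configuration\n")
  invisible(x)
}

#' Write evaluation outputs as TSV
#'
#' @param report An `eval_report`.
#' @param configurations A `configuration_report` (optional).
#' @param out_dir Output directory.
#' @return Named character vector of written paths.
#' @export
write_eval_tables <- function(report, configurations = NULL, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  p <- file.path(out_dir, "eval_report.tsv")
  utils::write.table(
    data.frame(tp = report$tp, fp = report$fp, tn = report$tn, fn = report$fn,
               n_pairs = report$n_pairs, sensitivity = report$sensitivity,
               specificity = report$specificity, accuracy = report$accuracy),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["eval_report"] <- p
  if (!is.null(configurations)) {
    p2 <- file.path(out_dir, "configurations.tsv")
    utils::write.table(configurations$labels, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["configurations"] <- p2
    p3 <- file.path(out_dir, "bridge2.tsv")
    utils::write.table(configurations$bridge2, p3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["bridge2"] <- p3
  }
  paths
}
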