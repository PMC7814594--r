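#' Construct a sigma70-style promoter position weight matrix model
#'
#' A two-box PWM model of a bacterial sigma70 promoter: a -35 box matrix, a
#' -10 box matrix (both 4 x 6, rows A/C/G/T, columns base probabilities
#' summing to 1), and an allowed spacer length range between the boxes.
#' This scorer is a self-contained surrogate backend for promoter calling;
#' it is not a reimplementation of any external neural-network predictor,
#' and output files always record which backend produced a call.
#'
#' @param minus35,minus10 4 x 6 numeric matrices with rownames
#'   `c("A","C","G","T")`; each column must sum to 1 (within 1e-9).
#' @param spacer_range Integer pair, min/max spacer length in bp between the
#'   -35 and -10 boxes.
#' @return An object of class `pwm_model`.
#' @export
pwm_model <- function(minus35, minus10, spacer_range = c(15L, 19L)) {
  for (m in list(minus35, minus10)) {
    stopifnot(is.matrix(m), nrow(m) == 4L, ncol(m) == 6L,
              identical(rownames(m), c("A", "C", "G", "T")))
    if (any(abs(colSums(m) - 1) > 1e-9)) {
      stop("each PWM column must sum to 1")
    }
  }
  stopifnot(length(spacer_range) == 2L, spacer_range[1L] <= spacer_range[2L],
            spacer_range[1L] >= 0L)
  model <- list(minus35 = minus35, minus10 = minus10,
                spacer_range = as.integer(spacer_range))
  class(model) <- "pwm_model"
  model
}

# probability matrix concentrated on a consensus hexamer
consensus_matrix <- function(consensus, consensus_prob = 0.85) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(consensus, "")[[1L]]
  stopifnot(length(chars) == 6L, all(chars %in% bases))
  m <- matrix((1 - consensus_prob) / 3, nrow = 4L, ncol = 6L,
              dimnames = list(bases, NULL))
  for (j in seq_len(6L)) m[chars[j], j] <- consensus_prob
  m
}

#' Default sigma70 PWM model (TTGACA -35, TATAAT -10, 15-19 bp spacer)
#'
#' @param consensus_prob Probability mass on the consensus base in each
#'   column (default 0.85, the remainder spread evenly).
#' @return A `pwm_model`.
#' @export
default_pwm_model <- function(consensus_prob = 0.85) {
  pwm_model(consensus_matrix("TTGACA", consensus_prob),
            consensus_matrix("TATAAT", consensus_prob))
}

#' Score one sequence with a two-box PWM model
#'
#' Slides the -35 box / spacer / -10 box arrangement over the sequence and
#' returns the best-scoring window. The raw score is the summed log-odds of
#' the 12 box positions against a uniform background, rescaled to [0, 1] so
#' that the model consensus scores exactly 1 and the worst possible
#' arrangement scores 0. Characters outside A/C/G/T contribute log-odds 0.
#'
#' @param model A `pwm_model`.
#' @param sequence Nucleotide string (oriented 5'->3' toward the gene).
#' @return List with `score` (0 if the sequence is shorter than the minimal
#'   window), `minus10_end` (1-based position of the last -10 box base in
#'   the sequence, `NA` if unscorable) and `minus35_start`.
#' @export
score_pwm <- function(model, sequence) {
  lo35 <- log(model$minus35 / 0.25)
  lo10 <- log(model$minus10 / 0.25)
  lo_max <- sum(apply(lo35, 2L, max)) + sum(apply(lo10, 2L, max))
  lo_min <- sum(apply(lo35, 2L, min)) + sum(apply(lo10, 2L, min))
  n <- nchar(sequence)
  min_win <- 12L + model$spacer_range[1L]
  if (is.na(sequence) || n < min_win) {
    return(list(score = 0, minus10_end = NA_integer_, minus35_start = NA_integer_))
  }
  idx <- match(strsplit(toupper(sequence), "")[[1L]], c("A", "C", "G", "T"))
  # per-position hexamer scores for each matrix (NA characters score 0)
  hex_score <- function(lo) {
    last <- n - 5L
    s <- numeric(last)
    for (k in 0:5) {
      v <- lo[, k + 1L][idx[(1L + k):(last + k)]]
      v[is.na(v)] <- 0
      s <- s + v
    }
    s
  }
  s35 <- hex_score(lo35)
  s10 <- hex_score(lo10)
  best <- -Inf
  best_i <- NA_integer_
  best_j <- NA_integer_
  for (sp in model$spacer_range[1L]:model$spacer_range[2L]) {
    offset <- 6L + sp  # -10 box starts this many bases after the -35 start
    imax <- n - 11L - sp
    if (imax < 1L) next
    tot <- s35[seq_len(imax)] + s10[seq_len(imax) + offset]
    i <- which.max(tot)
    if (tot[i] > best) {
      best <- tot[i]
      best_i <- i
      best_j <- i + offset + 5L
    }
  }
  if (!is.finite(best)) {
    return(list(score = 0, minus10_end = NA_integer_, minus35_start = NA_integer_))
  }
  list(score = unname((best - lo_min) / (lo_max - lo_min)),
       minus10_end = as.integer(unname(best_j)),
       minus35_start = as.integer(unname(best_i)))
}

#' Scan flank regions for promoters with a pluggable backend
#'
#' Assigns promoter evidence to the upstream and downstream flank of every
#' gene through one of three backends:
#' \describe{
#'   \item{nnpp_file}{calls parsed from an external promoter predictor's
#'     tabular output ([parse_promoter_file()]) are attributed to a flank by
#'     strict interval containment of the call position, requiring the same
#'     scaftig and the gene's strand. One call landing in the shared
#'     intergenic span between two co-directional genes counts as the
#'     downstream hit of the left gene and the upstream hit of the right
#'     gene at the same time.}
#'   \item{pwm}{each eligible flank's oriented sequence is scored with a
#'     two-box sigma70 PWM ([score_pwm()]); the best window per region is a
#'     hit when its normalized score reaches the threshold.}
#'   \item{oracle}{hits are read directly from a planted-truth table
#'     (columns `gene_id`, `side`, optionally `scaftig_id`, `strand`,
#'     `position`, `score`) as emitted by the synthetic genome generator.}
#' }
#' Only regions with status `ok` or `trimmed` are eligible; short-tagged
#' regions never receive a hit. When several calls land in one region the
#' best score wins, ties going to the gene-proximal position.
#'
#' @param regions Trimmed flank data.frame (with sequences for the pwm
#'   backend).
#' @param backend One of `"nnpp_file"`, `"pwm"`, `"oracle"`.
#' @param threshold Minimum score in [0, 1] for a call to count (default 0.8).
#' @param calls Promoter-call data.frame or file path (nnpp_file backend).
#' @param pwm A `pwm_model` (pwm backend; default [default_pwm_model()]).
#' @param oracle_truth Data.frame or TSV path with planted promoter truth
#'   (oracle backend).
#' @return An object of class `promoter_scan`: list with `backend`,
#'   `threshold`, `hits` (data.frame `gene_id`, `side`, `position`,
#'   `score`), and named logical maps `upstream_hit` / `downstream_hit`
#'   over every gene present in `regions`.
#' @export
scan_flanks <- function(regions, backend = c("nnpp_file", "pwm", "oracle"),
                        threshold = 0.8, calls = NULL, pwm = NULL,
                        oracle_truth = NULL) {
  backend <- match.arg(backend)
  stopifnot(threshold >= 0, threshold <= 1)
  eligible <- regions[regions$status %in% c("ok", "trimmed"), , drop = FALSE]
  hits <- data.frame(gene_id = character(0), side = character(0),
                     position = integer(0), score = numeric(0),
                     stringsAsFactors = FALSE)

  if (backend == "nnpp_file") {
    if (is.null(calls)) stop("nnpp_file backend requires a promoter-call table or file")
    if (is.character(calls)) calls <- parse_promoter_file(calls)
    calls <- calls[calls$score >= threshold, , drop = FALSE]
    if (nrow(eligible) > 0L && nrow(calls) > 0L) {
      hit_rows <- vector("list", nrow(eligible))
      for (r in seq_len(nrow(eligible))) {
        reg <- eligible[r, ]
        sel <- calls$scaftig_id == reg$scaftig_id &
          calls$strand == reg$strand &
          calls$position >= reg$start & calls$position <= reg$end
        if (!any(sel)) next
        cand <- calls[sel, , drop = FALSE]
        # gene-proximal coordinate of the region resolves score ties
        proximal <- if ((reg$side == "upstream") == (reg$strand == "+"))
          reg$end else reg$start
        cand <- cand[order(-cand$score, abs(cand$position - proximal)), ,
                     drop = FALSE]
        hit_rows[[r]] <- data.frame(gene_id = reg$gene_id, side = reg$side,
                                    position = cand$position[1L],
                                    score = cand$score[1L],
                                    stringsAsFactors = FALSE)
      }
      hit_rows <- hit_rows[!vapply(hit_rows, is.null, TRUE)]
      if (length(hit_rows) > 0L) hits <- do.call(rbind, hit_rows)
    }
  } else if (backend == "pwm") {
    if (is.null(pwm)) pwm <- default_pwm_model()
    if (nrow(eligible) > 0L && anyNA(eligible$sequence)) {
      stop("pwm backend requires flank sequences; ",
           "run extract_flank_sequences() first")
    }
    hit_rows <- vector("list", nrow(eligible))
    for (r in seq_len(nrow(eligible))) {
      reg <- eligible[r, ]
      sc <- score_pwm(pwm, reg$sequence)
      if (sc$score < threshold) next
      # map the -10 end back from oriented-sequence to scaftig coordinates
      pos <- if (reg$strand == "+") reg$start + sc$minus10_end - 1L
             else reg$end - sc$minus10_end + 1L
      hit_rows[[r]] <- data.frame(gene_id = reg$gene_id, side = reg$side,
                                  position = pos, score = sc$score,
                                  stringsAsFactors = FALSE)
    }
    hit_rows <- hit_rows[!vapply(hit_rows, is.null, TRUE)]
    if (length(hit_rows) > 0L) hits <- do.call(rbind, hit_rows)
  } else { # oracle
    if (is.null(oracle_truth)) stop("oracle backend requires a truth table or file")
    if (is.character(oracle_truth)) {
      oracle_truth <- utils::read.delim(oracle_truth, header = TRUE,
                                        comment.char = "#",
                                        stringsAsFactors = FALSE)
    }
    if (!all(c("gene_id", "side") %in% names(oracle_truth))) {
      stop("oracle truth needs columns gene_id and side")
    }
    if (nrow(oracle_truth) > 0L && nrow(eligible) > 0L) {
      key_elig <- paste(eligible$gene_id, eligible$side)
      keep <- paste(oracle_truth$gene_id, oracle_truth$side) %in% key_elig
      tr <- oracle_truth[keep, , drop = FALSE]
      if (nrow(tr) > 0L) {
        hits <- data.frame(
          gene_id = tr$gene_id, side = tr$side,
          position = if ("position" %in% names(tr)) as.integer(tr$position)
                     else NA_integer_,
          score = if ("score" %in% names(tr)) as.numeric(tr$score) else 1,
          stringsAsFactors = FALSE
        )
        hits <- hits[hits$score >= threshold, , drop = FALSE]
      }
    }
  }

  all_genes <- unique(regions$gene_id)
  up <- stats::setNames(rep(FALSE, length(all_genes)), all_genes)
  dn <- up
  up[hits$gene_id[hits$side == "upstream"]] <- TRUE
  dn[hits$gene_id[hits$side == "downstream"]] <- TRUE
  scan <- list(backend = backend, threshold = threshold, hits = hits,
               upstream_hit = up, downstream_hit = dn)
  class(scan) <- "promoter_scan"
  scan
}

#' @export
print.promoter_scan <- function(x, ...) {
  cat("promoter_scan:", x$backend, "backend, threshold", x$threshold, "-",
      sum(x$upstream_hit), "upstream and", sum(x$downstream_hit),
      "downstream hit(s) over", length(x$upstream_hit), "gene(s)\n")
  invisible(x)
}

# best (position, score) of a gene's hit on one side, NA when absent
hit_info <- function(scan, gene_id, side) {
  h <- scan$hits[scan$hits$gene_id == gene_id & scan$hits$side == side, ,
                 drop = FALSE]
  if (nrow(h) == 0L) list(position = NA_integer_, score = NA_real_)
  else list(position = h$position[1L], score = h$score[1L])
}
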