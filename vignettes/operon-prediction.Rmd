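---
title: "Operon prediction from intergenic distance and promoter evidence"
author: "operonr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operon prediction from intergenic distance and promoter evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonr)
```

## The problem and the model

Bacterial genes are commonly transcribed in operons: clusters of two or
more co-directional genes controlled as one transcription unit, with a
promoter upstream of the first gene. Predicting operons on assembled
metagenomic scaftigs is harder than on finished genomes: the sequence is
fragmentary, the organisms are mixed and mostly unknown, and no single
intergenic-distance cutoff fits every taxon.

`operonr` therefore predicts operons in two stages.

**Stage 1 — proximons.** Genes on one scaftig are walked in genomic order
and chained while two conditions hold: the strand is unchanged, and the
intergenic distance

$$\mathrm{IGD}(G_1, G_2) = \big(\mathrm{start}(G_2) - \mathrm{end}(G_1)\big) + 1$$

is strictly below a permissive threshold (default 601 bp, i.e. IGD
$\le$ 600 joins). Note the convention: abutting genes have IGD 2, and
overlapping genes have IGD $\le$ 0 — overlaps always cluster, since gene
overlap is itself strong evidence of co-transcription. Chains of two or
more genes are *proximons*: deliberately over-inclusive clusters with no
transcription unit boundary yet. The threshold is exposed as a parameter
(`max_igd`) precisely because intergenic spacing varies widely across
taxa; in a metagenome a permissive value ensures operonic genes are not
split apart, at the cost of including non-operonic genes that the next
stage removes.

**Stage 2 — transcription unit boundaries.** Promoter evidence refines
each proximon. Genes are walked in transcription order (for minus-strand
clusters, decreasing genomic coordinate). A unit *opens* at a gene with
an upstream promoter hit; the running unit *closes* after gene $i$ when
gene $i$ has a downstream promoter hit, when gene $i+1$ has an upstream
hit (one promoter in the shared intergenic span simultaneously ends one
unit and starts the next), or when the cluster ends. Absence of a hit
never splits: only evidence does. Units of $\ge$ 2 genes are the
predicted operons; genes that fall outside any unit are reported in a
non-operonic side table rather than silently dropped. The last unit of a
cluster may lack a downstream promoter — scaftig edges truncate operons —
and is recorded with an absent downstream boundary.

A second mode, `promoter_only`, applies the same boundary walk to maximal
co-directional runs with no distance constraint at all, so arbitrarily
distant co-directional genes can share an operon if no promoter
intervenes. Contrasting the two modes shows how much structure the
distance prior contributes.

## Flank regions

Promoters are searched in the *upstream flank* of each gene: the
intergenic span between the gene's transcriptional 5' end and the nearest
coding base of any neighboring gene (regardless of the neighbor's
strand), or the scaftig edge. Downstream flanks are symmetric at the 3'
end. Two rules shape the flanks:

* flanks longer than 700 bp are trimmed to the 700 bp nearest the gene.
  Trimming keeps the gene-proximal end because promoter signal
  concentrates near the transcription start; the distal cut loses the
  least information. The cap is configurable (`flank_cap`).
* flanks shorter than 15 bp are tagged `short_ups`/`short_dss` and
  excluded from promoter scanning — no promoter signature fits in fewer
  than 15 bases. Abutting or overlapping neighbors produce zero-length
  flanks, which fall under the same rule.

Minus-strand flank sequences are reverse-complemented so every sequence
reads 5'→3' on its gene's strand.

## Promoter backends

Promoter calling is pluggable, and output always records which backend
produced a call:

* **nnpp_file** — parses the tabular output of an external promoter
  predictor (such as the NNPP neural network, which this package
  interfaces but does not reimplement). A call is attributed to a flank
  by strict interval containment of its position on the matching strand;
  a call in the span shared by two co-directional genes counts as the
  left gene's downstream hit and the right gene's upstream hit at once.
  When several calls land in one flank the best score wins, ties going
  to the gene-proximal position.
* **pwm** — a self-contained two-box sigma70 position weight matrix
  scorer (TTGACA -35 box, 15–19 bp spacer, TATAAT -10 box by default).
  Scores are summed log-odds against a uniform background, rescaled to
  $[0, 1]$ so the model consensus scores exactly 1. This scorer exists so
  the whole pipeline can run with no external tool; it is a simple motif
  model, not a substitute claim about any neural network's accuracy.
* **oracle** — reads planted-truth hits directly from the synthetic
  generator's table; used for end-to-end validation where promoter
  detection is by construction perfect.

The score threshold defaults to 0.8 on the $[0,1]$ scale. It is a free
parameter (`promoter_threshold`); raising it can only remove hits (a
property the test suite checks). Scanning is gene-oriented: flanks are
scored on the gene's strand only.

## Scaftig filtering

Scaftigs of length $\le$ 500 bp are removed before prediction, together
with the genes on them (`min_scaftig_len`, boundary inclusive). Such
fragments are too short to carry a gene pair plus usable flanks.

## The synthetic genome generator

`synthetic_spec()` / `generate_synthetic_genome()` build fully
ground-truthed test genomes: scaftigs of random background sequence with
planted operons, each carrying the sigma70 consensus motif upstream of
its transcriptionally first gene (gene-proximal motif end 40 bp from the
5' start by default), plus non-operonic decoy genes between units so that
negative gene pairs exist and specificity is actually exercised.

Default conditions: operon sizes drawn from a distribution heavy on 2–4
genes (50/20/15/10/5% for sizes 2–6), echoing the predominance of binary
operons in microbial genomes; intra-operon gaps of 20–150 bp (well below
the clustering threshold); inter-unit gaps of 700–1200 bp (above it, so
units stay separable by distance); gene lengths 300–900 bp; strand
switching between units with probability 0.5; uniform base composition.
A *gap* of $g$ means the next feature starts $g$ bp after the previous
one ends, so a planted gap of $g$ corresponds to IGD $g+1$ — documented
to prevent off-by-one mismatches between truth and prediction. The
default scaftig length range (40–50 kb for 4 operons per scaftig) is
chosen so that even a worst-case draw of unit sizes packs; genuinely
infeasible specifications fail with an explicit packing error rather
than silently truncating.

What the generator does *not* emulate: read-level sequencing error,
assembly chimerism, gene-caller mistakes (truth coordinates are exact),
promoter-motif degeneracy, terminators, and overlapping genes. Passing
the end-to-end recovery tests therefore demonstrates the correctness of
the clustering and boundary logic under clean inputs, not the field
accuracy of promoter detection on real metagenomes.

## Evaluation conventions

Sensitivity, specificity and accuracy are computed over the universe of
**adjacent co-directional same-scaftig gene pairs** — the standard unit
in operon benchmarking. A pair is positive in the reference (or the
prediction) when both genes share a reference (or predicted) operon.
Metrics are reported as `NA`, not 0, when a denominator is empty.
Numbers are comparable across tools only under the same pair convention,
which is why the convention is stated prominently here and in the
function documentation.

Each predicted operon also receives one configuration label, applied in
this precedence order: `novel` (less than half of its genes shared with
its best-matching reference operon), `perfect_match` (set equality),
`bridge1` (intersects $\ge$ 2 reference operons), `superset` (properly
contains its one matched reference operon), `subset` (otherwise). The
`subset` bucket includes boundary-shifted single-reference matches,
since a staggered overlap reflects a differing transcription unit
boundary on one reference operon. The complementary reference-side
condition — one reference operon split across $\ge$ 2 predictions
(bridge-2) — is a property of the reference operon and is reported as a
separate table, not as a predicted-operon label. Overlap is computed on
gene identifiers, not coordinates.

## Worked example

```{r example}
td <- tempfile()
sim <- generate_synthetic_genome(synthetic_spec(seed = 7), td)
out <- run_operon_pipeline(
  scaftigs = sim$paths[["fasta"]], gff = sim$paths[["gff"]],
  gene_tool = "prodigal", out_dir = file.path(td, "run"),
  promoter_backend = "oracle", oracle_truth = sim$paths[["promoters"]]
)
out$operons_igd

ref <- as_reference_operons(sim$truth$operons$operon_id,
                            lapply(sim$truth$operons$gene_ids, as.character))
evaluate_pairs(out$operons_igd, ref, out$genes)
```

## Numerical and design choices

* Coordinates are GFF-style 1-based inclusive everywhere; half-open
  arithmetic never appears, and sequence slicing uses the same inclusive
  bounds directly.
* The intergenic-distance threshold is strict (`IGD < 601`); the
  boundary case IGD = 601 never joins, IGD = 600 always does.
* Negative IGDs are kept as-is, never clamped; nested genes chain like
  any other co-directional neighbors.
* Gene identifiers come from `ID=` (prodigal dialect) or `gene_id`
  (metagenemark dialect); when absent, a deterministic
  `<scaftig>_<ordinal>` is synthesized. Duplicate scaftig identifiers
  are fatal — renaming them silently would corrupt every gene-to-scaftig
  join.
* Malformed gene or promoter records are dropped per record, collected,
  and reported; they never abort a run.
* All outputs are deterministic: identical inputs and configuration give
  byte-identical files, and every run writes a manifest with its
  parameters and input checksums.

## Problem sizes used in the shipped checks

The package's own verification runs at desk scale: randomized layouts of
up to 20 genes checked against brute-force enumerators (500 instances),
1,000 random classification instances against an independent predicate
classifier, and 100 seeded synthetic genomes (1,000 planted operons
total) for end-to-end recovery. These sizes keep the full suite under a
minute of compute while still exercising every branch of the clustering
and boundary logic.

## Limitations

* Operons split across two scaftigs cannot be rejoined; each fragment is
  predicted independently, which biases real metagenomic predictions
  toward subsets of the true operon.
* No terminator model: boundaries rest on promoters alone.
* The PWM backend models only the canonical sigma70 two-box promoter;
  alternative sigma factors and degenerate promoters are out of reach by
  design — supply an external predictor's calls via `nnpp_file` for
  realistic promoter detection.
* Evaluation matches genes by identifier, so prediction and reference
  must share a gene-calling run.
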