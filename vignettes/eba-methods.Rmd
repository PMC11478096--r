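---
title: "Embedding-based alignment for superfamily classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-based alignment for superfamily classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embalign)
```

## The model

`embalign` treats a protein of length $l$ as a matrix
$e \in \mathbb{R}^{l \times D}$ of per-residue embeddings from a protein
language model. The core assumption is that contextual embeddings of
homologous residues are closer to each other than to the background of
unrelated residue pairs, even when sequence identity is far below the
twilight zone — so an alignment that maximises embedding closeness can
recognise remote homologs that sequence alignment misses.

For a pair of proteins the pipeline is:

1. **Distance matrix.** $D_{ij} = \lVert e^1_i - e^2_j \rVert_2$, all
   residue pairs, an $l_1 \times l_2$ matrix.
2. **Signal enhancement.** Each pair is contrasted with its background:
   $$S_{ij} = \tfrac{1}{2}\left(\bar D_{i\cdot} + \bar D_{\cdot j}\right) - D_{ij}.$$
   This converts distances to similarities for a maximising dynamic
   program while normalising away the overall distance level of the two
   proteins. The consequences are deliberate and worth knowing:
   a *constant* distance matrix enhances to exactly zero — the method
   scores the *pattern* of relative closeness, not absolute proximity in
   embedding space. For a square matrix with constant row and column
   means the enhanced scores sum to zero. A plain negation mode
   ($S = -D$, `enhance = FALSE`) is kept for ablation.
3. **Global alignment.** Needleman–Wunsch with affine gaps (Gotoh
   three-state recursion) over $S$. Terminal gaps are penalised: the
   length-normalised score below is only meaningful if unaligned
   overhangs cost score.
4. **Scores.** With total alignment score $s_{\mathrm{align}}$,
   $\mathrm{EBA}_{\min} = s_{\mathrm{align}} / \max(l_1, l_2)$ and
   $\mathrm{EBA}_{\max} = s_{\mathrm{align}} / \min(l_1, l_2)$.
   $\mathrm{EBA}_{\max}$ is high whenever the shorter protein is
   contained in the longer; $\mathrm{EBA}_{\min}$ additionally demands
   that the *whole* longer protein aligns. Classification uses
   $\mathrm{EBA}_{\min}$ because annotation transfer presupposes
   conservation of the full structural template. The min/max naming
   tracks the normalising length, so the stated order
   $\mathrm{EBA}_{\min} \le \mathrm{EBA}_{\max}$ holds for non-negative
   total scores.
5. **Nearest-bait transfer and triage.** A query takes the class of the
   reference protein ("bait") with the highest $\mathrm{EBA}_{\min}$.
   Each class's reference length range (RLR) is the closed interval
   spanned by its bait lengths; the query is called `within`, `below`
   or `above` that interval. Length conservation is used as a proxy for
   fold conservation: baits are structure-validated, so a query far
   outside the bait length range cannot adopt the same template even if
   its domains/motifs match.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `gap_open` | −1.0 | On the enhanced-score scale. Gap of length $k$ costs `gap_open` + $(k-1)$·`gap_extend`; switching gap sides re-opens. |
| `gap_extend` | −0.1 | Mild extension keeps long indels affordable where the background supports them. |
| `enhance` | `TRUE` | Set `FALSE` for the negated-distance ablation. |
| redundancy `threshold` | 95 (%) | Strictly-greater-than removal of queries nearly identical to the reference. |
| identity scoring | BLOSUM62, open −11 / extend −1 | Standard convention for the *sequence*-level identity used in curation and reporting; configurable and recorded in filter reports. |

The gap penalties are a genuinely open choice — nothing in the scoring
model pins them — so they are prominent, configurable arguments. The
defaults were fixed once against the scale of enhanced scores produced
by the synthetic generator's default geometry (enhanced match scores of
order 1) and are not tuned per dataset. Results intended for comparison
with other embedding-alignment implementations should state all three
alignment parameters and the enhancement variant; the enhancement
formula above is the package's fixed, versioned definition.

Two further conventions are pinned to make reported numbers exact:
overall agreement of a labeled run is rounded to one decimal, and
length-region fractions to integer percent. "Agreement" means exact
string equality of predicted and expected class labels.

## Numerical and tie-breaking choices

- Scores accumulate in double precision regardless of storage precision.
- DP tie-breaks are deterministic: match > gap consuming the first
  protein > gap consuming the second; traceback recomputes predecessor
  maxima instead of subtracting floats, so tie detection is exact.
- Across baits, ties on $\mathrm{EBA}_{\min}$ resolve by higher path
  identity to the query, then lexicographically smaller bait id.
- Self-hits are excluded by id equality only; a bait sequence-identical
  to the query under a different id is a legitimate neighbour.
- Degenerate inputs error early with the offending id in the message:
  empty sequences, empty matrices, embedding/sequence length
  mismatches, mixed embedding dimensions in one store, classes with no
  baits (no length range), identity ranges for single-bait classes.
- Alignment paths are 1-based with `NA` on the gapped side, the natural
  indexing for R consumers.

## The synthetic generator

Real per-residue embeddings are expensive (the production-scale models
run on GPUs), so the package ships a generator that emulates exactly the
geometry the classifier relies on:

- **Class centroids** drawn in $\mathbb{R}^D$ and rescaled so the
  closest pair sits at separation $\Delta$ (default 6).
- **Class-level positional drift**: a low-frequency sinusoid along a
  fixed random direction, evaluated at *relative* sequence position and
  stretched over each protein's length, amplitude $\Delta/8$. Members
  of a class share the field. This is what survives signal enhancement:
  the background normalisation cancels the centroid offset, so
  within-class alignments are recognised by shared positional structure
  — the analogue of homologous residues having similar contexts. An
  early design made the drift per-protein with amplitude equal to the
  noise level; that collapses at zero noise (all matrices become
  constant and every pair ties at zero), which is both a degenerate
  benchmark and a poor model of contextual embeddings, and was replaced
  by the class-level field.
- **Residue noise**: i.i.d. Gaussian, $\sigma = \Delta/8$ by default.
- **Sequences** from class-specific residue frequency profiles; bait
  lengths uniform in each class's configured range; query lengths
  follow a within/below/above mix (default 0.6/0.2/0.2, out-of-range
  lengths up to 25 residues beyond the bounds).

The default benchmark configuration — $K = 5$ classes, $D = 32$,
$\sigma = \Delta/8$, 20 baits and 20 queries per class, class length
ranges (60–75), (90–105), (120–135), (150–165), (180–195) — was fixed
once, with the acceptance bar (≥95% recovery of within-range query
classes, 100% at $\sigma = 0$) recorded alongside it. These sizes keep a
full benchmark run (10,000 pairwise alignments) around a minute on one
CPU; they are the package's calibration conditions, not tuned knobs.

What the generator does *not* emulate: real pLM geometry (anisotropy,
token-frequency effects), insertions/deletions as evolutionary events
(out-of-range queries are fresh draws at different lengths, not edits of
a template), correlations between sequence and embedding (profiles and
centroids are drawn independently), or any structure inside classes
(subfamilies, phylogeny). Passing the benchmark therefore shows the
pipeline recovers class structure of this geometric kind; it is not
evidence about any particular real protein family.

## Reference-set fixture

The package carries the per-class metadata of a curated GST reference
set — 20 classes, 284 proteins, per-taxon counts and per-class
shortest/longest lengths — as a plain TSV, and a builder
(`gst_reference_fixture()`) that instantiates a synthetic reference set
matching that metadata exactly (bait lengths spread across each class
range with the endpoints attained, so derived length ranges reproduce
the metadata). Sequences and embeddings in the fixture are synthetic
stand-ins; real data flow through the same `load_reference_set()`
surface (FASTA + labels TSV + embedding store). Length ranges are
*closed* intervals: the published region bounds place the below-range
region ending exactly one residue under each class minimum.

The packaged count tables for the labeled testing comparison (15,061
proteins) and the unlabeled trial classification (64,207 proteins) feed
the reporting arithmetic; their summary quantities (99.3% agreement,
46% outside the length ranges; 41% within / 58% outside on the trial
set) are recomputed from the tables at run time by
`scripts/acceptance.R`, never stored as results.

## Embedding storage

Stores hold one `l × D` float matrix per protein id plus a provenance
`model_tag` and the common dimension. The on-disk container is a single
serialised file with bit-exact round trips and partial reads by id; a
plain-text one-TSV-per-protein exchange format (17 significant digits,
so doubles survive) serves small, reviewable fixtures. An adapter that
invokes a real language model can sit behind the same
`embed_sequence()` contract; nothing in the package requires one, and
the `model_tag` records which model and layer produced stored matrices.

## Reporting conventions

Labeled summaries triage each query against its *expected* class's
length range when expected labels exist (reproducing the layout of
published labeled comparisons) and against the predicted class
otherwise — an unlabeled run has nothing else to key on. Region counts
partition each class's queries, and summarising per-query records is
exactly equivalent to summarising the count table built from them
(tested property). No rejection rule is applied by default: every query
receives a class, and unlabeled summaries take their denominator from
the table's total row when one is present, so runs with an unclassified
remainder still reconcile to 100% within integer rounding.

## Known limitations

- The alignment is strictly global; fragment queries are penalised by
  design, and local/glocal modes are out of scope.
- $O(l_1 l_2)$ time and memory per pair with no banding; fine for
  protein-scale inputs, not for genome-scale ones.
- The enhancement definition here is this package's fixed formula
  implementing background normalisation; other implementations of the
  same idea may differ in detail, so cross-tool score comparisons
  require matching the formula and gap parameters.
- Classification is single-label nearest-neighbour: no calibrated
  probabilities, no rejection threshold by default (`--min-score` style
  cutoffs can be layered on top by filtering on `eba_min`).
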