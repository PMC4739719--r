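---
title: "Surveying local position effects of targeted mutations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying local position effects of targeted mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankfx)
```

## The problem

Targeted mouse knockouts insert several kilobases of exogenous DNA — a LacZ
reporter and a neo selection cassette with its heterologous promoter — into
a gene. Two allele geometries are in scope: gene-trap (**TRAP**) alleles,
where a splice-acceptor cassette sits in an intron 5′ of a critical exon,
and deletion (**DEL**) alleles, where the open reading frame from the
translational start to the 3′ UTR is excised. Beyond silencing the target,
the insertion can dysregulate *neighboring* genes: disrupting intragenic
regulatory elements, bringing the target's promoter elements closer to
downstream promoters, or driving read-through from the cassette promoter.
These local "position effects" confound any phenotype attributed to the
knocked-out gene.

`flankfx` implements a survey of such effects from bulk RNA-seq of
homozygous mutant (HOM) versus wild-type (WT) libraries: differential calls
per library pair, a strand-aware ±500 kb flanking-gene survey with spatial
topography, a genome-wide empirical null with chi-square comparisons, an
exon-pattern classifier that confirms targeting, and a rule engine scoring
likely disruption of regulatory elements. A synthetic-data module generates
cohorts with all the structure the analysis assumes so that every stage is
exercised and validated without any external download.

## Differential calls without replicates

The design pools biological replicates into one HOM library per mutant line
and tissue, compared against a shared WT control of the same tissue, so
each comparison has $n = 1$ per group. The only defensible dispersion
estimator then borrows strength across genes:

* **Normalization** is median-of-ratios: library size factor $s_j$ is the
  median over genes (nonzero in every library) of $k_{ij} / (\prod_j
  k_{ij})^{1/J}$. This is the DESeq-family convention and is cross-checked
  in the tests against `DESeq2::estimateSizeFactorsForMatrix`.
* **Dispersion** uses a method-of-moments estimate per gene from each
  HOM/WT pair of normalized counts, pooled across pairs. With $x_h =
  k_h/s_h$ and $x_w = k_w/s_w$, $\tfrac12(x_h - x_w)^2$ has expectation
  $\mu\bar c + \alpha\mu^2$ under a common pair mean (the $\bar c$ term
  carries the size factors), giving a raw $\hat\alpha_g$. Raw estimates are
  heavily right-skewed, so a robust fit through the *per-gene* values would
  be biased low (an anticonservative test); instead we average raw values
  (which may be negative) inside ~20 mean-expression bins — bin means stay
  mean-unbiased — and fit the trend $\alpha(\mu) = a_0 + a_1/\mu$ by
  weighted least squares. The fitted curve is floored at
  $\alpha_{\min} = 0.01$, a minimal biological coefficient of variation of
  10%; on Poisson data the fitted trend collapses to this floor.
* **The pair test** is exact and conditional: under the null the two
  libraries share the mean $\hat\mu = (k_h + k_w)/(s_h + s_w)$; conditional
  on the observed total $N = k_h + k_w$ the HOM count follows the
  normalized product of two negative-binomial densities with dispersion
  $\alpha(\hat\mu)$ from the trend, and the two-sided p-value doubles the
  smaller tail (observed point included in both tails, capped at 1).
  Directions use the study's criterion — unadjusted $p < 0.05$ — with
  Benjamini–Hochberg adjusted p-values carried per pair for completeness.
  A pseudocount of 0.5 keeps log2 ratios finite; it affects reporting only,
  never the test.

On null NB cohorts of ~5,000 genes the empirical type-I error of this
construction sits within three Monte-Carlo standard deviations of the
nominal 0.05 (the acceptance suite recomputes this).

## The flanking-gene survey

Distances are **centrum-to-centrum**: the centrum of a gene is
`floor((start + end) / 2)` (the floor is our convention; the midpoint's
rounding is otherwise arbitrary), and the distance from target to neighbor
is negated for minus-strand targets so that negative always means 5′ of the
target's transcription direction. The window is boundary-inclusive,
$|d| \le 500$ kb, and the targeted gene itself is never counted. miRNA gene
models are ordinary neighbors.

Aggregation follows the two units the survey reports: a *library* has an
effect when at least one neighbor is called up (down) in that pair; a
*target* has an effect when any of its libraries does (logical OR). The
topography bins dysregulated neighbors into 50-kb intervals tiling
[−500, +500) kb (half-open bins; a co-located centrum at $d = 0$ falls in
[0, 50); the inclusive window edge +500 folds into the last bin). Counting
deduplicates to unique (target, neighbor, direction) pairs across libraries
by default — a neighbor dysregulated in four tissues is one regional
observation, not four — with an `"instance"` toggle to count per-library
occurrences instead, since either convention is defensible and published
totals do not always say which was used.

One consequence of a *calibrated* 5% test is worth stating plainly: with
~25 genes per window and four library pairs per target, the expected number
of false-positive neighbor calls per target is already above one, so the
per-target OR statistic saturates — nearly every target shows "an effect"
on synthetic cohorts even though the planted frequency is far lower. In the
original screen this statistic was far from saturation, which implies its
no-replicate calls were effectively much more conservative than their
nominal level. This is exactly why the survey separates the per-target
frequencies from planted-truth recovery metrics (recall, 3′-bias), and why
reproduction of printed frequencies goes through the stored per-library
p-values (the supplementary-table path) rather than through re-testing.

## The empirical null

The genome-wide null asks: around *any* down-regulated gene, how often are
neighbors up- or down-regulated? Every (gene, library) down-call is a focal
instance; every other gene with centrum within 500 kb contributes one
neighbor instance scored by its call in the same library; `f_up` and
`f_down` are fractions over neighbor instances. Focal genes are excluded
from their own neighbor sets. On null cohorts both fractions sit at
$\alpha/2$, since two-sided calls split evenly between directions.

The published comparison sets a *per-target* frequency against this
*per-neighbor-instance* background in one goodness-of-fit test. The units
do not match — a target aggregates ~25 neighbor instances by OR — and the
package reproduces the comparison as printed while exposing both
definitions separately. Chi-square tests are plain Pearson without
continuity correction (df = 1), the default reading of "a chi-squared
statistic" when no correction is named.

## Targeting QC

Total read counts alone cannot confirm a knockout: proximal exons upstream
of a trap still transcribe, non-functional transcripts splice around the
cassette, and partial deletions leave distal exons expressed. The screen
first flags mutants whose counts cannot confirm targeting — at least 100
normalized reads in either library AND HOM retaining at least 20% of WT
(both boundaries inclusive) — and then classifies per-exon profiles
(ordered 5′→3′ in transcription direction, plus an intronic total) through
a fixed cascade, most specific structural evidence first: indeterminate
(neither library expressed), failed targeting (reads persist on deleted
exons), intronic-only, distal retention (partial deletion with retained
exons at or above WT — compensatory overexpression), complete trap (nothing
beyond the trap intron), splice-around (a skipped run after the trap, then
distal resumption), uniform hypomorph (every exon reduced within 2-fold of
the gene-level ratio), and finally the total-count criterion. The floor
$F = 100$ reads and presence ratio $r = 0.2$ deliberately reuse the flag
criteria's constants rather than inventing new ones; the cascade order
makes the verdicts mutually exclusive by construction. Because $F$ is an
absolute read floor the cascade is scale-invariant only above it; the
ratio-based rules (2, 4, 7, 8) are scale-free.

## Regulatory-element scoring

The rule engine consumes static interval files (extended BED; 0-based
half-open coordinates converted on read) rather than querying live TFBS or
ChIP databases, whose contents are version-dependent. A TRAP event is
scored as likely disruptive when ≥ 2 *high-confidence* TFBS lie in the gene
body 3′ of the insertion intron — "distal" is read strictly: the region
from the transcription-side start of the first post-trap exon to the gene's
3′ end, because those are the sites the cassette separates from the
promoter. A DEL event needs ≥ 2 TFBS (any confidence; the high-confidence
requirement is stated only for TRAP) *within the deleted span* plus ≥ 1
overlapping ChIP peak (Pol2/CTCF/p300) as corroboration — one peak of any
track, since "corroborating" is not quantified. TFBS count by containment
(sites are ~10 bp), peaks by overlap. Both rules are monotone: adding
intervals can only turn a call disruptive.

## The synthetic cohort

`synthetic_config()` defaults encode the emulated study design: 29 DEL and
15 TRAP targets, 4 tissues (one pooled HOM library per line and tissue,
shared WT controls), an 8-fold target knockdown, and NB counts with
$\mathrm{Var} = \mu + \alpha\mu^2$, $\alpha = 0.05$. Other defaults, chosen
once:

* **Genome**: 4 chromosomes × 15 Mb at 25 genes/Mb — the gene-dense
  neighborhoods where targets of this kind sit — with log-normal gene
  lengths (median 12 kb, σ = 0.7 on the log scale; short enough that genes
  tile a dense genome without overlap), 2–8 exons per gene, 5% single-exon
  miRNA models, and uniform random strands. Targets are sampled among
  protein-coding genes with ≥ 4 exons and ≥ 5 neighbors in the window.
* **Expression**: log-normal baseline, median 300 counts (σ = 1.2),
  library depth factors log-normal with σ = 0.15 — a filtered gene-level
  RNA-seq profile at ~20M reads.
* **Planted local effects**: a neighbor at signed distance $d$ is
  up-planted with probability $p_{up}\,e^{-|d|/\lambda}\cdot 2b$ for 3′
  neighbors and $2(1-b)$ for 5′ ($b = 0.774$, the observed 3′ share of
  up-regulated flanking genes), and down-planted with the symmetric
  $p_{down}\,e^{-|d|/\lambda}$. The decay $\lambda = 100$ kb reflects that
  most local effects fall within 200 kb; an exponential is the simplest
  monotone choice, nothing in the data selects a functional form. With
  $p_{up} = 0.15$ and $p_{down} = 0.2$ the cohort plants ~1.5 dysregulated
  pairs per target, the order observed in screens of this size. Effects
  are $|\log_2| = 2$ and consistent across tissues (cis-acting), and the
  truth record lists every planted (line, neighbor, direction, tissue), so
  exact recovery metrics exist for every downstream module.
* **QC profiles** are generated per verdict scenario with per-exon WT
  means of 600 reads and Poisson noise, placing every threshold the
  cascade uses far from its boundary; under that noise recovery is ≥ 95%,
  and exact without noise.
* **Regulatory fixtures** plant disruption at the class frequencies the
  screen reported (0.586 DEL, 0.067 TRAP) and place qualifying intervals
  accordingly.

All draws derive from the config seed; the same config is bit-reproducible.
What the generator does **not** emulate: correlated expression between
neighboring genes (co-regulated clusters, bidirectional promoters),
tissue-specific expression, isoform structure, or mappability artifacts.
Passing recovery tests therefore shows the machinery is correct under the
stated model, not that biological confounders are handled.

## Validation, problem sizes, known limitations

The test suite validates each operation against an independent oracle:
brute-force window scans and double loops for the neighborhood and the
null, exhaustive conditional enumeration for the pair test, a predicate
grid for the flag, positional loops for both regulatory rules, hand
formulas and the $2\Phi(-\sqrt{x})$ closed form for the chi-squares. The
cohort-level suite uses 6 replicate null cohorts (~600 genes each) for null
calibration, a ~5,000-gene null cohort for type-I error, two 30-target
cohorts for recall and 3′-bias recovery, and 40 noisy profile pairs per QC
verdict — sizes at which the Monte-Carlo bands in those checks are
informative while the whole suite stays quick.

Reproduction of the published cohort's printed summaries
(`reproduce_from_s1()`) consumes the deposited per-library supplementary
table (stored normalized counts and unadjusted p-values, target rows
excluded from neighbor statistics) and is exercised in the tests on a
synthetic export; the deposited table itself is not redistributable with
the package, so the corresponding validation test reports failure when the
export has not been placed under `inst/extdata/`.

Known limitations: the no-replicate dispersion trend cannot separate
biological variability from genotype effect (a genuinely global
transcriptome shift would inflate the trend and deflate power); the
per-target OR saturation discussed above; the exon classifier works on
exon-level summaries, not nucleotide pileups or splice junctions, so it
cannot distinguish a functional hypomorph from a non-functional
splice-around product — that remains a protein-level question.
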