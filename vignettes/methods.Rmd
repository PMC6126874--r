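---
title: "Detecting cell-type-specific transcription factor co-occurrence from open chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell-type-specific transcription factor co-occurrence from open chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooctf)
```

## The problem

Enhancers drive cell-type-specific transcription, and they usually do it
through *combinations* of transcription factors (TFs) rather than single
factors. DNase-seq maps the open-chromatin regions (DNase hypersensitive
sites, DHSs) where such combinations can act. `cooctf` asks, for every pair
of TFs and every cell type: does this pair co-occupy the chromatin that is
open *specifically* in this cell type more strongly than it co-occupies
chromatin that is open *everywhere*?

The contrast with ubiquitously open chromatin is the core of the method.
Promoter-like regions are open in essentially all cell types and are packed
with binding sites for general factors; any co-binding statistic evaluated
against a naive genomic background is dominated by them. Using the
ubiquitous DHSs as the background stratum cancels that shared signal, so
what remains is co-occurrence tied to cell identity.

The pipeline has four stages, each exposed as ordinary functions:

1. **Chromatin specificity** — rank genome windows by a regularized
   t-statistic contrasting each cell type against the average profile.
2. **Binding affinity** — score each selected DHS for each motif with a
   biophysical occupancy model and call the top-k "bound".
3. **Co-occurrence statistics** — per motif pair and cell type, two
   stratified Fisher tests and their log-p contrast, the L score, with
   empirical-quantile significance and BH-adjusted q-values.
4. **Networks** — per-cell-type TF graphs, pan-cell-type filtering, and
   TF-centric co-factor queries.

## The specificity t-statistic

Reads are counted into fixed 200 bp non-overlapping windows by their
strand-aware 5' end, so each read increments exactly one window. Counts are
depth-scaled per sample (factor = grand mean count / sample mean count) and
transformed with `ln(x + 1)`. Scaling *before* the log keeps the pseudocount
comparable across sequencing depths.

For window $w$ with log-normalized values $X_{iw}$, cell types
$ct = 1,\dots,m$ with sample sets $C_{ct}$ of size $n_{ct}$:

$$\bar X_{ct} = \frac{1}{n_{ct}}\sum_{i \in C_{ct}} X_{iw},
\qquad \bar X = \frac{1}{m}\sum_{ct=1}^m \bar X_{ct},$$

$$s^2 = \frac{\sum_{j=1}^m \sum_{i\in C_j}(X_{iw}-\bar X_j)^2}
             {\sum_{j=1}^m (n_j - 1)},
\qquad t_{ct} = \frac{\bar X_{ct} - \bar X}
                    {\sqrt{1/m + 1/n_{ct}}\,(s + s_0)}.$$

$s_0$ is the mean of $s$ over all windows; it regularizes windows whose
within-class variance is estimated near zero, exactly as moderated
t-statistics do in expression analysis. Cell types with a single sample
contribute no degrees of freedom to $s$ but still receive a t value. The
statistic deliberately measures *consistent* openness relative to the
average profile: a window must be reproducibly open across a cell type's
replicates to rank highly, not just open in one noisy library.

Two presentation details are genuinely open and are therefore arguments:

* **Radical placement.** The denominator is implemented as
  $\sqrt{1/m + 1/n_{ct}}\,(s+s_0)$ (argument `denominator = "sum"`), the
  form dimensionally consistent with a two-sample t-statistic; the variant
  with the radical over the whole product is available as `"sqrt-inside"`.
* **Grand mean for depth factors.** The default uses the grand mean over
  all matrix entries (`grand_mean = "entries"`); the mean of per-sample
  means is available and identical for balanced designs.

Degenerate inputs are defined, not accidental: a constant matrix gives
$t \equiv 0$ (the 0/0 case is resolved to 0 because a window with no
deviation and no variance carries no specificity evidence), fewer than two
cell types is an error, and all-singleton designs are rejected because the
pooled SD is undefined.

### Selecting the two strata

Per cell type, the top-`l` windows by $t_{ct}$ form the cell-type-specific
(CTS) stratum. The ubiquitous stratum is formed once: windows whose global
mean accessibility strictly exceeds the `open_quantile` quantile of all
global means (openness filter) are ranked by $\max_{ct} |t_{ct}|$,
ascending, and the top `l` are taken. This operationalizes "open everywhere,
specific nowhere". All ties anywhere are broken by genomic coordinate so
every ranking is deterministic.

At atlas scale the defaults are `l = 5000` per stratum and
`open_quantile = 0.75`. On small fixtures both must be rescaled; the
synthetic spec carries its own settings (see below).

## The binding-affinity model

Hit-based motif scanning with a score threshold discards low-affinity sites,
which matter for cell-type-specific regulation. Instead, each motif count
matrix is converted to a mismatch-energy matrix: with pseudocount
$q$, per-position base probabilities $p_b = (c_b + q)/(\sum c + 4q)$ and
energies $E_b = \ln(p_{\max}/p_b)/\lambda$, so the consensus base has energy
0. A site of width $w$ starting at position $i$ has energy $E_i$ equal to
the sum of its per-position energies, and contributes the occupancy

$$\frac{r_0 e^{-E_i}}{1 + r_0 e^{-E_i}}$$

to the sequence's affinity; the affinity is the sum over **all** sites on
**both** strands (the reverse strand is scored on the reverse complement),
i.e. the expected number of occupied sites. Defaults are $\lambda = 0.7$ and
$\ln r_0 = 0.584\,w - 5.66$, the standard parameterization of this model
class; both are arguments, as is the pseudocount (default 1). Sites
containing `N` contribute zero occupancy. The model makes affinity
reverse-complement invariant and monotone under sequence extension — both
are enforced as property tests.

Per cell type, the `l` CTS and `l` ubiquitous DHSs are scored jointly and
the top-`k` DHSs per motif within this 2l-set are called **bound** (default
`k = 1000` of 2l = 10000 at atlas scale). Ranking is never genome-wide: the
bound/unbound call is relative to the stratum under study.

## The L score

For one motif pair (A, B) in one cell type, the 2l DHSs are stratified by
the CTS indicator $Z$ into two 2×2 tables of bound/unbound counts, each
summing to l. Both tables get a one-sided (upper-tail) Fisher exact
p-value — the hypothesis is *co-occurrence*, i.e. an excess of jointly bound
DHSs, so the upper tail is the relevant direction. The score is

$$L = \ln p_{\mathrm{ubiq}} - \ln p_{\mathrm{cts}},$$

large and positive when the pair co-binds the cell-type-specific stratum
far more significantly than the ubiquitous one, large and negative in the
opposite case (a *ubiquitously co-occurring* pair).

Numerical choices:

* **Log space end to end.** p-values are computed as log hypergeometric
  tails (`stats::phyper(log.p = TRUE)`, exact, no normal approximation) and
  never exponentiated on the way to L, so a table like
  `[[1000, 0], [0, 1000]]` yields a finite L instead of overflowing.
  The implementation is cross-checked against an explicit
  log-gamma/log-sum-exp enumeration in the tests.
* **Natural logarithms** throughout; the base only rescales L and the
  significance rule is quantile-based, so it is inconsequential.
* **Significance is empirical.** Within each cell type, a pair is flagged
  cell-type-specific when its L *strictly* exceeds the 99.5% quantile of
  that cell type's L distribution, and ubiquitously co-occurring when L is
  strictly below the 0.5% quantile. Quantiles use linear interpolation
  between order statistics (R type 7). Strict inequality means an
  all-tied L distribution flags nothing.
* **BH q-values** for both strata are computed per cell type and reported
  alongside, but they do not enter L: the score is a contrast of raw
  evidence, and the quantile rule provides the selection.
* Only pairs whose motifs map to **different TF groups** are tested.
  Distinct motifs often represent one factor (and similar motifs several),
  so same-group pairs would mostly measure motif redundancy; the method is
  by design insensitive to homotypic pairs.

Motif pairs are aggregated to TF-group pairs by the union rule: a TF pair
is significant if any constituent motif pair is, and carries the best
(maximum) L and smallest CTS log-p among its motif pairs.

The same machinery gives single-motif overrepresentation: one
bound/unbound × CTS/ubiquitous table per motif per cell type, upper-tail
Fisher p, motifs ranked ascending; the report view flags the top 50 per
cell type. Note the one-sided convention: a perfectly balanced table has an
upper-tail p around 0.5–0.7 depending on the margins, not 1 — p = 1 would
only hold for a two-sided independence test.

## Networks

Each cell type's significant TF pairs become an undirected graph (edges
attributed with L and log-p). A frequency table counts in how many cell
types each pair is significant; `filter_common()` removes edges at or above
`max_freq` (default 30) cell types, leaving the cell-type-specific part —
pan-cell-type pairs are real but uninformative about identity. The
threshold counts *cell types*, the unit used everywhere else in the
analysis, not individual cell lines. `cofactor_profile()` inverts the view:
all significant partners of one TF with their supporting cell types.
`pairset_enrichment()` tests a predicted pair set against any external
reference set (e.g. curated protein–protein interactions) over an explicit
universe of testable pairs, reporting the odds ratio and upper-tail Fisher
p. GraphML export is attribute-lossless; SIF carries topology only.

Node annotations such as expression status are joined from optional input
tables, never computed here.

## The synthetic fixture generator

`planted_spec()` defines a complete synthetic study; every stage of the
pipeline is testable against the ground truth it plants. Defaults:
2000 windows of 200 bp, 4 cell types × 3 samples, 12 motifs in 8 TF groups,
one planted co-occurring cross-group pair per cell type at planting rate
0.6, background singleton motif rate 0.05 per window and motif.

* **Counts** are negative-binomial (dispersion `size = 10`), not Poisson:
  DNase-seq replicates are overdispersed, and the $s_0$ regularization is
  only exercised under real within-class variance. Closed windows have mean
  2; planted CTS windows are open at mean 20 in all cell types and elevated
  8-fold (mean 160) in their own; planted ubiquitous windows sit at the
  elevated level everywhere.
* **Sequences** are i.i.d. uniform bases with consensus words planted at
  non-overlapping offsets. Consensus planting (rather than PWM-sampled
  sites) keeps the truth table unambiguous. The twelve built-in consensus
  words use only A/C/G, so no word collides with any reverse complement.
* **Seeding**: all randomness derives from one master seed via a
  counter-based splitting scheme, so the count matrix and the sequences are
  independently reproducible.

The spec also carries the analysis settings appropriate to its own scale,
chosen once from the generator's geometry:

* `l = 50` per stratum — the planted per-type CTS count, so a correct
  selection is exactly recoverable;
* `k = 40` of 2l = 100 — the bound set must be able to hold every planted
  occurrence of a motif (≈ rate × l + background ≈ 35). If k were smaller
  than the number of motif-bearing windows, the top-k cut would fall
  *inside* a set of near-tied affinities and the bound call would be driven
  by background noise, destroying genuine co-occurrence before the
  statistics ever see it. At atlas scale the default k/2l = 0.1 has the
  same property because motif-bearing windows are rarer;
* `open_quantile = 0.95` — 250 of 2000 windows are truly open, so the
  atlas-scale default of 0.75 would pass ~430 noisy closed windows into the
  eligible set, where they outnumber the 50 genuinely ubiquitous windows in
  the smallest-|t| ranking. The 0.95 quantile admits ~100 windows,
  dominated by the planted open ones.

What the generator does **not** emulate: fragment-length and cut-bias
structure, mappability, GC-dependent coverage, correlated motif grammars
(spacing, orientation), overlapping DHSs between cell types, and realistic
motif information content. Passing tests on these fixtures therefore
demonstrate the statistical machinery — ranking, stratification, exact
tests, quantile selection — not performance on real chromatin.

Problem sizes in the test suite are deliberately small (600–2000 windows,
recovery experiments over 20 seeds, Fisher oracle over 200 random tables
with totals up to 500); they were chosen so the full suite exercises every
code path in about a minute while keeping the recovery experiments
statistically meaningful.

## Known limitations

* Homotypic (same-TF-group) co-occurrence is excluded by construction.
* Competitive binding (two TFs occupying the same sites in different cells)
  is invisible to a co-occurrence statistic.
* The bound/unbound call is a hard top-k cut of a continuous affinity;
  pairs whose co-binding lives entirely below the cut are missed.
* The empirical-quantile rule flags a fixed fraction of pairs per cell
  type by design; with very few testable pairs its granularity is coarse
  (with 62 pairs, the strict 99.5% rule can flag at most one pair, a rate
  of 1.6%).
* The L score compares significance, not effect size; with unequal
  stratum compositions the Fisher p-values absorb margin differences.
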