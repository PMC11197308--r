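---
title: "TEdynamics: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TEdynamics: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEdynamics)
```

This vignette is the package's account of its science: the models it
implements, the thresholds and tie-break conventions it fixes, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reading was defensible.

## Dating LTR retrotransposons from terminal-repeat divergence

An intact LTR retrotransposon carries two long terminal repeats that
were identical copies at the moment of insertion. Each repeat then
accumulates substitutions independently and (we assume) neutrally, so
the divergence between the two repeats clocks the insertion:

$$ T = \frac{K}{2\mu}, $$

where $K$ is the per-site substitution distance between the two LTRs
and $\mu$ the per-site per-year mutation rate. The factor 2 reflects
that both copies mutate. The default $\mu = 4\times10^{-9}$ is the
rate conventionally used for Rosaceae; it is a plain argument
(`dateLTRPairs(..., mu = )`) because it is the single most influential
constant in the analysis — ages scale as $1/\mu$.

`pairwiseDivergence()` assumes its two inputs are *already aligned*
and equal-length; alignment is an upstream step (LTR annotation
pipelines emit aligned or identical-length LTR pairs) that the package
deliberately does not re-implement. Columns containing a gap or an `N`
in either sequence are excluded before counting; an alignment with no
retained columns is an error, not a zero.

The multiple-hit correction is Jukes–Cantor,
$K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$: the simplest model, the one
the standard LTR-dating tools use, and adequate at the divergences
intact elements show (a 10-MY-old element at the default rate has
$p \approx 0.077$, far from the $p = 0.75$ singularity, at which the
function errors). `model = "raw"` skips the correction for
diagnostics. K2P/HKY corrections and bootstrap intervals are out of
scope.

Ages are carried at full float precision; any binning happens only in
the profiling step.

## Transposition-rate and accumulation profiles

`buildRateProfile()` bins ages into 0.1-MY intervals over a 0–10 MY
window: 100 left-closed right-open bins, with the window edge itself
kept in the last bin. Two numerical details matter:

* **Bin edges are rounded to 10 decimals** before binning, so an age
  printed as 0.7 lands in the bin `[0.7, 0.8)` even though
  `7 * 0.1 > 0.7` in binary floating point.
* **Elements older than the window are excluded from normalization
  but reported** (`nOlder`): only extant, datable elements are
  observable, and the profile describes the windowed population.

The *transposition rate* of a bin is the fraction of in-window
elements dated to it — i.e. the net increase in surviving elements per
0.1 MY relative to the windowed total. No correction is attempted for
elements inserted and subsequently lost: extant annotations cannot
show them, so the rate is a survivor-based estimate by construction.

The *accumulation* value at a bin's left edge $t$ is the fraction of
in-window elements at least $t$ MY old: 1 at the present-day boundary,
non-increasing with $t$. Whether "accumulation" means cumulative
fraction or cumulative count is a genuine ambiguity; fraction is the
default and `cumulative = "count"` is available.

Burst statistics (`estimateBurst()`) are the median in-window age and
the modal bin midpoint, with modal ties broken toward the *younger*
bin — a deterministic, stated rule. `youngOldSplit()` labels elements
at or below the median age `young` (ties young, same rationale) and
warns when all ages are identical rather than inventing a split.

`correlateGenomeSize()` wraps `stats::cor.test(method = "spearman")`
with average-rank ties and asymptotic two-sided p-values
(`exact = FALSE`, so the result is deterministic in the presence of
ties); constant count columns have undefined rank correlation and are
reported `NA` with a warning rather than dropped.

## Domain and expression classes

The five-domain vocabulary (GAG, AP, INT, RT, RH) is closed: a domain
table row outside it is an input error, caught at the reader.
`classifyDomainStatus()` counts *distinct* domains per element — all
five make an element `structure_intact`, at least one
`domain_existent` — so structure-intact elements satisfy the
domain-existent criterion by construction, and repeated rows (multiple
RT hits, say) do not inflate the count.

The *expressed* filter keeps elements with TPM > 1 (strict) in **at
least one** sample. The alternative reading — above 1 in *every*
condition — is available as `mode = "all"`; "ever expressed" is the
default because the set it selects is the one used for downstream
element-level analysis, where a single active condition suffices. The
*high expression* flag is inclusive at $\log_2(\mathrm{TPM}+1) \ge
3.5$, i.e. TPM $\ge 2^{3.5}-1 \approx 10.31$.

The specificity index is
$\tau = \sum_i (1 - \hat x_i)/(n-1)$ with
$\hat x_i = x_i / \max(x)$ computed on $\log_2(\mathrm{TPM}+1)$:
0 for a flat profile, 1 exactly when one sample is non-zero. The
index, and its default call threshold of 0.85, are this package's own
summary of what the field reports qualitatively as "tissue-specific
expression" — they are not literature constants, and the threshold is
an argument. Because $\tau$ is computed on log-transformed values it
is only approximately invariant to global rescaling of a row; we keep
the log transform because raw TPM would let a single extreme sample
saturate the index. LINE elements present in expression sets are
carried through with their own order label, not silently dropped.

## Proximity and syntenic DEG-pair classification

`assignTEProximity()` assigns a TE to a gene when the nearest-edge gap
is **strictly** below the 5000-bp radius. The conventions, each of
which the tests pin down at its boundary:

* Touching or partially overlapping intervals have distance 0; a gap
  of exactly 5000 bp is *not* proximal.
* A TE **fully contained** in the gene body is excluded — "inside the
  gene" is read as full containment, so a boundary-straddling
  insertion (which disrupts the gene's context from outside as much
  as inside) still counts, at distance 0. The gene body is one
  interval; intron/exon resolution is out of scope.
* Upstream/downstream are **coordinate-order** sides, strand-agnostic:
  nothing in the classification scheme conditions on transcription
  direction, and a strand-aware convention would silently relabel
  half the records. For overlap cases the side follows the TE
  midpoint relative to the gene midpoint, ties upstream.
* One TE may serve several genes; assignment is per (gene, TE) pair.

The implementation is interval-tree based
(`GenomicRanges::findOverlaps` with `maxgap = radius - 1`); its oracle
— an exhaustive all-pairs scan in plain integer arithmetic — is kept
in the test suite and the acceptance script, and the two must agree
exactly on random landscapes.

DEG calling is threshold-rule based, matching how the comparisons are
defined rather than fitting a statistical model. Period-specific:
max over adjacent timepoints of $|\log_2$ fold change$|\ \ge 1.5$ in
cultivar A *and* $< 1.5$ everywhere in B. Fold changes use a +1 TPM
pseudocount (the rule is applied to TPM courses that contain zeros)
and are absolute by default; `signed = TRUE` restricts to increases.
Cultivar-specific: TPM > 32 at some timepoint in A (strict) and TPM <
8 at every timepoint in B (strict); `all_timepoints = TRUE` tightens
the A rule. Both matrices must share an ordered timepoint axis of
equal length — the two cultivars' sampling days differ by calendar
date but align one-to-one by stage.

`classifyPair()` separates two ideas deliberately: the **main type**
depends only on the *count* discrepancy (I: more TEs near A's gene,
II: more near B's, III: equal), while the **subtype** is the ordered
pair of positional states (NONE/UP/DOWN/BOTH), the full 4×4 grid of
16. Equal states with unequal counts are therefore Type I or II, and
IIIα is the stricter equal case of *no* proximal TEs on either side
(the equal-nonzero reading remains distinguishable downstream via the
counts, which are returned). Classification is total — every pair gets
exactly one type and one subtype — and antisymmetric under swapping
the cultivars (I↔II, subtype transposed), a property the acceptance
checks verify wholesale. By default all TE orders count toward the
states; `ltr_only = TRUE` restricts to LTR elements.

## Input/output conventions

All containers are Bioconductor-native: TE and gene annotations are
GRanges (1-based closed coordinates, converted at the GFF3 boundary by
rtracklayer), the TE set is a validated GRanges subclass
(`TEAnnotation`) whose validity method enforces the nine-superfamily
vocabulary, unique ids and 5′-before-3′ LTR geometry, and expression
matrices ride in SummarizedExperiments. Classification attributes
outside the nine codes map to an explicit `"unknown"` bucket with a
warning — never a silent drop. Read→write→read round trips are
identity on every supported format, and downstream functions consume
only the parsed containers, never file paths.

## The synthetic-data generator

The generator exists so every analysis stage can be validated against
known truth without any external data. Its design inverts each
analysis:

* **LTR pairs** start identical and each copy mutates every site
  independently with probability $\mu T$ (not $1-e^{-\mu T}$; at the
  simulated regime of $\le 10$ MY the relative error is below
  $2\times10^{-5}$ and the simpler form is transparent). Replacement
  bases are drawn uniformly from the three alternatives, so repeated
  hits at one site can converge — which is exactly what makes the
  Jukes–Cantor correction in the dating path non-trivial to pass.
  Regimes with $\mu T \ge 0.25$ per copy are refused. The expected raw
  divergence is $2\mu T - \tfrac{4}{3}(\mu T)^2$ (the quadratic term
  is same-site collision), and the calibration tests check the
  simulated mean against this closed form within Monte-Carlo error.
* **Solo LTRs** are recorded deterministically as
  `round(ratio * n_intact)`; the default ratio of 8 sits in the
  moderate range observed across well-assembled rosaceous genomes.
* **Gene/TE landscapes** place syntenic gene pairs on matching
  coordinates of two cultivars, cycle through all 16 positional
  configurations, draw flanking gaps strictly inside the radius, and
  add two kinds of decoys — beyond-radius TEs and TEs fully inside
  gene bodies — that the proximity rules must exclude. Flank and decoy
  TEs carry ages from the configured age distribution so young/old
  splits can run on the same landscape. Gene spacing (30 kb) keeps
  each gene's flanks out of its neighbours' radius by construction.
* **Expression courses** inject three patterns — period-specific (one
  elevated timepoint giving two adjacent fold changes of the
  configured effect, default 2.0 in log₂), cultivar-specific (constant
  64 TPM in A vs 2 in B), and null (constant background of 5 TPM) —
  under multiplicative log-normal noise **truncated at ±3σ**
  (default σ = 0.05). `simConfig()` refuses any combination where the
  worst-case truncated noise could move a pattern across a caller
  threshold (the adjacent-fold-change perturbation is bounded by
  $6\sigma/\ln 2$), which is what makes precision = recall = 1 a
  meaningful target rather than a lucky draw. No published noise
  model exists for these TPM courses; σ and the log-normal form are a
  stand-in, stated as such.

What the generator does **not** emulate: target-site duplications,
nested insertions, internal coding sequence, read-level RNA-seq (TPMs
are generated directly), assembly artefacts, or solo-LTR genomic
positions. Passing tests therefore demonstrate correctness of the
*computations* under the stated models, not robustness to annotation
error or quantification noise in real genomes.

Determinism is part of the contract: a `simConfig` (whose `seed` is
mandatory) fully determines every output, and `runSyntheticPipeline()`
writes byte-identical files across runs — checked in the acceptance
suite.

## Validation problem sizes

The acceptance checks run at the sizes the properties were designed
for: 2000 elements × 1-kb LTRs for age recovery (per-element binomial
noise then gives ≈0.42 MY mean absolute error and a regression slope
within a few percent of 1), 5000 elements for burst recovery (the
modal bin of an sd-0.3 burst is stable to ±1 bin at this count — the
burst check runs on the injected ages, since re-estimated ages add
≈0.55 MY of dating noise that is the age-recovery check's subject, not
this one's), 100 random landscapes of up to 200 genes × 500 TEs for
the proximity oracle, 500 pairs for classification, and 1000 pairs for
DEG recovery.

## Known limitations

* Ages assume neutrality and a single clock; gene conversion between
  LTRs biases real ages downward, and no correction is attempted.
* The solo:intact ratio consumes counts; identifying solo LTRs is an
  annotation-pipeline task upstream of this package.
* The 16-subtype grid is a reconstruction of the positional scheme
  from its definition in terms of per-side states; the returned
  per-side counts let a user re-cut the grid differently.
* Thresholds (1, 3.5, 1.5, 32, 8, 5000) are conventions of the
  analysis the package implements, exposed as arguments but not
  re-estimated from data.
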