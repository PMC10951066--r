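---
title: "Models and methods behind repdominance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind repdominance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repdominance)
```

This vignette is the package's own account of the statistical models it
implements, the choices that were genuinely open, and what the synthetic
data generator does and does not emulate.

## The limiting-dilution Poisson model

When CD4 T cells are distributed across culture wells at `c` cells per
well and a fraction `f` of them is specific for the antigen, the number
of specific precursors per well is Binomial(`c`, `f`), which at
`c = 200,000` and `f` of a few per million is indistinguishable from
Poisson with mean `cf`. A well grows into a responding T-cell line iff
it received at least one specific precursor, so the zero class estimates
`exp(-cf)` and

$$\hat f = -\ln(n_\text{neg}/n_\text{tot})/c.$$

`precursor_frequency()` implements exactly this, reporting per million
cells. The estimator is undefined on an all-positive plate (saturation);
`call_plate()` flags that case rather than extrapolating. The estimator
carries a small upward Jensen bias of order `Var(p̂)/(2p²)` — about 1%
at 96 lines and `f = 6/M` — which is why the recovery test below uses a
5% band. `frequency_interval()` is a parametric bootstrap on the
positive-line count; we clip saturated bootstrap draws to
`n_total - 1` instead of discarding them, which keeps the interval
defined near saturation at the cost of a slightly conservative upper
tail.

Positivity of a line (`call_positive()`) requires spots with antigen to
be at least twofold the no-antigen control *and* at least 25 spots above
it. Two boundary readings were open and are fixed as: the fold condition
is non-strict (`>=`), since strictness is unobservable at integer spot
counts once the 25-spot floor dominates; and a zero control satisfies
the fold condition vacuously — any positive count is infinitely many
folds above zero — leaving the absolute floor to gate noise.

Cross-donor summary frequencies are reported as the arithmetic mean of
per-donor estimates, with pooling (summing positives and totals) as an
option (`aggregate_frequency()`). Published cross-donor values of this
kind are consistent with per-donor averaging and not with pooled
tallies, but per-donor counts are rarely printed, so both modes are
exposed and the default is documented rather than asserted.

## Repertoire statistics

**Background subtraction.** Bulk-culture repertoires contain clonotypes
that expanded without antigen; any clonotype whose key also occurs in
the paired unstimulated control is removed and the survivors'
frequencies renormalized by the surviving mass. The clonotype key is
configurable: within-donor operations default to the triple
(junction, V gene, J gene); cross-donor public-clonotype analysis keys
on the bare CDR3β amino-acid string, the form in which public sequences
are reported. Gene calls are truncated to gene level on input because
usage statistics are reported at gene level.

**Diversity and dominance.** `gini_simpson()` is `1 − Σ pᵢ²`, bounded by
`1 − 1/n` with equality at uniformity. `top_fraction()` sorts by
frequency descending with lexicographic tie-break on the junction (so
results are identical across platforms and runs) and returns the
smallest prefix reaching the target cumulative mass; a `1e-12` slack
absorbs floating-point rounding at exact boundaries.

**Positional composition.** Sequence logos over variable-length CDR3β
sets require a common coordinate system. Rather than depend on an
external progressive aligner (whose output varies with version and
guide-tree tie-breaking), `align_cdr3()` uses a deterministic
anchor-and-centre-pad scheme: the junction's first and last four
residues — the conserved C/F anchors plus their immediate neighbours,
which are the least variable positions — are pinned to the block edges,
and the interior is centred with gap padding (left gap gets the floor on
odd splits). This is a positional summary device, not a homology claim;
`composition_profile()` accepts an externally produced alignment block
wherever higher fidelity is wanted. Gaps are excluded from each
position's denominator. The chemical-class table uses hydrophobic
{A,V,L,I,M,F,W,C}, polar {S,T,N,Q,Y}, basic {K,R,H}, acidic {D,E},
neutral {G,P}.

**Hydrophobic doublet.** The self-reactivity signature is scored at
junction positions 6 and 7, 1-based from the conserved cysteine. The
cited literature's exact positional convention is not restated in the
study this package models, so the C-anchored convention is documented
here as this package's definition rather than asserted as anyone
else's. Whether logos and this statistic weight clonotypes by frequency
or count each once is likewise unstated in the field; both modes are
implemented and the default is unweighted (each clonotype once).

**V/J usage.** Defaults to frequency weighting because "X% of the total
repertoire" is a mass-weighted statement; count weighting is available.
The pairing distribution's marginals equal the usage vectors by
construction, and tests assert it to `1e-9`.

**Public clonotypes.** A sequence is public when observed in at least
two donors (after background subtraction). Each donor contributes a
sequence once, with its V/J variants' masses summed. Records are sorted
by sharing degree, then maximum per-donor frequency, both descending.

## Epitope mapping

`select_promiscuous()` implements the percentile-rank rule: selected
iff strictly fewer than `threshold` (default 10) on at least
`min_alleles` (default 4) alleles. "Below 10%" is read strictly; the
boundary is configurable and tested under both readings.

`rank_epitopes()` ranks by total positive T-cell lines because the
headline quantity ("X% of the total T cell response is elicited by k
epitopes") is a cumulative-intensity statement; responding-donor count
is the tie-break, and peptide position (parsed from `P<start>-<end>`
ids) the final deterministic tie-break — the original ordering of tied
peptides is not recoverable from published material, so determinism was
the criterion. Both `k_response` (smallest prefix at the response
target) and `k_coverage` (smallest prefix covering every donor) are
reported, since whether a published epitope set was cut strictly at the
response target or adjusted for coverage is not stated.

## The synthetic-data generator

The generator's defaults are the study conditions of the data it stands
in for: 535 clonotypes per sample (the mean detected per donor for
FVIII), CDR3 lengths 10–19 with the mode at 12–13, V usage dominated by
TRBV7-4 (60%) and TRBV7-3 (25%), J usage led by TRBJ1-2 and TRBJ2-7,
ELISPOT plates of 96 lines at 200,000 cells/well with a true frequency
of 6/M, 63-peptide score matrices over 15 alleles with 18 planted
promiscuous peptides, and response matrices totalling 872 positive
lines with the dominant set carrying 50% of the mass.

Clone sizes follow a geometric law `p_r ∝ (1−c)^r` rather than a
discrete power law: a single shape parameter with the closed form
top-k coverage `1 − (1−c)^k`, which makes recovery tests exact. The
default `c = 0.052` is calibrated so that ~13 clonotypes cover half the
repertoire (solving `1 − (1−c)^13 = 0.5`), reproducing the observed
dominance scale; the implied Gini–Simpson is ≈ `c/(2−c)` below 1, i.e.
≈ 0.97. Counts are expected template counts at a 10⁵-read scale
(minimum 1), so frequencies are exactly the geometric law up to
rounding — sampling noise on counts is deliberately omitted because the
statistics under test are functions of frequencies.

Sequences carry the conserved C…F anchors with interior residues drawn
uniformly except at core positions (5 to L−4), where a configurable
fraction of probability mass (default 0.2) is moved onto the
hydrophobic class. Planted structure is collision-free by construction:
public clonotypes (same junction *and* gene calls everywhere they
appear) are inserted into the antigen samples of a random subset of ≥ 2
donors; background clonotypes are inserted into both the antigen and
control samples of their donor, which is exactly what
`subtract_background()` must remove. The ELISPOT simulator seeds
`k ~ Binomial(cells, f)` precursors per line with Poisson baseline and
signal spots (defaults 10 and 100; the underlying spot distributions
are not published, so these are free parameters exposed in the
configuration, chosen so the 2-fold/25-spot rule has a realistic but
small false-positive rate).

What the generator does **not** emulate: V(D)J recombination mechanics
and indel profiles, sequencing error, PCR amplification bias, shared
germline-encoded sequence motifs between donors (public clonotypes are
planted, not convergently generated), or correlation between a
clonotype's sequence and its abundance. Passing recovery tests
therefore demonstrates the correctness of the statistics on data with
the study's marginal properties, not robustness to upstream sequencing
artifacts — those are assumed handled by the upstream aligner and error
correction.

## Numerical and testing choices

Determinism throughout: all generators are pure functions of
(configuration, seed) via scoped RNG (`withr::with_seed`), tie-breaks
are lexicographic, and pipeline re-runs are byte-identical. Probability
vectors must sum to 1 within `1e-9`; cumulative thresholds use `1e-12`
slack. Degenerate inputs (empty samples, header-only files, saturated
plates, all-zero matrices) either pass through as documented empties or
raise typed errors — malformed clonotype rows are dropped and counted
rather than fatal, because bulk exports routinely contain out-of-frame
junctions.

Test problem sizes: oracle-equivalence checks run 200 random instances
of ≤ 20 clonotypes and ≤ 5 donors against brute-force implementations;
recovery checks run 100 seeds of a 3-donor, 120-clonotype study and
1,000 simulated plates of 96 lines; the well-occupancy convergence
check uses 10,000 lines. These sizes give binomial standard errors
comfortably inside the asserted bands while keeping the default suite
around a minute.

## Known limitations

The packaged FVIII precursor reference is a synthetic scaffold (true
residues only inside the 18 packaged peptide windows), so coordinate
validation against arbitrary other peptides requires supplying a real
P00451 FASTA. Clonotype identity is amino-acid level by default;
nucleotide-level identity is supported only insofar as junctions are
carried through. The anchor alignment is intentionally crude for long
interiors; motif analyses at single-position resolution beyond the
anchors should use a dedicated aligner. The immunodominance ranking
treats T-cell line counts as independent units and ignores per-donor
line totals; no normalization for unequal donor sampling depth is
applied.
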