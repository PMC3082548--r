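---
title: "Dye-swap two-colour microarray analysis with one-class SAM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dye-swap two-colour microarray analysis with one-class SAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyeswapr)
```

## The experimental design this package analyzes

The pipeline targets a classic two-colour spotted-array comparison of a
small patient cohort against a pooled reference. Each patient's RNA is
co-hybridized with the pooled control RNA on one slide, then again on a
second slide with the fluorophores exchanged (a *dye swap*), so each
patient contributes a pair of slides with opposite dye orientation. Genes
are spotted in duplicate on every slide. The default synthetic experiment
emulates a 4-patient, 8-slide study with 2,000 genes — a desk-scale
stand-in for genome-wide arrays of ~21,000 probes; all stage outputs scale
linearly in gene count, so nothing in the analysis depends on this choice
beyond runtime.

Dye-swap designs exist because the two fluorescent labels do not incorporate
or fluoresce equally, and the imbalance depends on spot brightness. In MA
coordinates — `A = (log2 ch1 + log2 ch2)/2`, `M = log2 ch1 − log2 ch2` —
this appears as a smooth trend of M on A that is attached to the *channels*,
not to the samples: it has the same sign on both slides of a swap pair even
though the samples switch channels. The synthetic generator reproduces
exactly this structure (`dye_bias_coeffs`, default `M = 0.5·A − 5`), which
is what makes both LOWESS balancing and the dye-swap concordance filter
meaningfully testable against ground truth.

## Stage 1: spot filtering and LOWESS balancing

**Background policy.** Spot tables carry foreground and background per
channel. The working intensity is `max(fg − bg, 1)` by default
(`background = "subtract"`); the floor of 1 intensity unit keeps `log2`
defined for spots at or below background. An `"ignore"` mode uses raw
foreground. Nothing downstream depends on the policy beyond the working
intensities.

**Low-intensity Z-score filter.** Within each slide and each channel, the
log2 working intensities are standardized; a spot is flagged when its
z-score falls below `z_threshold` (default −2) in *either* channel. Spots
near background have unstable ratios, and requiring both channels to be
credible is the conservative reading of removing dim spots "from both
channels". If a channel has zero spread the z-score is defined as 0
everywhere, so degenerate slides flag nothing rather than everything.

**LOWESS normalization.** A robust locally weighted regression
(`stats::lowess`, span 0.3, 3 robustness iterations, locally linear fits)
of M on A is fitted over the unflagged spots of each slide and subtracted:
`M_norm = M_raw − fit(A)`. Normalization is location-only in M — A values
and the spot count are unchanged, and spots are *flagged*, never deleted,
so every exclusion is auditable. The span of 0.3 is standard MA-plot
practice: wide enough that 5% regulated genes do not bend the fit, narrow
enough to track intensity-dependent bias.

**Outlier discarding.** Spots whose final residual exceeds
`outlier_k` residual SDs are flagged `lowess_outlier` and their `M_norm` is
withheld. Two deliberate choices here:

* The residual scale is the *classical SD over all residuals*, not a highly
  resistant estimate. With a MAD-type scale, artifact contamination (and
  genuine regulation) is excluded from the scale estimate, the band
  collapses onto the pure-noise floor, and any gene whose log-ratio sits a
  few noise SDs from zero — which is precisely what a regulated gene looks
  like — is discarded as an "outlier". The classical SD lets heavy
  contamination widen the band, so the rule removes only spots that are
  extreme relative to everything on the slide, including its biology. A
  `scale = "mad"` option is kept for slides where regulation is known to be
  negligible.
* `outlier_k` defaults to 4. Planted artifacts in the synthetic data (and
  scanner artifacts in real data) sit an order of magnitude above the
  noise, while genuine regulation at 3–6 noise SDs must survive; k = 4
  separates these regimes, k = 3 does not once the DE amplitude is about
  4 noise SDs.

A residual scale below 1e−8 is treated as a numerically perfect fit and
flags nothing.

## Stage 2: orientation, duplicate collapse, and the dye-swap filters

Each slide's normalized ratio is oriented to log2(patient/reference):
`M_norm` as-is when the patient is in channel 1, `−M_norm` otherwise.
Duplicate spots are collapsed by the mean of the unflagged duplicates
(median available); a gene is missing on a slide only if every spot was
flagged.

**Concordance (3 SD) filter.** For a swap pair with oriented ratios R1 and
R2, `delta = log2(R1/R2)` should be zero up to noise for a well-behaved
gene regardless of its regulation, because the true ratio cancels. Within
each pair the SD of delta is computed over all genes with both values, and
a gene is dropped for that patient when `|delta − mean(delta)| > 3·SD`.
The rule is applied *centered*: an uncentered reading would make it depend
on a mean offset that the swap design exists to cancel. When the SD is
exactly zero, nothing strictly exceeds it and everything is retained. The
SD is per pair rather than pooled — each pair has its own hybridization
quality. Duplicates are collapsed before this filter so that delta
measures slide-level (hybridization) disagreement, not spot-level noise.

**Cross-patient pattern consistency.** A gene is kept only if its
summarized ratio has strictly the same sign in every patient; a zero has
no sign and drops the gene. Genes missing any patient value are dropped as
missing rather than imputed — requiring a pattern "in all patients"
presumes a value in all patients, and imputing one would invent data.

**Geometric-mean summary.** The per-patient value is the arithmetic mean
of the pair's two oriented log2 ratios — identically the log2 of the
geometric mean of R1 and R2, the natural average for ratios.

Every gene ends in exactly one state: `kept`, `dropped_concordance`,
`dropped_missing`, or `dropped_pattern`, and the run report tallies all of
them, so `called_up + called_down = called_total` and the kept set shrinks
monotonically through the chain by construction.

## Stage 3: one-class SAM

The kept genes' patient values form the test matrix (genes × 4 by
default). For gene *i* with replicate values `x_ij`,

    d_i = x̄_i / (s_i + s0),   s_i = sd(x_i)/√n

the "relative difference": a one-sample t statistic whose denominator is
inflated by the fudge factor `s0 ≥ 0` so that genes with accidentally tiny
variance cannot reach huge scores. With `s0 = 0`, `d` is exactly the
classical one-sample t statistic (this closed-form limit is tested to
1e−10).

**Choosing s0.** Candidates are the percentiles of the `s_i` distribution
from 0 to 100 in steps of 5. For each candidate the genes are binned into
se-quantile windows, the MAD of `d` within each window is computed, and
the candidate minimizing the coefficient of variation of these window
scales is chosen — the value making the spread of `d` most independent of
`s_i`. A fixed user value short-circuits the search.

**Permutation null.** The one-class null hypothesis is mean zero, so the
permutation group is sign assignment: each permutation multiplies every
gene's replicate vector by the same ±1 vector and recomputes `d` with `s0`
held fixed. With `n` replicates there are `2^n` sign vectors; enumeration
is exhaustive whenever `2^n ≤ 4096` (16 at patient granularity, 256 at
slide granularity), eliminating Monte-Carlo error at this design's scale;
otherwise sign vectors are sampled without replacement under the run seed.
The expected order statistic `d̄_(i)` is the mean over permutations of the
i-th smallest permuted `d`.

**Delta table and calling.** For a threshold delta, the upper cutpoint is
the smallest sorted observed `d` whose displacement above `d̄_(i)` reaches
delta (scanning upward from where the expected null crosses zero), and
symmetrically for the lower cutpoint — the cutpoints are asymmetric, as in
the original formulation. Genes beyond the cutpoints are called; each
permutation's false-call count is its number of `d` values beyond the same
cutpoints; the FDR estimate is `median(false calls)/n_called` (times an
optional π0 multiplier, default 1), defined as 0 when nothing is called
and clamped to [0, 1]. The default delta grid contains every distinct
observed displacement, so every achievable calling set appears in the
table. "0% FDR" calling selects the smallest delta whose FDR is exactly ≤
0 — i.e. the median false-call count is zero — and splits called genes by
the sign of `d`.

**Granularity.** By default SAM runs on the summarized patient values
(n = 4), matching a workflow in which geometric means are computed and
then tested. A `granularity = "slide"` mode tests the oriented per-slide
ratios (n = 8, 256 exhaustive sign vectors) for the same kept genes; it
gives a finer permutation null at the cost of treating the two slides of a
pair as exchangeable replicates.

## A known and deliberate limitation: selection before testing

The pattern-consistency filter precedes SAM, and this ordering is part of
the analysis being implemented. It has a real statistical consequence that
users should understand. Under a pure null, a fraction `2·(1/2)^P` of
genes (12.5% at P = 4 patients) pass the same-sign filter by chance, and
*those genes are selected precisely for having replicate values that all
lean one way* — their |mean| is biased upward. The sign-flip permutation
null is computed on the selected matrix but destroys the selection, so the
observed `d` of selected null genes sit systematically above the expected
order statistics. With only 16 sign vectors, of which 14 "mixed" ones
carry little structure, the median false-call count reaches zero at
liberal deltas, and the 0%-FDR call set picks up selected null genes.

The package's own acceptance checks quantify this honestly on synthetic
data: planted-signal recovery is high (~95% of planted genes at the
default conditions), but the empirical false-discovery proportion among
called genes is large (~0.5 at patient granularity, ~0.1–0.15 at slide
granularity), and most pure-null runs call at least one gene at "0% FDR".
A second, smaller effect points the same way even without selection: with
a median-based false-call count, the most liberal zero-FDR delta calls the
single top gene whenever its displacement ranks in the upper half of the
permutation maxima, which happens for about half of pure-null datasets by
exchangeability. These are properties of the method as defined — filter to
same-sign genes, then test against a sign-flip null with a median-based
FDR — not of this implementation; the SAM mechanics are verified against
independent exhaustive enumeration to 1e−12. Users wanting calibrated
error control should treat the 0%-FDR gene list as a ranking, validate
externally (the package's qPCR concordance tools exist for exactly that),
or run SAM before/without the consistency filter.

## Stage 4: over-representation

Called genes are tested against flat gene sets (GMT input) with the
one-sided hypergeometric upper tail: for a set with `total` members in the
universe and `changed` of them called, `p = P(X ≥ changed)` with
`X ~ Hypergeom(|universe|, total, |called|)`. The default universe is the
genes that survived all filters (the set actually eligible to be called);
`universe = "all"` uses every gene on the array. This choice matters —
p-values against the "all" universe are systematically smaller — and is
the main reason published over-representation p-values are hard to
reproduce without knowing the universe used. Raw p-values are reported in
the familiar changed/total layout, with an optional Benjamini–Hochberg
column (off by default, for fidelity to the classic report format).

## Assay quantifications

* **Relative qPCR**: `AU = 2^−(C̄t,target − C̄t,reference)` — the
  efficiency-free ΔCt model, with replicate Ct collapsed by mean (median
  available) and an optional efficiency base `E^−ΔCt`. Only the Ct
  *difference* matters; the invariance is tested.
* **Fold change vs controls**: ratio of group mean AUs; controls map to 1
  by construction.
* **Platform concordance**: Pearson correlation between microarray and
  qPCR fold changes over shared genes, on log2 scale by default so up- and
  down-regulation contribute symmetrically.
* **Doubling time**: `T = interval · ln 2 / ln(signal_t1/signal_t0)`, the
  only growth model identifiable from two timepoints; the exponential
  assumption is explicit, and no-growth inputs are an error rather than a
  negative time.
* **Viability**: reference-corrected OD of treated over untreated wells,
  as a percentage.
* **Incorporation**: counts per minute divided by DNA absorbance.
* **Two-group tests**: classical equal-variance unpaired t (two-tailed) or
  exact-when-possible Mann-Whitney, via `stats::t.test` / `stats::wilcox.test`.

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the pipeline assumes:
duplicate spotting, per-patient dye-swap pairs with a pooled reference,
channel-attached intensity-dependent dye bias, log-normal spot
brightness over a configurable range (the raw-intensity distribution of
real platforms is not modelled from data; log-normal is a modelling
convenience), additive log-scale spot noise, near-background spots, and
slide-level artifacts confined to one slide of a pair. It does not emulate
image-level structure (spot morphology, print-tip or grid effects),
RNA-amplification chemistry, or per-patient biological variance around the
planted effect (planted DE genes have exactly the same true log2 ratio in
every patient). Passing tests on this generator therefore demonstrate the
pipeline's algebra and calibration under its own assumptions, not
robustness to the full messiness of scanner data.

Default study conditions (4 patients, 2,000 genes in duplicate, 5% DE at
|log2FC| = 1, noise SD 0.25, bias `0.5A − 5`, 1% discordant, 2%
low-intensity) are fixed once in `simulation_config()` and used unchanged
by the analysis scripts, the test suite, and `scripts/acceptance.R`; the
acceptance checks average over 20 generator seeds (200 for the null-
calibration rate).

## Numerical conventions

* Working-intensity floor 1; z-scores defined as 0 under zero channel
  spread; "no spots survive" and "too few spots to fit" are errors, not
  empty output.
* LOWESS fit evaluated at duplicate A values via interpolation with
  constant extrapolation at the range ends.
* Concordance SD is the sample SD; fewer than 2 defined deltas is an
  error; SD = 0 retains everything.
* `se + s0 = 0` with nonzero mean is a degenerate-statistic error; with
  zero mean, `d = 0`.
* FDR convention 0/0 → 0 at vacuous deltas; FDR clamped to [0, 1];
  ties in the s0 CV criterion go to the smallest candidate.
* All randomness (generator, sampled permutations) flows from explicit
  integer seeds; identical configuration and seed give byte-identical
  outputs.
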