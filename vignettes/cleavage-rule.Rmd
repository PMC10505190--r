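---
title: "The cleavage rule: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cleavage rule: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavr)
```

## The model and its assumptions

`cleavr` analyzes variant-by-target cleavage-activity matrices of
increased-fidelity SpCas9 nucleases under a latent-threshold model. Each
target carries an activating sequence contribution `c_t`, each variant an
inhibitory fidelity level `f_v` with the wild type pinned at `f = 0`, and
each mismatched spacer position a penalty `m_p >= 0`, all in the same
arbitrary activation units. A variant cleaves a target iff `c_t > f_v`,
and cleaves a single-mismatch off-target iff `c_t > f_v + m_p`. The
symbols and the linear-threshold formalization are this package's choice:
the underlying biological rule is qualitative (the contribution, the
fidelity mutations and the mismatches act on the same activation step),
and no functional form or units are established for it. Everything
downstream only uses the induced *orderings* and the threshold structure,
so any monotone reparameterization of `c`, `f`, `m` describes the same
data.

Assumptions worth stating explicitly:

* `c_t` is (approximately) a fixed property of the target, independent of
  which variant probes it;
* `f_v` is a fixed property of the variant, shared across targets;
* cleavage is all-or-nothing at the call level: cleaved cells scatter in
  a broad wild-type-normalized band rather than decreasing gradually with
  fidelity, non-cleaved cells sit near zero. Consequently the model
  predicts *membership* of the cleaved class, not the activity value
  within it.

## From raw activities to calls

Raw per-replicate percentages (EGFP-negative cells, or indel read
percentages) are processed per (experiment, target) block: the mean
background from dead-Cas9 / non-targeting controls is subtracted from
every treatment mean — including wild type, which is a treatment like any
other — then each variant is divided by the background-subtracted
wild-type value. Negatives clip to zero; values are quantized to two
decimals with half-up rounding, and the cleavage call threshold
`theta = 0.20` is applied to the *rounded* value, so a raw 0.195 calls as
cleaved. Replicates are averaged before normalization by default (the
heatmap convention); per-replicate normalization is available behind a
flag. Cells where wild type does not exceed background are undefined and
propagate as `NA`, never as zero.

## Ordering and the staircase boundary

Variants are ordered by cleaved-target count (ties: mean normalized
activity, then id). Targets are ordered by cleaved-by count with outlier
minimization taken into consideration. The staircase boundary assigns
each variant the prefix cutoff minimizing its own misclassified cells
(ties to the smaller cutoff); cells disagreeing with the boundary are
outliers, and the pooled confusion matrix gives sensitivity, specificity
and their geometric mean. A per-variant ROC scores targets by
cleavability rank and sweeps rank cutoffs; the AUC is the tie-aware rank
(Mann–Whitney) probability that a cleaved target outranks a non-cleaved
one, and agrees with the trapezoid area under the curve to numerical
precision.

Two designs here were genuinely open:

* **Boundary mode.** Fixing the boundary at the variant's observed
  cleaved count ("count-matched") forces paired false positives and
  negatives whenever a row has one interloper; minimizing
  misclassifications reproduces the single-outlier readings of published
  maps. Both modes are provided; minimization is the default.
* **Target ordering vs. global optimality.** A strict count-descending
  primary key is *not* always compatible with the global outlier minimum:
  there exist small dense matrices whose optimal order must promote a
  less-cleaved target (we keep a verified 4x6 counterexample in the
  decisions record). Since outlier minimization is part of the ordering's
  purpose, `order_targets` enumerates all permutations exhaustively on
  small instances — with the count-descending order winning every tie, so
  staircase-consistent data always come out in count order — and on large
  instances runs count-primary tie-block search followed by a
  deterministic cross-block refinement that only ever accepts a strict
  improvement. All search is deterministic (fixed scan order, no RNG), so
  orderings are bit-reproducible. Boundary monotonicity across variants
  is *not* enforced (published maps satisfy it; a warning reports
  violations), but an enforcing flag exists.

## The synthetic generator: what it emulates, and what not

`sample_model()` draws `c_t ~ Uniform(0, 10)` and spaces `f_v` evenly
over `[0, 10]` — a graded panel in which each variant cleaves a distinct
expected fraction of targets, mimicking a fidelity series with wild type
at the bottom. Defaults state the emulated world: 50 reporter targets, 20
variants (wild type + 19 nucleases), biological triplicates, 2% dead-Cas9
background, 50% raw wild-type activity, replicate jitter of 1 percentage
point, cleaved cells uniform in 0.70–1.20 of wild type (the typical
scatter band; a 0.75–1.25 band is a matter of changing one argument),
non-cleaved cells at `|N(0, 0.03)|` capped below the call threshold, and
three PAM-distal mismatch positions with penalty 2 units probed as
three-guide mixtures. The penalty default (20% of the contribution range)
makes off-target cleavage common for low-fidelity variants and absent for
target-matched ones, which is the regime the screen operates in; no
published value exists for it, and it is configurable.

Simulated true activities are converted *back* to raw percentages with
background and replicate noise, so every test exercises the full
normalization path rather than feeding normalized values directly. A
single global seed feeds a counter-based substream per (variant, target,
replicate): subsetting targets or variants never changes other cells.

What the generator does **not** emulate: sequence-level determinants of
`c_t` (no nucleotide model), variant-specific mismatch-position
interactions (one penalty per position, the same for all variants),
saturation and expression-level artifacts, and day/cell-line effects. A
green round-trip test therefore establishes that the pipeline recovers a
threshold world faithfully — not that real data obey that world.

Recovery is scored by Spearman concordance between true parameters and
recovered orders in two flavors: tie-excluded (exactly 1.0 on noiseless
data, but based on few targets when count-tie blocks are large) and
midrank (`*_concordance_all`, using every target at its block midrank;
the calibrated quantity for noisy runs, >= 0.9 in the stated world).

## The two-step screen

Step 1 measures wild type plus the three panel members whose cleavable
fractions are nearest 3/4, 1/2 and 1/4, and brackets the transition
between the last sufficiently active probe and the first insufficient
one. Step 2 measures the untested variants inside the bracket; the
target-matched variant is the highest-fidelity one reaching the selection
threshold, and up to two top candidates are nominated for external
genome-wide off-target confirmation. The step-1 threshold defaults to the
cleavage-call level (0.20) and the selection threshold to 0.50
("sufficiently active" for confirmation-grade editing); both are
application-dependent and exposed. Under a hard-threshold oracle —
activities either in the cleaved band (>= 0.70) or near zero, so both
thresholds agree — the two-step selection provably equals the full-panel
scan, and on a 17-member panel uses at most `4 + fine-interval` assays
(<= 10 in all tested worlds). Non-monotone measurements (noise) are
resolved by trusting the contiguous active run from the bottom of the
panel, with a warning.

## Kinetics

In vitro plasmid-cleavage time courses are fit per replicate with
`y(t) = A exp(-t/tau) + c`, `k = 1/tau` in 1/s. The plateau is fixed at
zero by default — the assay follows consumption of intact circular
plasmid under single-turnover conditions — with a free-plateau flag for
incomplete cleavage; published fits do not state which was used, so
neither mode claims to be "the" published one. Initialization is a
log-linear regression (exact on noiseless data), refined by `nls` (port)
with a Nelder–Mead fallback, unweighted (no densitometry error model is
available). Non-decreasing series are flagged `no_decay` with `k` unset
rather than fit. Rescaling time rescales `k` by the exact inverse;
noiseless recovery is exact to well below 1e-6 over at least four decades
of `k`. The two-group rate comparison is a thin, routine-statistics
wrapper: Shapiro–Wilk normality screen choosing Welch's t vs. exact
Mann–Whitney, both available explicitly.

## Amplicon counting

Coordinates are 0-based half-open internally; the cut site is the
inter-base offset 3 nt upstream of the PAM (between protospacer positions
17 and 18), and reports are 1-based. Eligibility requires >= 75% of the
first 20 reference bases covered and matched (>= 15/20; the boundary is
kept). The counted indel event is a *gap operation* — substitutions never
qualify, and substitutions elsewhere in an eligible read do not
disqualify it; this reading of "indels without mismatches" is a
documented interpretation. Each gap is reduced to its placement span,
from left-normalized start to right-normalized end against the reference,
and a read is indel-positive when any span overlaps cut ± 2 bp. Anchoring
on the span rather than the leftmost coordinate alone is deliberate: a
leftmost-only rule is strand-asymmetric for multi-base deletions (a 3 bp
deletion starting at the cut maps, on the reverse complement, to one
ending at it), and span overlap makes every count invariant under
reverse-complementing reads and reference together. The indel frequency
divides by *total* reads (the published formula), with an eligible-reads
denominator available for sensitivity analysis. dsODN tag integration is
counted by exact, case-insensitive substring match of either 15-mer
center fragment of the GUIDE-seq tag; desired-edit (HDR) reads must carry
every programmed substitution and no window indel. Read pairs are counted
as independent reads (mate-aware merging is out of scope and the read
simulator emits single fragments).

## Numerical choices and degenerate inputs

* Half-up two-decimal rounding (base R rounds half to even), with a 1e-9
  guard against binary representation error.
* Strict inequality `c > f` defines cleavage; exact ties count as
  not-cleaved (measure-zero under continuous contributions).
* `theta` outside (0, 2] is rejected; all-cleaved or all-non-cleaved maps
  yield flagged `NA` G-means/AUCs rather than 0 or 1.
* Empty read sets tally to zero frequencies with an `empty_input` flag.
* Decay fits with fewer than 3 points, non-increasing time, or fractions
  outside [0, 1] are rejected with specific errors.

## Known limitations

* The ordering search is exact only on small instances; large maps get a
  deterministic local optimum (count-primary plus refinement), which
  matched the exhaustive oracle on every tested instance but carries no
  global guarantee.
* The latent model cannot and does not predict `c_t` from sequence;
  nothing here claims which sequence features drive cleavability.
* The mismatch generator applies one penalty per position for all
  variants and both simulated mixture outcomes; real mismatch effects
  vary with sequence context.
* GUIDE-seq site discovery, read alignment and flow-cytometry gating are
  out of scope: the package consumes aligned reads and per-replicate
  percentages.
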