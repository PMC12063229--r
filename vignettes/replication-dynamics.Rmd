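---
title: "Calling replication dynamics from BrdU gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling replication dynamics from BrdU gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifork)
```

# The measurement model

A nanopore base caller reports, for every thymidine position of an aligned
read, the probability that the position carries BrdU. When asynchronous
cells are labelled with stepwise-increasing BrdU (`label_schedule()`:
+0.5 µM every 2.5 min to 12 µM, then a 60-min hold), DNA synthesized later
in the labelling period incorporates more analog. A replication fork
moving rightward therefore leaves a left-to-right *rising* incorporation
profile on the reference; a leftward fork a falling one; an initiation
event a V-shaped minimum; a termination an inverted V.

Three small parametric models connect replication kinetics to the observed
probabilities:

* **Incorporation** (`incorporation_model()`): the substituted fraction of
  thymidines in DNA made at medium concentration *c* follows a saturating
  hyperbola `f(c) = f_max · c/(c + K)`. The defaults `K = 1.7822` µM and
  `f_max = 0.7659` are the unique hyperbola through the two observed
  anchors — modal incorporation of 35 % at 1.5 µM and 65 % at 10 µM — and
  are solved in closed form, not fitted.
* **Emission** (`emission_model()`): each thymidine's probability is drawn
  from a background Beta(1, log₂(1/fpr)) component, or, with weight equal
  to the local incorporated fraction, from a BrdU
  Beta(log₂(1/fnr), 1) component. These shapes make the tail identities
  exact: an unsubstituted position is called (probability ≥ 0.5) at
  exactly the false-positive rate (default 0.001), a substituted one
  missed at exactly `fnr_at_full` (default 0.02), so the expected call
  rate at incorporated fraction *f* is `f(1 − fnr) + (1 − f)·fpr`
  identically. Setting either rate to 0 switches the component to a
  uniform half-interval (noise-free limit).
* **Replication kinetics** (`genome_model()`, `sample_molecules()`):
  origins fire from focused zones (per-molecule Bernoulli) and a dispersed
  Poisson background (default 10⁻⁵/bp, i.e. a 100-kb mean inter-origin
  distance, matching single-molecule estimates), and launch two forks at
  constant speed (default 1500 bp/min — not directly measured by the
  labelling design, but consistent with mammalian fork rates and with the
  ≈3.75 kb a fork travels per 2.5-min concentration step). The
  replication time of a position is the first-passage time
  `min_k(τ_k + |x − x_k|/v)`; candidate origins that another fork would
  reach before their own firing time are passively replicated and pruned,
  so realized initiation counts sit below the nominal Poisson intensity —
  the generator reports both.

## Phases, strands and what "nascent" means

Molecule phases emulate an asynchronous culture: S-phase entry offsets are
uniform over `cycle_length − s_phase_duration` (defaults 20 h and 8 h),
centred on the label start so the label meets molecules at every
replication stage; origin firing times are i.i.d. uniform across the
molecule's S phase. Two strand-level effects are modelled because they
dominate the observed nascent fraction: sequencing reads either strand of
a replicated duplex, so half the reads are unlabelled templates
(`parental_strand_prob = 0.5`), and a `quiescent_fraction` (default 10 %)
of molecules comes from non-cycling cells. Under a constant label lasting
one cell cycle this yields roughly 40 % nascent reads (≥ 5 % BrdU), the
fraction observed experimentally; under the 2-h stepped label, only the
minority of molecules replicating during those 2 h carry gradients.

The simulator deliberately does **not** emulate: raw signal or
base-calling error structure beyond the probability mixture; sequence
context (thymidines are placed i.i.d. at density 0.29, which is all the
290-T windowing sees); a replication-timing program (zones fire with one
probability, not earlier); fork stalling, variable fork speed, or
sister-strand effects. Passing tests therefore certify the inference
machinery under these idealizations, not performance on real signal-level
artifacts.

# The fork caller

1. **Windowing** (`window_fractions()`): consecutive, non-overlapping
   blocks of exactly 290 thymidines; the trailing remainder is dropped
   (independent fixed-size windows, no short tail window). The window's
   genomic interval is `[first T, last T + 1)`. The per-window fraction of
   calls at the ≥ 0.5 threshold is the signal. (The operative definition
   is ≥; at float precision the distinction from > is immaterial, and the
   threshold is configurable.)
2. **Differentiation** (`tv_derivative()`): the window series, scaled to
   percent, is differentiated by total-variation regularized numerical
   differentiation — minimize `α·TV(u) + ½‖Au − (y − y₁)‖²` with *A* the
   trapezoidal antiderivative on the unit window grid. Windows are treated
   as unit-spaced by index; genomic mapping happens after segmentation.
   The ε-smoothed problem (ε = 10⁻⁶) is solved by lagged-diffusivity
   fixed-point iterations `(α DᵀE_k D + AᵀA)u = Aᵀ(y − y₁)`,
   `E_k = diag(1/√((Du_k)² + ε))`. Fifty iterations are ample for
   window-series signals (hundreds of points); the iteration is
   deterministic, and on small adversarial instances it converges to the
   same minimizer as a generic dense convex solver (asserted in the test
   suite to 10⁻³ RMS).
3. **Segmentation** (`segment_forks()`): maximal runs with derivative
   > +1 percent/window are rightward forks, < −1 leftward. Thresholds of
   magnitude 1 are meaningful only on the percent scale — on the raw 0–1
   fraction scale a unit derivative is unattainable — so percent per
   window is the package's derivative unit, with scale and thresholds
   configurable.
4. **Pairing** (`pair_events()`): adjacent divergent (left-then-right)
   fork calls define an initiation site over the inter-fork gap, adjacent
   convergent calls a termination site; the gap width is the site's
   resolution and sites < 5 kb (strict) are the high-resolution set.
   Abutting forks are widened to a ≥ 1 bp gap. Unpaired edge forks
   produce no events; initiations and terminations therefore strictly
   alternate along a read. The caller runs on nascent reads only
   (configurable), since parental reads carry no gradient.

## Calibrating α and the run-length filter

Neither the regularization weight nor a minimum segment length is given by
the method's published description, so both were calibrated on the
simulator, against three requirements: (i) a noiseless linear ramp must be
differentiated essentially exactly — true for *any* α, because a constant
derivative has zero total variation, so this anchors nothing by itself;
(ii) flat signal carrying the binomial noise of a 290-T window
(SD ≈ 3 percentage points at mid incorporation) must essentially never
produce a fork call — plateau regions of fully-labelled DNA are abundant,
and every spurious call there carries a coin-flip direction that poisons
ensemble statistics; (iii) planted initiations with resolvable gradients
must be recovered. Small α (≲ 1) fails (ii) catastrophically: the
derivative chases noise and the majority of flat stretches exceed the
thresholds somewhere. Large α erodes (iii) by shrinking true slopes. The
shipped defaults, `alpha = 5` with `min_segment_windows = 7`, give a
< 2 % spurious-call rate per 100 flat windows, exact ramps, and full
recovery of resolvable planted events; both remain configurable, and the
calibration is re-asserted by the test suite on every run.

## Which initiations are resolvable at all

Because incorporation saturates with concentration, the per-window
gradient of a fork born at concentration *c₀* scales like
`1/(c₀ + K)²`: it is ≈ 5.7 percent/window at the ramp start and falls
below the ±1 calling threshold once the concentration at replication
passes ≈ 2.5 µM — only the early ramp is temporally resolvable, and the
hold is entirely flat. `eligible_initiations()` encodes this from ground
truth: an event is deemed recoverable when each flanking fork has at
least `min_windows` (default 10) windows of room and the expected mean
gradient over those windows, *measured from the origin outward*, clears
the calling threshold plus the total-variation shrinkage bias
(≈ `2α/min_windows`, the amount by which a TV-regularized estimate
understates a length-`min_windows` segment's slope). Anchoring at the
origin matters: an origin that fired long before labelling has
perfectly good gradients tens of kilobases away, but its minimum is wide
and cannot be localized — exactly the wide-minima ambiguity expected for
early-firing origins. Recovery experiments in the test suite condition on
this eligible set; molecules are simulated with the `"labelling"` phase
mode (replication overlapping the label window), since molecules
replicating outside the label carry no information for this purpose.

# Permutation statistics

**RIGR** (`rigr()`) is the number of initiation sites whose width overlaps
a (merged) region set by strictly more than 50 %, divided by the gigabases
of read footprint overlapping that set (per-base coverage semantics, like
`samtools bedcov`). The null rebuilds the statistic 1000 times by placing
the same number of sites, with the same lengths, uniformly inside a
random subsample of the read footprints (default fraction 0.8) and
dividing by the subsample's coverage. Two properties of this null are
worth knowing:

* With subsampling, the null's expected density exceeds the observed-side
  expectation by exactly `1/fraction` (the same site count lands in fewer
  read bases), so enrichment p-values are conservative by ≈ 25 % at the
  default. Setting `read_subsample_fraction = 1` gives the exchangeable,
  exactly calibrated regime; the bias factor is asserted as a property
  test.
* The add-one estimator `p = (1 + #{null ≥ obs})/(N + 1)` can never be 0
  and is conservative when the discrete count statistic ties with null
  draws. The result also carries a mid-p variant
  (`p_enrichment_mid`, ties counted half), which is the calibrated choice
  for simulation studies; the reported headline p remains the add-one
  form.

**Relative distance** (`relative_distance()`): for a site midpoint between
two consecutive region midpoints, `d = min(d_left, d_right)/gap ∈ [0, 0.5]`
(0 at a region midpoint, 0.5 exactly between two). Independent placement
gives a flat histogram; colocalization piles mass near 0. Sites outside
the outermost midpoints, and chromosomes with fewer than two regions, are
skipped with a warning. Midpoint (not edge) distance is used, matching the
established relative-distance test; an edge variant would differ only for
wide regions.

**RFD ensembles** (`rfd_ensemble()`): each fork call contributes its
direction to every bin its interval overlaps (membership, not
length-weighting — configurable by bin size); `RFD = (R − L)/(R + L)`,
undefined (NA) in uncovered bins. The null band flips each fork's
direction with probability ½, 1000 times; swapping all directions negates
the profile exactly, which is asserted as a property.

**Transcription context** (`fork_directionality_at_anchors()`,
`gene_body_rigr()`, `split_genes_by_expression()`, `meta_profile()`):
anchors are flipped so transcription reads left-to-right, making
"co-directional" = rightward after flipping; genes are split at the median
expression rank with ties broken by gene id (stable) and the extra gene of
an odd count going to the low half; meta-profiles average a bedGraph
signal in 1-kb bins ± 100 kb around anchor midpoints, with NA (excluded)
where the track is undefined, and the geometric mean computed on
`value + 1` with the pseudocount removed afterwards.

# Numerical and degenerate-input choices

* Coordinates are uniformly 0-based half-open across every interface;
  BED/bedGraph/detect round-trips are lossless at six decimals.
* `tv_derivative()` rejects signals shorter than 4 windows or containing
  non-finite values; reads with fewer than 4 windows yield empty calls.
* A constant stratification track cannot be split into quantile strata:
  everything is assigned to stratum 1 with a warning.
* Zero-width inter-fork gaps are widened to ±1 bp so site resolution is
  at least 1 bp.
* Random placement of a site longer than every footprint is an error, not
  a silent retry.
* The scale identity (y, α, ε) → (cy, cα, c²ε) maps the solver's iterates
  exactly; with ε held fixed the homogeneity `u(cy, cα) = c·u(y, α)` holds
  to O(ε).

# Problem sizes in the shipped tests

The suite validates at sizes chosen to exercise every code path while
completing in minutes on one core: 200 molecules of 150 kb for recovery
(about 9 M simulated thymidines), 200 replicate datasets × 199
randomizations for p-value calibration, 10⁴ sites for relative-distance
flatness, 50 instances of n ≤ 32 for oracle equivalence, and 10⁵+
thymidines for emission calibration. All are configuration, not limits:
every generator and statistic takes its sizes as arguments.

# Known limitations

* Fork speed, firing-time distributions and the emission mixture shapes
  are weakly constrained by the anchors used; all are configuration, and
  conclusions driven by them should be checked for sensitivity.
* Only early-ramp-firing initiations are localizable (see above); genome
  -wide initiation catalogues from this design are therefore samples, not
  censuses, and density statistics (RIGR) are the right currency.
* The caller does not estimate fork speed, detect pausing, or handle
  multi-analog labelling.
* modBAM ingestion is not implemented; the detect text format is the
  ingestion surface.
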