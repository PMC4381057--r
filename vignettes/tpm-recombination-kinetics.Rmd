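---
title: "Modeling and inferring recombination kinetics from TPM traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inferring recombination kinetics from TPM traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmkin)
```

## The model

A tethered particle motion (TPM) recombination assay watches one DNA
molecule at a time. The package models the reaction as a continuous-time
Markov chain over seven states: free substrate `U`, non-productive
complex `NP`, pre-synaptic complex `PS`, wayward synapse `WW`, long-lived
wayward synapse `LLWW`, recombinogenic synapse `RS`, and the absorbing
product `PROD`. Binding out of `U` is pseudo-first-order: the two
channels compete with rates $k_{NPf}[E]$ and $k_{PSf}[E]$, where $[E]$ is
the recombinase concentration (50 nM for Cre presets, 200 nM for Flp
presets, the assay concentrations). All other transitions are first
order. Waiting times are exponential and branching probabilities are
proportional to rates, so `simulate_trajectory()` is an exact Gillespie
realization, not a discretized approximation.

Assumptions worth stating explicitly:

* **No pre-synaptic dissociation.** `PS` exits only into synapsis. The
  rate tables that parameterize the presets contain no `PS -> U`
  constant, so adding one would be an invented parameter; the cost is
  that in long simulations every bound molecule eventually synapses,
  which inflates late-pathway occupancy relative to a 30-min experiment
  with unbinding.
* **Wayward decay branching.** A decaying wayward synapse returns to
  `PS` or to `U`; both fates occur but their ratio is not quantified
  anywhere we can anchor to, so `p_ww_to_ps` defaults to 0.5 and is a
  scheme parameter.
* **Holliday-junction reversal.** For head-to-tail sites the slow phase
  of the synaptic decay is interpreted as junction resolution back to the
  parental configuration; the presets therefore set `k_REV = k_REC` for
  the recombination-competent Cre variants and `k_REV = 0` for Flp, where
  reversal is a minor process.
* **Phenomenological amplitudes.** Bead/polymer physics is out of scope.
  States emit Gaussian amplitudes around three levels; a completed
  product emits low for head-to-tail sites (excision) and high for
  head-to-head sites (inversion conserves length), which is also the SDS
  logic of `apply_sds()`: only `RS` at quench (trapped Holliday junction,
  either orientation) or `PROD` with head-to-tail sites stays low.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `duration` | 1800 | s | the assays quench with SDS at 30 min |
| `enzyme_concentration` | 5e-8 / 2e-7 | M | assay concentrations of Cre / Flp |
| `frame_interval` | 0.1 | s | acquisition rate is not published; 10 Hz is typical of camera-based TPM and resolves every tabulated rate (fastest ~1 s⁻¹) |
| `mean_high`, `mean_low` | 81, 44 | nm | substrate and synapsed amplitudes, anchored to the published per-protein table |
| `mean_mid` | 65 | nm | the intermediate-high level is never tabulated; chosen between the anchored levels with > 3 frame-SD clearance above the low threshold so three-state calling is well posed |
| `sd_frame` | 8 | nm | per-frame noise, chosen so per-molecule state means reproduce the published ~4-6 nm between-molecule scatter after averaging |
| `sd_molecule` | 4 | nm | between-molecule (bead/tether) offset, same anchor |
| `thresholds` | midpoints | nm | transparency: midpoints between adjacent emission means |
| `min_dwell` | 2 | s | observability dead time; also the left-truncation point for fitting |
| hysteresis `band` | 2 | nm | suppresses threshold chatter without moving clean edges |

## Synthetic data: what it emulates, what it does not

The generator emulates amplitude *levels*, Gaussian frame noise, fixed
per-molecule offsets, the 30-min window, the SDS end point, and state
transitions at the tabulated rate constants. It does **not** emulate
drift, stuck beads, anisotropic tethers, blur/aliasing from finite
exposure, or non-Gaussian excursions of real bead tracking. A green test
therefore establishes that the inference chain is correct *given the
emission model*, not that it is robust to every artifact of real traces
(the pipeline accepts external traces, but they should be pre-filtered).

Reproducibility: every ensemble derives per-molecule seeds from the
master seed by a fixed counter scheme (`master * 48271 + molecule * 7919 +
stream * 104729, mod 2^31 - 1`, one stream for the trajectory and one for
rendering), so molecule $i$ is identical whether simulated alone or in
any larger ensemble.

## Numerical choices

**Segmentation.** Frames are classified against two cutoffs with a ±2 nm
hysteresis band (ties keep the current state), a majority filter at the
`min_dwell` scale removes isolated noise flips without moving clean step
edges by more than one frame, and runs shorter than `min_dwell` are
absorbed into the preceding confirmed segment. Dwells shorter than
`min_dwell` are unobservable by construction, so the MLE fitter treats
`min_dwell` as a left-truncation point (for the exponential this reduces
to subtracting it from every dwell).

**Per-molecule offset.** With `sd_molecule` ≈ 4-5 nm a few percent of
molecules sit with one level near a fixed threshold, which chatters. When
an emission model is supplied, `segment_trace()` first estimates the
molecule's offset by EM on a three-component Gaussian mixture with known
level means (a hard min-distance profile was rejected: with frame noise
comparable to half the level spacing its maximum parks the template
*between* levels). Two regularizers enter: a Gaussian prior with the
between-molecule SD, and an anchor on the median of the first ~2 s of
frames — every molecule starts unbound when protein is added, which
breaks the label-switching degeneracy of a trace that occupies a single
level. Segment mean amplitudes are reported on the raw scale so
between-molecule variability stays measurable.

**Binned fits.** Histogram of uncensored dwells, bin width `max(t)/20`
by default, counts fitted at bin centers by unweighted least squares
(the histogram method of the source assays); for two components the
amplitudes are profiled out by linear least squares (variable
projection) and only the two log-rates are optimized, seeded from a
coarse rate grid. Note an identifiability limit: a fast phase whose mean
dwell is smaller than one bin cannot be recovered by any least-squares
fit at that binning — choose `bin_width` ≈ half the fast time constant
for two-phase histograms.

**Unbinned MLE.** One component is closed-form ($k = n_{unc}/\sum t$,
censored dwells contributing their full observation time); two
components maximize the censored, left-truncated mixture likelihood from
eight moment- and quantile-matched starts, with canonical ordering
$k_1 \ge k_2$. The published "residual" diagnostic of the MLE analysis
is not defined anywhere, so the fit reports the log-likelihood and a KS
distance, clearly labelled, instead of reproducing an unknown quantity.

**Model selection.** Two processes are accepted only if the minor
amplitude is ≥ 0.05, the rates are ≥ 3-fold apart, and the fit improves
materially (ΔR² ≥ 0.03 binned; likelihood-ratio p < 0.01, 2 df, MLE).
The first failed guard is recorded, mirroring how near-degenerate
two-exponential fits (minor amplitude below 1%) are rejected in the
source analyses.

**Census normalization.** Fractions are reported among responded
(recombinase-bound) molecules. The mutually exclusive final call uses
the furthest-progressed state (synapse outranks a non-productive
episode). That rule cannot recover a *branching* fraction when molecules
rebind within the window — a molecule whose first complex was
non-productive but which later synapses is final-called wayward — so the
census also reports `frac_first_non_productive`, the fraction of
responded molecules whose first bound complex was non-productive, which
is the quantity that estimates how binding partitions between the NP and
PS channels.

**Statistics.** Orientation comparisons use Welch's unequal-variance
two-sample test, two-sided: group SDs differ and Ns are small in the
amplitude tables, and the source reports only "P < 0.05" without naming
a test — Welch is a declared choice, not an inference about the original
analysis. Bootstrap errors are nonparametric over dwells. Stochastic
"≥ 90% of seeded repeats" checks in the test suite are assessed with a
one-sided binomial test at α = 0.01 so that verdicts reflect the
property, not repeat-sampling noise (the Flpe wayward/recombination pair
sits at a true joint-recovery probability of ~0.91 for the efficient
MLE, right at the target rate).

## Design decisions that were genuinely open

* **Cre(K201A) long-lived wayward calls** are made by thresholding the
  low dwell at a configurable cutoff (suggested: `3 / k_WWd` of the fast
  class), because the original analysis separates the two populations
  only through the double-exponential fit, which gives no per-molecule
  assignment.
* **Head-to-head ambiguity** (a decaying low state may be a wayward
  synapse or a completed inversion) is preserved as an annotation on the
  label, never silently resolved.
* **Wild-type NP rates.** The pathway tables give no NP
  formation/dissociation constants for the wild types; the Cre preset
  uses the values reported alongside the R173A assay, and the Flpe
  preset derives `k_NPf` from the ~3% non-productive share of bound
  molecules. The tyrosine-mutant presets reuse the wild-type binding
  constants, since loss of the nucleophile does not block the
  pre-chemical steps.
* **RS at quench reads low for either orientation** (trapped Holliday
  junction) — implied by the SDS logic but not stated; modeled as low.

## Known limitations

* Rates much faster than ~1/frame_interval are invisible; Cre pre-synaptic
  dwells (mean ~0.8 s at the tabulated rates) fall below the 2 s dead
  time, so Cre traces typically jump high→low and the pre-synaptic label
  is inferred rather than observed — exactly as in the real assay, where
  transient pre-synaptic associations could not be resolved.
* The binned least-squares estimator at 300 dwells has ~11% relative SD
  (simulation oracle), so single-fit recoveries tighter than ~20% should
  use the unbinned MLE.
* Offsets beyond ~half the smallest level spacing are unresolvable for
  single-level traces in principle; the t = 0 anchor handles the common
  case but a molecule that binds within the first seconds *and* never
  changes state again can be mis-anchored.
* No HMM backend: thresholds-with-hysteresis is the reference path by
  design; an HMM would improve marginal-SNR traces at the cost of
  transparency.
```{r session}
sessionInfo()
```
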