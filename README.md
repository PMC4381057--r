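# tpmkin

Single-molecule tethered particle motion (TPM) kinetics of site-specific
DNA recombination.

## The problem

In a TPM recombination assay a linear DNA molecule carrying two
recombinase target sites (loxP for Cre, FRT for Flp) tethers a polystyrene
bead to a cover slip. The bead's Brownian-motion (BM) amplitude reports
the effective tether length, and therefore the reaction stage:

| BM amplitude | species |
|---|---|
| high (~81 nm) | free substrate |
| intermediate-high | recombinase-bound, bent sites: **non-productive (NP)** or **pre-synaptic (PS)** complex |
| low (~44 nm) | synapsed sites: **wayward (WW)**, **long-lived wayward (LLWW)** or **recombinogenic (RS)** complex; Holliday junction or excision product |

An SDS challenge at the 30-min quench strips protein from DNA: only
molecules that performed covalent strand exchange (a trapped Holliday
junction, or the excision product of head-to-tail sites) retain the low
amplitude. The kinetic scheme is a continuous-time Markov chain

```
        k_NPf[E]             k_RSf          k_REC
   U  <==========>  NP   PS ------> RS  ----------> PROD (absorbing)
   |     k_NPd           ^  \          <---- k_REV
   |  k_PSf[E]           |   \ k_WWf / k*_WWf
   +-------------> PS    |    v
                         +--- WW / LLWW     (k_WWd / k*_WWd; decay returns
                                             to PS or U with prob. p)
```

with second-order binding constants `k_NPf`, `k_PSf` (M⁻¹s⁻¹, multiplied
by the enzyme concentration) and first-order rates (s⁻¹) elsewhere. Dwell
times in each amplitude state are exponential (or exponential mixtures),
so rate constants are estimated from dwell-time distributions by
single/double-exponential fits — binned least squares on histograms, or
unbinned maximum likelihood with right censoring at the quench.

The package provides, per module:

* **simulator** — exact Gillespie realizations of the scheme, rendering to
  noisy amplitude traces, SDS readout, reproducible ensembles, presets for
  Cre, Flpe and their catalytic pentad / tyrosine mutants populated from
  the published rate tables;
* **segmentation** — three-state threshold calling with hysteresis, a
  min-dwell observability filter and per-molecule offset correction;
  dwell extraction with censoring; amplitude statistics;
* **classification** — per-molecule complex taxonomy and ensemble census
  normalized to the recombinase-bound fraction;
* **kinetics** — binned and unbinned 1-/2-component exponential fitting,
  model selection, second-order conversion, bootstrap errors;
* **geometry** — synapse-amplitude comparisons across site orientations
  (Welch test) and the per-protein amplitude summary table;
* **pipeline** — end-to-end orchestration plus a CLI
  (`inst/cli/tpmkin.R`) with `simulate`, `segment`, `fit`, `census`,
  `report` and `validate` subcommands.

## Worked example

Simulate the Flpe(R308A) mutant (synapsis-competent but
cleavage-inactive) for 30 min at 200 nM and run the full inference chain:

```r
library(tpmkin)

rc <- run_config(preset = "Flpe(R308A)", n_molecules = 80, seed = 11)
en <- simulate_ensemble(rc$scheme, rc$emission, rc$config, 80, seed = 11)
an <- run_analyze(en, rc)
an
#> complex census: 80 molecules, 80 responded (100%)
#>   non_productive       0.000
#>   pre_synaptic         0.000
#>   wayward              1.000
#>   long_lived_wayward   0.000
#>   recombinogenic       0.000
#> binding: k_obs = 0.0135 s^-1, k2nd = 6.77e+04 M^-1 s^-1 (n = 79)
#> low-state dwell fits:
#> <exponential_fit 1-component, unbinned_mle, n = 586>
#>   k1 = 0.01642 s^-1 (A1 = 1)
#>   logLik = -2866.144  KS = 0.028
#> model selection: 1 process(es) — two-component fit degenerate or failed
```

Reading the numbers: every responded molecule ends as a wayward synapse —
correct for a cleavage-dead mutant, which can never retain the low
amplitude through SDS. The low-state exit rate `k1 = 0.0164 s⁻¹` recovers
the preset's wayward-decay constant `k_WWd = 1.7e-2` within 4%, and the
pseudo-first-order binding rate divided by concentration
(`6.8e4 M⁻¹s⁻¹`) recovers `k_NPf + k_PSf = 7.3e4` within 7%. Model
selection correctly calls a single decay process. Against the simulator's
ground truth the segmentation is 99.8% accurate per frame
(`frame_accuracy(en, an$segmentations)`).

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tpmkin.R", package = "tpmkin"))')" \
    simulate --preset Cre --n 50 --seed 7 --out run1
```
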