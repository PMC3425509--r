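# polyrec

Measuring cation-dependent DNA-polymerase fidelity landscapes from
barcoded primer-extension deep sequencing — simulation, read processing,
misincorporation calling, transfer-function estimation, error statistics
and information-theoretic summaries, as one tested R package.

## The problem

An error-prone DNA polymerase copying a known template writes a record of
its chemical environment: divalent cations (Mn²⁺, Mg²⁺, Ca²⁺) modulate its
misincorporation rate, so the density and identity of wrong bases in the
product strand encode the cation concentration present during extension.
Turning this into a measurement device requires the *transfer function*
`cation concentration → misincorporation rate`, resolved by template
position, template base and base-to-base transition, together with the
statistical structure of the errors (molecule heterogeneity, nearest-
neighbour coupling, sequence-context effects) and the Shannon information
a single copied base carries about the cation state.

`polyrec` is for anyone building or analysing such polymerase-recording
assays: it implements the full analysis pipeline of a 96-well barcoded
primer-extension experiment with paired-end sequencing readout, and a
calibrated synthetic-data generator so that every stage is testable
without sequencing anything.

## What it computes

- **Simulation** (`simulate_plate`, `simulate_extension`): seeded,
  bit-reproducible paired FASTQ plates with ground truth — per-base
  cation-dependent error rates, fixed wrong-dNTP transition rows, Gamma
  molecule heterogeneity, optional lag-one error coupling, abortive
  extensions, rare indels, a 10⁻³ template-synthesis noise floor and a
  primer-dimer contaminant. Bundled presets: `dpo4_paper` (Mn²⁺ sensor,
  template-T-driven), `klenow_paper` (weaker Mn²⁺ response, dATP-dominated
  transitions, lag-one coupling), `phusion_control` (noise floor only).
- **Read processing** (`filter_and_demux`): landmark filters (left
  primer-binding sequence, 12-base right-adapter prefix, exact barcode),
  exact mate agreement, primer-dimer removal, per-well routing with
  partition-conserving rejection statistics.
- **Misincorporation calling** (`quantify_well`, `misincorporation_rates`,
  `transition_matrix`, `noise_floor`): global alignment to the error-free
  product (match +1, mismatch 0, gap −10/−2, end gaps scored; inserts
  ≥ 70 nt with score > 60 accepted), per-position/per-base tallies, 4×4
  transition matrices, replicate means ± SEM, control-based noise floors.
- **Transfer functions** (`fit_gain`, `ca_response`, `colony_error_rate`):
  OLS gain in %/mM, fold changes versus the lowest concentration, Ca²⁺
  endpoint responses, and the classic blue/white colony error rate
  `f = −ln(F)/(d·b)`.
- **Error statistics** (`lag_one_excess`, `dispersion_test`, `fit_glm`):
  lag-one excess errors with bootstrap SE, chi-square Poisson
  overdispersion test on per-read totals, and a binomial GLM over template
  base, position and a ±3 secondary-structure window, with cross-template
  prediction scored by R².
- **Information** (`info_gain`, `info_profile`, `capacity_bytes`): Shannon
  information gain per base about a binary cation state via the Bayesian
  posterior-entropy route, per-position profiles, and recording-capacity
  extrapolation.

## Worked example

```r
library(polyrec)

plate  <- titration_plate("mn", reads_per_well = 2000,
                          preset_name = "dpo4_paper")   # 6 Mn2+ levels x 2 wells
report <- run_all(list(template = "original", preset = "dpo4_paper",
                       plate = plate, seed = 42),
                  stages = c("transfer", "stats"))

report$transfer[c("gain", "gain_se", "fold_change")]
#> $gain        [1] 2.059046
#> $gain_se     [1] 0.3211589
#> $fold_change [1] 16.49918

report$stats$dispersion[c("dispersion_index", "p_value")]
#> $dispersion_index [1] 1.425959
#> $p_value          [1] 5.390734e-24
```

The gain says this polymerase preset senses Mn²⁺ at ≈2% misincorporation
per mM; the mean rate rises ≈16-fold across the 10–800 µM grid; and the
per-read error totals are overdispersed (variance/mean ≈ 1.4, Poisson
firmly rejected), i.e. nominally identical polymerase molecules differ in
their error rates. Transition matrices
(`transition_matrix(report$tallies[["W11"]])`) show the template-T row
dominated by dGTP, and the wrong-dNTP distributions are invariant across
cation concentrations — cations scale rates without reshaping them.

See `vignettes/polyrec-methods.Rmd` for the model, its assumptions,
calibration and limitations.

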