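# fretdist

Inter-dye distance distributions from FRET-filtered fluorescence-lifetime
data.

`fretdist` is for single-molecule and ensemble fluorescence spectroscopists
who use Förster resonance energy transfer (FRET) between a donor and an
acceptor dye to measure distances in biomolecules. Because the donor
lifetime is quenched as a function of the inter-dye distance `R` — each
donor decay component's rate is multiplied by `1 + (R0/R)^6` — a
time-correlated single photon counting (TCSPC) histogram of donor photons
encodes the full distance *distribution*, not just its mean. The package
fits the donor decay model

    F(t) = I0 [ (1 - x_D0) * F_DA(t) + x_D0 * F_D0(t) ] + BG
    F_DA(t) = sum_i x_i * sum_R w(R) exp( -(t / tau_D0,i) (1 + (R0/R)^6) )

with a Gaussian distance distribution `p(R)` (mean `<R_DA>`, width
`sigma_DA`, discretized at 0.25 Å over ±4 sigma), an explicit donor-only
molecule fraction `x_D0` and a constant background, by iterative
reconvolution with the instrument response function. Errors come from
support-plane analysis and F-statistic confidence surfaces
(`chi2r(xi)/chi2r_min <= 1 + (k/nu) F(k, nu; 1-P)`).

Around that core the package provides:

* a Poisson-noise decay simulator and a systematic precision/accuracy
  study of how the donor-only fraction degrades the recovered distribution
  (`run_study()`),
* a synthetic two-channel pulsed-interleaved-excitation (PIE) photon
  stream generator and a burst pipeline — IPD burst search (7-point moving
  average, 50 µs threshold), background/crosstalk corrections
  (`alpha = 0.85%`), burst-wise efficiencies
  (`E = F_A / (F_A + 0.47 F_D)`), shot-noise-limited efficiency
  histograms, and donor-only-free filtered decays built from the donor
  microtimes of bursts detected on the directly excited acceptor channel,
* an idealized B-DNA duplex builder for the two 48-mer reference
  constructs (labels 10 / 17 bp apart) with PDB input/output,
* the weighted accessible volume (wAV) algorithm: steric accessible
  volumes for coarse-grained dye-linker constructs (flexible tube linker,
  ellipsoidal dye), Gaussian occupancy weighting with width
  `sigma_AV = sqrt(b_eff * L_link / 3)` from an ideal-chain model of the
  linker, inter-dye distance distributions from the weighted point-cloud
  pairs, and calibration of the effective bond length `b_eff` against a
  measured width.

See the methods vignette (`vignettes/fretdist-methods.Rmd`) for the model,
its assumptions and the numerical design decisions.

## Worked example

Simulate a noisy donor decay at the study conditions (mean 60 Å, width
6 Å, 20% donor-only molecules, 10^4 peak counts, background 20
counts/bin), then fit it starting from deliberately wrong guesses with
`I0` and `BG` fixed:

```r
library(fretdist)

grid  <- time_grid(bin_width = 0.016, n_bins = 3125)   # 50 ns at 16 ps
truth <- fret_decay_params(exp_components(1, 4.025),
                           gaussian_distance(mean_R = 60, sigma_R = 6),
                           R0 = 53.6, x_D0 = 0.2, I0 = 1e4, BG = 20)
decay <- generate_synthetic_decay(truth, grid, seed = 7)
start <- fret_decay_params(exp_components(1, 4.025),
                           gaussian_distance(53, 8), 53.6,
                           x_D0 = 0.18, I0 = 1e4, BG = 20)
fit_decay(decay, irf = NULL, start, fixed = c("I0", "BG"),
          ci = c("mean_R", "sigma_R"))
#> FRET decay fit
#>   <R_DA> = 59.86 A, sigma_DA = 5.58 A, x_D0 = 0.205
#>   I0 = 1e+04, BG = 20, chi2r = 1.1138 (nu = 2498)
#>   mean_R: 68.3% CI [59.333, 60.400]
#>   sigma_R: 68.3% CI [4.896, 6.228]
```

The mean distance is recovered to 0.2% with a ±0.5 Å confidence interval;
the width — always the harder parameter, and the one donor-only molecules
corrupt first — is recovered within its interval. `reduced_chi2` near 1
indicates a shot-noise-limited fit.

The same machinery drives the structural prediction. Build the 17-bp
reference duplex, compute donor and acceptor accessible volumes on a 0.8 Å
grid, and compare the uniform AV with the Gaussian-weighted wAV at
`b_eff = 3.6` Å:

```r
seqs <- dsdna_sequences()
dna  <- build_bdna(seqs$donor_17bp, seqs$acceptor)
pos  <- dsdna_label_positions("17bp")
sites <- attachment_sites(dna, list(
  list(strand = "top",    residue = pos$donor),
  list(strand = "bottom", residue = pos$acceptor)))
res <- wav_distance_distribution(dna, sites[[1]], sites[[2]],
                                 spacing = 0.8, b_eff = 3.6)
c(mean = res$mean_R, sigma = res$sigma_R)
#>      mean     sigma
#> 61.554003  6.653719
```

The weighting pulls the mean in by ~2.6 Å and roughly halves the width
relative to the uniform AV (64.2 / 10.8 Å) — uniform occupancy of the
accessible volume overstates how far the tethered dye strays from its
attachment point.

A thin command-line wrapper exposes the workflows
(`inst/cli/fretdist simulate-decay | fit-decay | study | simulate-stream |
bursts | filtered-fit | build-dna | wav | calibrate`); every run writes a
JSON manifest with the config echo, seed and output checksums.

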