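---
title: "Recovering inter-dye distance distributions from FRET-filtered lifetime data"
author: "fretdist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering inter-dye distance distributions from FRET-filtered lifetime data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretdist)
```

## The problem

A donor dye transfers excitation energy to an acceptor dye with efficiency
$E(R) = 1/(1 + (R/R_0)^6)$, where $R$ is the inter-dye distance and $R_0$
the Förster radius (~53 Å for the Alexa 488/647 pair). Because the transfer
quenches the donor's fluorescence lifetime, a time-correlated single photon
counting (TCSPC) histogram of donor photons carries information not only
about the mean inter-dye distance but about its entire distribution: dyes
tethered by ~20 Å flexible linkers explore a sterically accessible volume
on a ~100 ns timescale, so each photon samples a distance from a quasi-static
distribution $p(R)$, well approximated by a Gaussian with mean
$\langle R_{DA}\rangle$ and width $\sigma_{DA}$.

Two practical obstacles stand between the raw histogram and reliable
distribution parameters:

1. **Donor-only molecules.** A fraction $x_{D0}$ of molecules lack an
   active acceptor (incomplete labeling, photobleaching, blinking). Their
   unquenched decay is strongly correlated with $(\sigma_{DA},
   \langle R_{DA}\rangle)$ in the fit, degrading both precision and — less
   predictably — accuracy.
2. **Dye-linker motion.** Even on a rigid scaffold (double-stranded DNA),
   the measured $\sigma_{DA}$ is dominated by linker flexibility. To say
   anything about a biomolecule's own motions, the linker contribution must
   be predicted from structure.

`fretdist` implements a complete treatment of both: the decay model and
reconvolution fitting machinery with rigorous error surfaces, a simulation
study quantifying donor-only bias, a pulsed-interleaved-excitation (PIE)
burst pipeline that removes donor-only molecules *experimentally*, and a
weighted accessible volume (wAV) model that predicts the dye-linker distance
distribution from a structure.

## The decay model

The unquenched donor decay is multi-exponential,
$F_{D0}(t) = \sum_i x_i e^{-t/\tau_{D0,i}}$ (local quenching by nearby
bases gives a small second component for dye-labeled DNA). FRET multiplies
each component's decay rate by $1 + (R_0/R)^6$, and the observed decay
averages over the distance distribution:

$$F_{DA}(t) = \sum_i x_i \sum_R w(R)\,
  \exp\!\left[-\frac{t}{\tau_{D0,i}}\left(1 + \left(\frac{R_0}{R}\right)^6\right)\right].$$

The discrete weights $w(R)$ sample a Gaussian on a grid with 0.25 Å steps
over $\langle R_{DA}\rangle \pm 4\sigma_{DA}$. Numerical choices here:

* The grid is **centered on the mean** and the truncated weights are
  **renormalized to unit mass**. The raw ±4σ truncation loses only
  ~6×10⁻⁵ of the mass, but renormalization makes the amplitude at $t = 0$
  exactly 1 so that $x_{D0}$ retains its exact interpretation as a molecule
  fraction; a `renormalize = FALSE` switch restores the plain truncated
  integral. Centering makes the $\sigma \to 0$ limit collapse exactly onto
  the single-distance decay.
* The lower integration bound is clipped at 1 Å to avoid the $(R_0/R)^6$
  singularity; with realistic parameters the Gaussian carries no mass
  there.
* Model curves are evaluated at **bin centers** of the 16 ps grid; at
  nanosecond lifetimes the difference from bin integration is far below
  shot noise. (The one place where this approximation fails — an IRF whose
  width is comparable to the bin — is handled by bin-integrating the IRF
  itself, see below.)

The full model adds a donor-only fraction and a flat background:
$F(t) = I_0[(1 - x_{D0})F_{DA}(t) + x_{D0}F_{D0}(t)] + BG$, and is
convolved with the instrument response function (IRF) for fitting:

```{r model-example}
grid <- time_grid(bin_width = 0.016, n_bins = 3125)   # 50 ns at 16 ps
params <- fret_decay_params(
  donor_components = exp_components(1, 4.025),        # free Alexa 488
  distance = gaussian_distance(mean_R = 60, sigma_R = 6),
  R0 = 53.6, x_D0 = 0.2, I0 = 1e4, BG = 20)
model <- total_donor_model(params, grid)
model$counts[1]   # I0 * 1 + BG at t = 0
```

Reconvolution details that matter numerically:

* `convolve_with_irf()` is an FFT-based causal convolution of the
  area-normalized IRF with the model; a delta IRF short-circuits to the
  identity (bit-exact). Periodic wrap at the 50 ns laser period is
  available but off by default — the fit window ends at 40 ns of a 50 ns
  period, so wrap effects are well below shot noise.
* When a real IRF is used, the model decay is sampled on a zero-origin time
  axis and its $t = 0$ sample enters the convolution with weight 1/2 (the
  trapezoidal treatment of the causality step). Without the half weight the
  model systematically overshoots on the rising edge by
  $\approx \mathrm{IRF}(t)\cdot\Delta t/2$, which a high-count fit
  "repairs" by distorting $\sigma_{DA}$.
* `gaussian_irf()` returns bin-integrated (not midpoint) Gaussian values,
  exact for arbitrarily narrow IRFs.

## Fitting and error analysis

`fit_decay()` fits the model by bounded Levenberg–Marquardt iteration on
the window from 1 ns before the measured peak to 40 ns, with convergence
declared when the estimated relative decrease of the objective falls below
$10^{-8}$. Free parameters are any subset of
$(\langle R_{DA}\rangle, \sigma_{DA}, x_{D0}, I_0, BG)$, with bounds
$x_{D0} \in [0,1]$, $\sigma_{DA} > 0$, $\langle R_{DA}\rangle > 0$; the
donor components and $R_0$ come from independent reference measurements and
stay fixed.

**Weighting.** The default objective is the Poisson deviance (maximum
likelihood via signed square-root deviance residuals). Neyman weighting
$1/\max(d,1)$ — the traditional TCSPC choice — is available
(`weighting = "neyman"`) but is *not* the default, because in
background-dominated tails it measurably biases the minimizer: at the study
conditions below it inflates $\sigma_{DA}$ by ~15% and
$\langle R_{DA}\rangle$ by ~1.5%, chasing downward count fluctuations. The
*goodness-of-fit statistic* reported as `chi2r` is always the classical
Neyman-weighted reduced chi-square evaluated at the optimum. This
separation reproduces a characteristic empirical signature: a
background-level Poisson bin with mean $\mu$ contributes
$E[(X-\mu)^2/X] \approx \mu/(\mu-1)$ to the statistic, so a well-fitted
decay with a $BG = 20$ tail yields mean $\chi^2_r$ of 1.03–1.07, larger
for faster (high-FRET) decays that spend more bins at background level.

**Confidence intervals** use the F-statistic threshold
$F_\chi = 1 + (k/\nu)\,F(k, \nu; 1-P)$ with $P = 0.32$ (68.3%).
`support_plane_interval()` scans one parameter away from its estimate,
re-minimizing all other free parameters at each scan point, and brackets
the crossing of $\chi^2_{r,\min} F_\chi$ with geometric step growth and
linear interpolation; a parameter hitting its bound (e.g. $x_{D0} = 0$)
yields a one-sided interval. `confidence_surface()` evaluates the
$\chi^2_r$ ratio on a 3-D grid over
$(\sigma_{DA}, \langle R_{DA}\rangle, x_{D0})$ with $I_0$ and $BG$ fixed —
note that these axis-aligned sections through a strongly correlated
("banana"-shaped) minimum are much narrower than the support-plane
intervals, so the grid should be placed at sub-CI scale.

## The donor-only simulation study

`run_study()` generates artificial decays — Poisson noise on the model
curve — at the study conditions: $\langle R_{DA}\rangle = 40$ or 60 Å
(high/low FRET), $\sigma_{DA} = 6$ Å, $x_{D0} \in \{0, 0.05, \ldots,
0.5\}$, $I_0 = 10^4$ counts at the peak, $BG = 20$ counts/bin, 50 ns decays
at 16 ps binning. Start guesses mimic a real experiment where the truth is
unknown: $\langle R_{DA}\rangle$ starts at 35/53 Å, $\sigma_{DA}$ at 8 Å,
$x_{D0}$ at 0.9 of its true value, while $I_0$ and $BG$ are fixed at truth
(both are read directly off an experimental histogram). The donor is
modeled as a single 4.025 ns component with $R_0 = 53.6$ Å (the free-dye
reference; the study's conclusions are insensitive to the small second
component of DNA-bound donors). Replicates default to 1 per condition
(mirroring a single-decay-per-condition design) and are raised to ≥10 in
the acceptance analyses for stable statistics.

```{r study, eval = FALSE}
study <- run_study(study_config(means = 60, replicates = 10, seed = 1,
                                ci = c("mean_R", "sigma_R")))
study_mean_chi2r(study)
```

Precision is the relative CI half-width $\delta\xi/\xi$; accuracy the
signed relative deviation $(\xi - \xi_\mathrm{true})/\xi_\mathrm{true}$.
The study reproduces the qualitative structure that motivates donor-only
filtering: widths are recovered with several-fold worse precision than
means, both degrade as $x_{D0}$ grows, and at $x_{D0} \le 0.05$ the
width is recovered to better than 15% (precision) and 10% (accuracy) and
the mean to better than 1% and ~0.5%. One caveat worth stating precisely:
at 60 Å the mean-distance estimator has an intrinsic spread of ~0.4%
(consistent with its ~0.65% CI half-width), so "accuracy below 0.5%" is a
statement about the typical realization, not a guarantee for every seed —
across many seeds roughly a quarter of single decays land slightly outside
0.5%.

## The PIE burst pipeline

`simulate_stream()` produces a synthetic two-channel photon stream with
the structure of a PIE single-molecule experiment (20 MHz cycle: donor
excitation at 0 ns, direct acceptor excitation at 25 ns; macrotimes in µs,
microtimes in ns). Molecules appear as rectangular bursts of elevated
count rate with log-normal durations around 1 ms — diffusion profiles,
triplet dynamics and photobleaching are *not* modeled, which is sufficient
for exercising inter-photon-distance burst selection but means the
simulator says nothing about brightness-dependent selection biases in real
data. Burst rate defaults correspond to the ~0.03 confocal-volume
occupancy of a properly diluted sample; microtimes of donor photons are
drawn from the FRET-quenched decay of the configured distance distribution
(a fresh distance per photon — dye motion is fast compared with the
inter-photon time), jittered by the 448 ps IRF, and wrap at the full 50 ns
cycle, so decay tails spill into the red window rather than folding onto
the early bins.

`process_stream()` implements the selection chain: inter-photon distances
of the PIE channel (acceptor emission under red excitation) are smoothed
with a 7-point centered moving average; runs below the 50 µs threshold
become bursts whose boundaries are the first/last photon of the run; green
window donor/acceptor photons join a burst by macrotime (closed interval);
per-channel background rates are estimated from the inter-burst stretches
(trimmed-mean of chunked rates) unless supplied; counts are corrected as
$F_D = S_D - BG_D \Delta t$, $F_A = S_A - BG_A \Delta t - \alpha F_D$
(crosstalk $\alpha = 0.85\%$); efficiencies are
$E = F_A/(F_A + \gamma F_D)$ with $\gamma = \gamma' g = 0.47$
($\gamma' = \phi_A/\phi_D = 0.36$ from amplitude-averaged-lifetime quantum
yields, $g = g_A/g_D = 1.3$); and only bursts with $F_D + F_A \ge 40$
survive. Because selection requires directly excited acceptor photons,
donor-only molecules never enter `build_filtered_decay()`, which bins the
retained donor microtimes into a TCSPC histogram for refitting. Efficiency
histograms can be fitted free or with the variance pinned to the
shot-noise limit $\sigma^2_{SN} = \langle E\rangle(1-\langle E\rangle)/N_T$
at the photon threshold $N_T = 40$.

The package's end-to-end check simulates a stream in which *half* of all
molecules are donor-only, filters it, and refits the filtered decay: the
fitted $x_{D0}$ drops below 0.05 (residual contamination comes from
donor-only bursts overlapping detected bursts in time) and
$(\langle R_{DA}\rangle, \sigma_{DA})$ are recovered within their
support-plane intervals. This requires the counting statistics the method
itself prescribes — at least $10^4$ counts at the histogram peak; with an
order of magnitude fewer photons the correlated
$(\sigma_{DA}, x_{D0}, \langle R_{DA}\rangle)$ minimum is too shallow for
reliable parameters.

## B-DNA builder and the wAV algorithm

`build_bdna()` produces an idealized straight B-form duplex for the two
48-mer reference constructs (labeled thymines 10 or 17 bp apart; the 10-bp
construct carries an engineered mismatch adjacent to its label). Each
nucleotide is three pseudo-atoms — phosphate (r = 2.9 Å at helix radius
9.4 Å), sugar (2.9 Å at 7.4 Å), base (3.5 Å at 2.5 Å) — with 3.4 Å rise
and 36° twist, and the second strand offset azimuthally by 154° (the
B-form phosphate separation across the minor groove). This reproduces the
duplex's ~20 Å steric envelope, which is what the accessible-volume
results are sensitive to; sequence-dependent fine structure, bending and
mismatch distortion are deliberately out of scope, and the mismatch is
built with standard geometry since its true local structure is unknown.
Attachment points sit 3 Å radially outward of the labeled base.

The accessible volume (AV) of a dye-linker construct collects every grid
point (0.8 Å spacing by default, 0.4 Å for refinement checks) that the dye
can reach: the linker, a flexible tube of width $w_\mathrm{link}$ and
contour length $L_\mathrm{link}$, must find a path from the attachment
point through free space no longer than $L_\mathrm{link}$, and the dye
must fit at the end point. Numerical decisions:

* **Path metric.** Shortest paths are computed by Dijkstra on the grid
  graph. The textbook 26-neighbor mask overestimates Euclidean distances
  by up to ~8%, which visibly shrinks the AV (a free-space AV came out 22%
  smaller than the analytic sphere). `fretdist` uses the 98 coprime
  offsets of the 5×5×5 mask (worst-case ~2%) and additionally replaces
  path lengths by exact Euclidean distances wherever the straight segment
  from the attachment is unobstructed; the free-space AV then matches the
  sphere volume to ~0.5%. Length-2 jumps require a passable midpoint cell
  so they cannot tunnel through thin walls. A consequence worth noting:
  with a metrically accurate path computation the AV width is essentially
  independent of grid spacing — implementations with a chamfer-metric bias
  report widths that shrink on refinement, but that effect is an artifact
  of their metric, and this package does not reproduce it.
* **Dye clearance.** The dye ellipsoid (semiaxes from the construct
  geometry, e.g. 5.2/4.2/1.5 Å for T-C6-Alexa 488 and 9.9/7.7/1.5 Å for
  T-C6-Alexa 647) is handled as the union of the three semiaxes treated as
  sphere radii; a point is accessible if the smallest clearance is
  available. Free dye rotation (confirmed by fast anisotropy decay)
  justifies the orientational averaging.
* **Seed channel.** On a coarse-grained duplex the attachment point itself
  is sterically sealed by the ±1 neighboring base pseudo-atoms (3.5 Å radii
  plus half the linker width). The labeled residue's own pseudo-atoms are
  excluded from the obstacle set and cells within 2 Å of the attachment
  are always traversable — the covalent exit channel of the linker.

The inter-dye distance distribution follows from the two point clouds:
$\langle R_{DA}\rangle$ and $\sigma_{DA}$ are the weighted mean and
standard deviation of $|R_{D,i} - R_{A,j}|$ over all pairs
(`interdye_distribution()`; exact double sum up to 10⁷ pairs, seeded
weight-sampled Monte-Carlo with 10⁶ pairs and a standard-error report
beyond).

A uniform AV overestimates $\sigma_{DA}$ — all points equally occupied is
a poor model of a tethered chain. The **wAV** weighting multiplies each
point by a Gaussian in its distance from the attachment,
$w_i \propto \exp(-|R_i - R_\mathrm{attach}|^2 / 2\sigma_{AV}^2)$,
normalized over the discrete cloud. The width comes from an ideal-chain
model of the linker, $\sigma_{AV} = \sqrt{b_\mathrm{eff} L_\mathrm{link}/3}$
with an effective bond length $b_\mathrm{eff}$ (mean-square end-to-end
distance $b_\mathrm{eff} L_\mathrm{link}$, divided by 3 per Cartesian
component; a rigid-linker scaling $b_\mathrm{eff}\sqrt{L_\mathrm{link}/3}$
is selectable, and the two differ by ~20% at worst). Each dye gets its own
$\sigma_{AV}$ through its own $L_\mathrm{link}$. `calibrate_beff()`
inverts the monotone map $b_\mathrm{eff} \mapsto \sigma_{DA}^{wAV}$
against a measured width by root finding; on the idealized duplex the
calibration against the measured 7.2 Å lands near 4.3 Å, somewhat above
the ~3.6 Å obtained with fully detailed reference structures — the
coarse-grained AVs are a little narrower, and the calibrated value absorbs
that difference, which is exactly its job when the same dye pair is later
used on a protein.

```{r wav, eval = FALSE}
seqs <- dsdna_sequences()
dna <- build_bdna(seqs$donor_17bp, seqs$acceptor)
pos <- dsdna_label_positions("17bp")
sites <- attachment_sites(dna, list(
  list(strand = "top", residue = pos$donor),
  list(strand = "bottom", residue = pos$acceptor)))
wav_distance_distribution(dna, sites[[1]], sites[[2]],
                          spacing = 0.8, b_eff = 3.6)
```

## Problem sizes and reproducibility

All stochastic entry points take explicit seeds and restore the RNG state.
The sizes used by the shipped analyses: simulation studies with 10
replicate seeds per condition (140 fits for the two chi-square series, 20
CI analyses at $x_{D0} = 0.05$); AV grids of ~90³ cells at 0.8 Å and
~175³ at 0.4 Å; photon streams up to ~10⁷ photons for the end-to-end
filter check (chosen to reach the prescribed 10⁴ peak counts). The
command-line wrapper (`inst/cli/fretdist`) writes a JSON manifest (config
echo, package version, seed, output checksums) next to every artifact.

## Known limitations

* The photon simulator's rectangular bursts ignore diffusion profiles,
  triplet blinking and bleaching; conclusions about burst-selection
  artifacts in real data are out of reach.
* The idealized B-DNA geometry shifts absolute AV distances by ~1–2 Å
  relative to fully detailed structures; calibrated quantities
  ($b_\mathrm{eff}$) absorb this, absolute means mostly do not.
* Electrostatic dye-dye and dye-surface interactions are not modeled in
  the wAV weighting; for closely spaced or strongly charged systems the
  Gaussian occupancy model is the first thing to revisit.
* Donor-only removal by PIE filtering is limited by time-overlapping
  molecules: a few-percent residual $x_{D0}$ remains at realistic
  occupancies and must still be carried as a fit parameter.
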