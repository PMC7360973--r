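---
title: "Models for chaperone-driven trimer dissociation and HX-MS deconvolution"
author: "ChaperKin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models for chaperone-driven trimer dissociation and HX-MS deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChaperKin)
```

# The problem

Heat shock transcription factor 1 (Hsf1) trimerizes under proteotoxic
stress through its leucine-zipper heptad repeats (HR-A/B) and binds heat
shock elements (HSEs) in promoter DNA with high avidity — three
DNA-binding domains engaging simultaneously. Attenuation of the response
requires removing Hsf1 from DNA. The Hsp70 system (Hsc70 targeted by its
J-domain co-chaperone DnaJB1) does this by *monomerizing* the trimer:
Hsc70 binds next to the trimerization domain and, through the entropic
pulling force generated by its excluded volume, unzips the triple
leucine-zipper protomer by protomer. ChaperKin implements the
quantitative machinery this mechanism is tested with:

* equilibrium DNA binding under ligand depletion (fluorescence
  polarization titrations),
* delayed single-exponential dissociation kinetics,
* a binomial trimer-composition model coupled to a shared-rate global
  kinetic fit, with single-site-sufficient and three-sites-required null
  models compared by information criteria,
* two-Gaussian deconvolution of bimodal (EX1-type) hydrogen-exchange
  isotope envelopes into high- and low-exchanging subpopulations,
* sliding-window Hsp70 binding-site scanning of protein sequences, and
* two-state thermal transition (Tm) fitting.

A seeded synthetic-data module generates every input with the
statistical structure the analyses assume, so the full pipeline is
exercisable and testable without instrument data.

# Equilibrium binding under ligand depletion

With a labelled HSE probe at 5 nM and trimer affinities in the same
range, free and total concentrations cannot be equated; the bound
fraction follows the quadratic solution of the law of mass action,

$$LR = \frac{(L + R + K_D) - \sqrt{(L + R + K_D)^2 - 4LR_{tot}}}{2},$$

implemented in `quadraticBound()` and fitted by `fitTitration()` with
three free parameters ($K_D$, free- and bound-probe polarization). Units
are nM throughout; the polarization signal is treated as unit-agnostic.

```{r titration}
tt <- genTitration(Kd = 4.7, probeTotal = 5, noiseSd = 0, seed = 1)
fitTitration(tt, probeTotal = 5)
```

# Dissociation kinetics with a lag

Chaperone-mediated dissociation traces show a short (5–10 min) delay
before the exponential phase, so a composite curve is fitted
(`delayExponential()`, `fitDissociation()`):

$$y(t) = y_{max} \;\; (t \le t_0), \qquad
  y(t) = y_0 + (y_{max} - y_0)\,e^{-k(t - t_0)} \;\; (t > t_0).$$

The delay $t_0$ is a *fitted* parameter bounded to $[0, 15]$ min —
wide enough to bracket the observed lag, tight enough to keep it from
absorbing slow-decay ambiguity. Rates are reported per minute.
Monotonically rising or flat traces return a structured failure flagged
`"no decay"`; data-quality problems never raise conditions.

# Binomial trimer composition and the multi-rate global model

Mixing wild-type monomers (with the HR-B-proximal Hsc70 site) and
site-deleted monomers at ratio $a\!:\!b$ and heat-shocking yields
trimers assembled binomially: with $p = a/(a+b)$ the species with 3, 2,
1, 0 accessible sites occur at $p^3$, $3p^2(1-p)$, $3p(1-p)^2$,
$(1-p)^3$ (`trimerComposition()`; at 2:1 this is 29.6 %, 44.4 %,
22.2 %, 3.7 %).

The central kinetic hypothesis is that the dissociation rate of a trimer
depends on *how many* protomers Hsc70 can engage. Each trace is modelled
as a species-weighted sum of delayed exponentials
(`mixtureSignal()`):

$$y(t) = y_0 + (y_{max} - y_0)\left[f_0 + \sum_{j=1}^{3} f_j
  E(k_j, t)\right],$$

with $E(k,t) = 1$ for $t \le t_0$ and $e^{-k(t-t_0)}$ after the lag.
The 0-site homotrimer never dissociates ($k_0 \equiv 0$), matching the
complete resistance of the site-deleted homotrimer. This species-sum is
declared the package's reference form for the global model: it is the
minimal model consistent with rates indexed by accessible-site count
plus a non-dissociating 0-site species.

`globalFitMixture()` fits all traces of a mixing series simultaneously:

* $k_1, k_2, k_3$ shared across traces;
* $y_{max}$ and $t_0$ per trace (the lag is a trace-level property,
  shared by the species within a trace);
* the free-DNA baseline $y_0$ as a **single shared parameter**. Every
  trace uses the same labelled probe, so the baseline is a property of
  the probe, not of the mixture. Sharing it is also what makes the
  residual plateaus informative: with a per-trace free baseline the
  plateau level $y_0 + (y_{max}-y_0)f_0$ can be reproduced for *any*
  $f_0$, the two null models collapse onto a single family, and the
  slowest rate (half-life longer than the 100-min window) trades off
  against the baselines.

Rates are initialized from a single-trace fit of the most
wild-type-like trace ($k_3$ start, $k_2 = k_3/2$, $k_1 = k_3/10$) and
refined from four deterministic start patterns (graded, equal, widely
spread), keeping the lowest residual sum of squares — a seed-free guard
against the local optimum in which a slow rate pins at zero. Rates whose
species carry no weight in the supplied ratios (e.g. $k_1, k_2$ from a
pure wild-type trace alone) are flagged `"under-determined"` and
reported with infinite standard error.

```{r mixture}
traces <- genMixtureExperiment(noiseSd = 0, seed = 1)
globalFitMixture(traces)
```

## Null models and model comparison

Two competing hypotheses are fitted to the same traces
(`nullPrediction()`, `compareModels()`), both with the rate fixed to the
value fitted on the pure wild-type trace:

* **single-site-sufficient**: any trimer with at least one site decays
  at the full rate (decaying fraction $1 - f_0$);
* **three-sites-required**: only the all-wild-type species decays
  (fraction $f_3$).

`compareModels()` reports RSS, parameter counts, AIC, AICc and BIC per
variant and flags the lowest-AIC model. AIC is the default criterion:
with $\ge 101$ points per trace the small-sample correction is
immaterial, but AICc and BIC are reported alongside. The Gaussian
likelihood counts the residual variance as one extra parameter.

```{r compare}
noisy <- genMixtureExperiment(noiseSd = 2.4, seed = 2)
compareModels(noisy)$table
```

# HX-MS: centroids, back-exchange, bimodal deconvolution

Deuteron incorporation is computed from intensity-weighted envelope
centroids (`centroidMass()`) corrected with a 100 %-deuterated control
(`correctBackExchange()`): deuterons
$= (m_{obs} - m_{0\%}) / (m_{100\%} - m_{0\%}) \cdot n_{max}$. The
exchangeable-amide count (`maxExchangeable()`) uses the field's standard
convention — sequence length minus two (fast-back-exchanging N-terminal
residues) minus internal prolines — since amide bookkeeping conventions
differ between laboratories and only the relative scale depends on it.

Condition-versus-reference comparisons (`differenceTable()`) report
$\Delta D$ per peptide (protection negative), pooled SD and a
deliberately conservative significance flag: Welch t-test at
$\alpha = 0.05$ **and** $|\Delta D| > 2\times$ pooled SD, both required,
to avoid over-flagging with $n = 3$ replicates. Peptides present on one
side only are listed as unmatched, never dropped.

EX1-type exchange produces bimodal envelopes — two coexisting
conformations exchanging at different extents. `fitBimodal()` fits

$$I(m) = A\left[(1-p)\,G(m;\mu_{low},\sigma_{low}) +
  p\,G(m;\mu_{low}+\delta,\sigma_{high})\right], \quad \delta > 0,$$

to the stick intensities. Numerical choices: $\mu_{low} < \mu_{high}$
enforced through the $\delta$ parameterization; both widths free with a
common floor of 0.3 Da (the natural isotope envelope width); means
initialized from the 25th/75th intensity-weighted mass percentiles. Two
degenerate regimes are flagged `"effectively unimodal"`: weight
concentrating in one mode ($p < 0.02$ or $p > 0.98$), and mode
coincidence ($\delta$ below the larger width), where the split of
weight between two superimposed Gaussians is arbitrary and the fit is
collapsed to the one-mode description with $p = 0$. With reference
centroids supplied, each subpopulation's mean is converted to a relative
deuteration, exposing the contrast between an unzipped, highly
exchanging zipper and the protected trimeric state.

```{r bimodal}
env <- genEnvelope(pHigh = 0.3, noiseSd = 0.01, seed = 3)
fitBimodal(env, undeut = 1250, fulldeut = 1258)
```

`subpopulationSummary()` aggregates replicate fits per peptide and
condition and flags conditions whose high-exchanging fraction exceeds
the reference by more than two pooled SD.

# Hsp70 binding-site scanning

`windowScores()` scans a sequence with a 13-residue window (offsets
$-6..+6$), summing a position-specific score matrix entry per (residue,
offset) pair and assigning the sum to the window's *center* residue;
termini are untiled. Scores at or below $-5$ mark good Hsp70/Hsc70
binding sites; both "below −5" and "score ≤ −5" phrasings circulate,
and the inclusive rule (the one printed with the counting procedure) is
applied uniformly in `callSites()` and `countSitesInRange()`. The
original peptide-library-derived energy matrix is not redistributed
here; `readScoringMatrix()` loads any 20×13 matrix CSV with documented
provenance, and all tests use synthetic toy matrices. Coordinates are
1-based inclusive everywhere (explicitly *not* BED half-open).

`rescoreVariant()` applies substitutions (e.g. hydrophobic-to-serine
scans) and internal deletions before rescanning; deletions are excised
and the surviving residues keep their original numbering, so wild-type
and variant profiles align. Because the score is additive, a single
substitution changes exactly the 13 windows overlapping it — a property
the test suite checks literally. Site counting in a region reports
per-center counts with per-run (segment) counts attached as an
attribute, covering both tallying conventions.

# Thermal transitions

The trimer fraction versus incubation temperature is fitted with a
four-parameter Boltzmann sigmoid with flat baselines
(`thermalFraction()`, `fitThermal()`):

$$f(T) = b_{low} + \frac{b_{high} - b_{low}}{1 + e^{-s(T - T_m)}}.$$

This is the standard two-state melt with the fewest assumptions; $T_m$
is the quantity of interest and the only one compared across variants.
A fitted midpoint outside the measured range, or constant data, is a
structured failure. The default temperature grid is the study's
(4, 20, 25, 30, 35, 39, 42 °C).

# The synthetic-data module

Generators (`genTitration()`, `genDissociationTrace()`,
`genMixtureExperiment()`, `genEnvelope()`, `genMelt()`,
`genSequence()`) emulate the study designs: probe at 5 nM titrated
0.2–100 nM; traces on 0–100 min at 1-min spacing with amplitudes
200 → 80 mP, a 7-min lag and rates $(k_1,k_2,k_3) =
(0.005, 0.02, 0.05)\,\mathrm{min}^{-1}$; the five-ratio mixing design
1:0, 2:1, 1:1, 1:2, 0:1; bimodal envelopes 3 Da apart with
$\sigma = 0.6$ Da at the isotopic spacing; melts on the 7-temperature
grid. Noise is additive homoscedastic Gaussian on the signal
(plate-reader polarization noise is approximately signal-independent at
these amplitudes; default 2.4 mP = 2 % of the 120 mP amplitude) and
multiplicative on envelope intensities (clamped at zero). Seeds are
mandatory — there is no silent global RNG use, and the caller's RNG
state is left untouched — and every dataset embeds its ground truth in
metadata, so recovery tests are self-describing.

What the generators deliberately do **not** emulate: correlated
(autoregressive) detector drift, photobleaching, envelope centroid
drift from charge-state misassignment, peptide-dependent back-exchange,
or inter-replicate batch effects. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated noise
model, not robustness to every artefact of real instrument data.

# Problem sizes and reproducibility

The simulation studies shipped with the package use 50 replicates for
the global-fit and deconvolution recoveries, 200 for the single-trace
rate, 100 sequence/matrix pairs for the scanning oracle and 100–150
melt pairs — sizes at which the Monte-Carlo error of each summary is
well below its acceptance margin. `scripts/acceptance.R` recomputes all
of them from scratch under a caller-supplied seed; sub-seed blocks keep
the stages independent. Tm shifts are estimated from matched pairs (a
wild-type and a shifted melt sharing one noise realization), which
cancels most of the estimator's edge-of-grid skew near the 42 °C end of
the temperature series.

# Known limitations

* The global model treats heterotrimer DNA-binding affinity as
  identical across species; only dissociation rates vary.
* Chaperone and ATP concentration dependence of the rates is not
  modelled; rates are fitted constants for one condition.
* Envelopes are consumed as decharged stick spectra; charge-state
  deconvolution, peak picking and retention-time alignment are out of
  scope, as is residue-level (Linderstrøm-Lang) exchange modelling.
* `fitBimodal()` assumes at most two subpopulations; three-state
  exchange would need a different model.
* The delay-exponential treats the lag as sharp; a smooth lag
  (e.g. consecutive-step) model would fit the transition region
  differently but was not needed to describe the data class.
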