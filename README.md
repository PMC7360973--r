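# ChaperKin

Quantitative models for how the Hsp70 chaperone system dismantles
DNA-bound transcription-factor trimers. Heat shock factor 1 (Hsf1)
trimerizes through a triple leucine-zipper and binds heat shock
elements with avidity from three DNA-binding domains; Hsc70, targeted
by DnaJB1, removes it by unzipping the zipper protomer by protomer
(entropic pulling) and monomerizing the trimer. ChaperKin implements
the analysis machinery for testing that mechanism and is aimed at
anyone fitting fluorescence-polarization kinetics, HX-MS envelopes or
chaperone-site predictions for oligomeric clients:

* **Equilibrium binding under ligand depletion** — the quadratic
  solution of the law of mass action,
  `LR = ((L+R+K_D) − sqrt((L+R+K_D)² − 4LR_tot))/2`, fitted to
  polarization titrations (`quadraticBound()`, `fitTitration()`).
* **Dissociation kinetics with a lag** — the composite curve
  `y = y_max` for `t ≤ t0`, `y = y_0 + (y_max−y_0)·exp(−k(t−t0))`
  afterwards (`delayExponential()`, `fitDissociation()`).
* **Binomial trimer composition + multi-rate global fit** — mixtures of
  wild-type and binding-site-deficient monomers assemble trimers with
  3/2/1/0 accessible Hsc70 sites at binomial fractions
  (`trimerComposition()`); each trace is a species-weighted sum of
  delayed exponentials with shared rates `k1, k2, k3` and a
  non-dissociating 0-site species (`globalFitMixture()`), compared by
  AIC against single-site-sufficient and three-sites-required nulls
  (`compareModels()`).
* **HX-MS** — envelope centroids, back-exchange correction against a
  100 %-deuterated control, per-peptide difference tables, and
  two-Gaussian deconvolution of bimodal (EX1-type) envelopes into
  high-/low-exchanging subpopulations (`centroidMass()`,
  `correctBackExchange()`, `differenceTable()`, `fitBimodal()`).
* **Hsp70 binding-site scanning** — 13-residue sliding-window scores
  from a pluggable 20×13 position-specific matrix, site calling at the
  −5 threshold, mutant rescoring with substitutions and deletions
  (`windowScores()`, `callSites()`, `rescoreVariant()`).
* **Thermal transitions** — four-parameter Boltzmann melt, reporting Tm
  (`fitThermal()`).
* **Seeded synthetic data** for every input (`genTitration()`,
  `genMixtureExperiment()`, `genEnvelope()`, `genMelt()`, ...), plus a
  pipeline entry point (`runPipeline()`, with a CLI wrapper in
  `inst/scripts/chaperkin.R`).

## Worked example

Compose a 2:1 wild-type:mutant mixing experiment, fit the shared-rate
global model, and compare it with the null hypotheses:

```r
library(ChaperKin)

trimerComposition(2, 1)
#> MixtureComposition (wt:mut = 2:1)
#>   sites 3/2/1/0: 0.2963 / 0.4444 / 0.2222 / 0.0370
```

At a 2:1 ratio, 29.6 % of trimers carry all three Hsc70 sites, 44.4 %
two, 22.2 % one, and 3.7 % none (these cannot be dissociated).

```r
traces <- genMixtureExperiment(noiseSd = 2.4, seed = 11)  # 5 ratios
fit <- globalFitMixture(traces)
fit
#> GlobalKineticFit [full] converged; 5 traces
#>   k1 = 0.0052615 (se 0.000247), k2 = 0.019766 (se 0.000586), k3 = 0.051088 (se 0.000938) /min
#>   RSS = 2741, AIC = 2317.42
```

The generating rates were (0.005, 0.02, 0.05) per minute: trimers with
more accessible sites dissociate faster, the kinetic signature of
successive entropic pulling. The competing hypotheses lose decisively:

```r
compareModels(traces)$table[, c("variant", "rss", "n_params", "aic", "daic")]
#>            variant       rss n_params      aic     daic
#> 1             full  2741.403       14 2317.420    0.000
#> 2 single_site_null 89539.238       11 4071.954 1754.535
#> 3 three_sites_null 92026.991       11 4085.794 1768.374
```

An equilibrium titration under ligand depletion (probe at 5 nM):

```r
tt <- genTitration(Kd = 4.7, probeTotal = 5, noiseSd = 3, seed = 11)
fitTitration(tt, probeTotal = 5)
#> ModelFit [titration] converged
#>   Kd           = 4.08019 (se 0.347)
#>   signal_free  = 57.2371 (se 1.66)
#>   signal_bound = 206.296 (se 2.4)
```

The fitted `Kd` of 4.1 ± 0.3 nM recovers the generating 4.7 nM within
noise; with `noiseSd = 0` the round trip is exact.

See `vignette("trimer-unzipping")` for the models, assumptions,
numerical choices and limitations.

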