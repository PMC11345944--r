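# gastroPK

Deducing human gastric-motility patterns from oral-capsule
pharmacokinetics by coupling biopredictive dissolution testing with
physiologically based biopharmaceutics modelling (PBBM).

After a fasted subject swallows a hard capsule, the plasma
concentration–time profile is shaped less by the drug itself (here a
highly soluble, rapidly permeating compound) than by what the stomach
does to the capsule: when phase-II contractions of the interdigestive
migrating motor complex (IMMC) squeeze it open, how fast noncaloric
fluid leaves the stomach (the first-order constant *k*<sub>GE</sub>,
1–14 h⁻¹), and when the phase-III "housekeeper wave" flushes the
remaining contents into the duodenum (the complete gastric emptying
time, GET). `gastroPK` implements the full modelling chain that turns
this physiology into testable, simulated PK:

* **pkcore** — a two-compartment disposition model with lag time,
  first-order absorption and linear elimination; body weight (centred at
  70 kg) scales CL/*F* and *V*₁/*F* allometrically
  (θᵢ = θ · e^η · (WT/70)^β); log-normal between-subject variability
  with ω² = ln(1 + CV²); combined additive + proportional residual
  error; NCA (C<sub>max</sub>, T<sub>max</sub>, AUC by linear
  trapezoid); and two-stage individual fitting with 1/Ŷ² weights and
  ±20% disposition bounds around a reference tablet fit.
* **physiocell** — a digital twin of a closed-loop flow-through
  dissolution apparatus: a 34 mL stress cell circulating with a 466 mL
  reservoir at the programmed pump flow (50 → 8 mL/min ramp, 110 mL/min
  refill pulse during the gastric-emptying sequence), Weibull or
  double-Weibull capsule release with a lag, and modified Noyes–Whitney
  particle dissolution dX<sub>d</sub>/dt = z·X₀^⅓·X<sub>s</sub>^⅔·(C<sub>s</sub> − X<sub>d</sub>/V)
  with z = 1.08 mL/mg/h and C<sub>s</sub> = 27 mg/mL, plus fitting of
  the release coefficients and of z from the post-GET burst.
* **ivivp** — the in vivo absorption–transit model: stomach plus five
  small-intestinal segments with dynamic fluid volumes (240 mL of
  co-ingested water emptying at *k*<sub>GE</sub>), gastric release and
  dissolution, a housekeeper-wave event that converts remaining
  encapsulated drug to free solid and switches emptying to 100 h⁻¹,
  fixed transit constants, and permeability-limited absorption
  (k<sub>abs</sub> = 2·P<sub>eff</sub>/R, P<sub>eff</sub> = 1.5×10⁻⁴
  cm/s calibrated to the 0.5 h tablet T<sub>max</sub> at
  *k*<sub>GE</sub> = 8.5 h⁻¹), coupled to the pkcore disposition.
* **classify** — rule-based assignment of capsule profiles to six
  motility groups from T<sub>max</sub> and the early-exposure ratio
  C(0.5 h)/C<sub>max</sub>.
* **popsim / synthdata** — prevalence-weighted virtual populations
  (27/22/18/13/13/7% across groups), the final per-group
  *k*<sub>GE</sub> rules, repeated randomised draws with summary
  curves, and generators for synthetic crossover trials and noisy
  dissolution fixtures with known ground truth.

## Worked example

```r
library(gastroPK)

## the typical 70 kg subject of the published population model
typ <- covariate_scale(default_poppk("capsule"), 70)
typ
#> Individual PK parameters, subject 1 (70 kg)
#>  tlag    ka    CL    V1     Q    V2
#>  0.36  4.88 75.23 86.69 41.43 31.38

## a lazy stomach: housekeeper wave at 1.5 h, slow emptying (2 1/h),
## capsule opened early by gentle phase-II stresses (group 3 release)
sc  <- motility_scenario(6)
prof <- simulate_subject(typ, default_release_params(sc$release_group),
                         default_gi_config(), clinical_times(),
                         scenario = sc, kge = 2)
nca(prof)
#> NCA: Cmax 0.5288 mg/L at Tmax 2 h; AUC_last 1.3515 mg*h/L; C(0.5 h) 0.1349 mg/L
```

The late T<sub>max</sub> (2 h on the clinical grid) and the low 0.5 h
concentration are exactly the signature the classifier maps to group 6.
The prevalence-weighted population run reproduces the study's headline
observation — capsules peak a full hour after dosing even though tablets
of the same drug peak at 0.5 h:

```r
run_virtual_trial(n = 100, n_draws = 10, seed = 7)
#> Virtual trial: 100 subjects x 10 draws; median Tmax 1 h on the 10-point grid
```

On the in vitro side, the apparatus twin simulates a dissolution
program, and the release model is fitted back from the (noisy,
triplicate) curves:

```r
fx  <- generate_invitro_fixtures(list(default_scenario(3)),
                                 list(default_release_params(3)), seed = 1)
fit_release(mean_invitro_profile(fx, group = 3), default_scenario(3),
            kind = "double_weibull")
#> double_weibull release: tlag 2.53 min, tau 9.57 min, b 2.14,
#>   tau2 98.5, b2 1.2, w 0.41; z 1.08 mL/mg/h, Cs 27 mg/mL, X0 100 mg
```

Default configuration files (population parameters, the six dissolution
programs, release coefficients, GI physiology, final scenario rules)
ship under `inst/extdata/` as YAML and can be regenerated with
`make_default_configs()`.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "gastroPK",
                               load_package = "installed")'
```

Two property checks are intentionally failing and documented in the
methods vignette (`vignettes/gastric-motility-ivivp.Rmd`): the
double-peak prominence at the slowest gastric emptying sits just below
the 5% detection threshold, and closed-loop motility-label recovery is
limited by the tight-stomach group lying on its own classification
boundary.

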