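---
title: "A semi-physiological PBPK model of the human respiratory tract for nasal sprays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-physiological PBPK model of the human respiratory tract for nasal sprays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and intent

`nasalpbpk` implements a mechanistic model of drug disposition in the human
upper and lower airways, coupled to a lumped systemic compartment —
"semi-physiological" in the sense that one organ system (the respiratory
tract) is resolved anatomically while the rest of the body is a single
central compartment. The intended use is locally acting nasal sprays:
plasma concentrations are measurable but pharmacologically irrelevant,
nasal tissue concentrations are the relevant exposure but unmeasurable in
humans. The model lets the measurable inform the unmeasurable: systemic
disposition is identified from oral data, nasal deposition from intranasal
plasma data, and nasal tissue exposure then follows from the physiology.
The worked case throughout is varenicline nasal spray (0.06 mg twice
daily), with oral varenicline 1 mg as the systemic anchor.

## Model structure

States are drug amounts (ng). For each respiratory segment
x ∈ {Nose, BB (bronchi), bb (bronchioles), AL (alveoli)} there is an
epithelial lining fluid (ELF) amount `A_ELF[x]` and a tissue amount
`A_tissue[x]`; in addition a GI depot, a central (plasma) compartment, and
two cumulative bookkeeping pools (eliminated; unabsorbed). With
concentrations `C = A / V` and plasma `Cp = A_central / Vc`:

* ELF → tissue, one way: flux `PS_x · fu_ELF · C_ELF[x]`.
* tissue ↔ plasma, two ways, same PS: net flux
  `PS_x · (fu_tissue · C_tissue[x] − fu_p · Cp)`.
* Mucociliary clearance: bb-ELF → BB-ELF at `kmcc,bb`, BB-ELF → pharynx →
  GI at `kmcc,BB`. The pharynx itself holds no mass: anything reaching it
  (including the F2 fraction of a spray) is swallowed instantly.
* GI: first-order absorption `ka`, fraction `FA` reaching plasma, the rest
  booked as unabsorbed. No first-pass metabolism is modelled, so `FA`
  doubles as oral bioavailability.
* Plasma: linear clearance `CL` acting on total concentration (because
  `CL` is estimated against total plasma concentrations; the unbound
  fractions appear only in the permeation fluxes).

The system is closed: at all times the compartment amounts plus the two
cumulative pools sum to the administered dose (`mass_balance()` verifies
this to ~1e-13 in practice; the package invariant is 0.1%).

**Why two-way tissue–plasma exchange.** The source model's full equation
set is not public, and the directionality of the tissue–plasma link is the
one genuinely open structural choice. One-way (tissue → plasma only)
transport empties the nasal tissue at `PS_Nose/V_tissue ≈ 1.6 h⁻¹`
(terminal t½ ≈ 0.4 h), which contradicts the reported simulated nasal
half-life of 13–15 h running parallel to plasma. Two-way exchange on the
unbound gradient reproduces exactly that parallelism — after the deposited
depot drains, nasal tissue tracks plasma — and also reproduces the
reported nasal AUC0–∞ and CL/F through the flux identity discussed below.

**Dosing.** Intranasal doses are split by deposition fractions F1–F5
(nasal ELF, pharynx→GI, BB/bb/AL ELF); the residue `1 − ΣFi` lands on the
keratinized nasal vestibule and is booked directly to the unabsorbed pool.
Oral doses pass through a pre-absorption holding state and are released
into the GI depot at `t + tlag`; the holding state keeps mass balance
exact during the lag. The model is linear and time-invariant, so multidose
profiles equal sums of shifted single-dose profiles; `superpose_check()`
audits the integrator against this to < 1e-6.

## Parameter derivation

Internal units are ng, mL, h, ng/mL, mL/h throughout (chosen so plasma
concentrations carry no scale factors); published litre-based values are
converted ×1000 on entry.

Fixed physiology (defaults of `build_physiology()`): `FA` 0.9, `fu_ELF` 1,
`fu_tissue` 1, `fu_p` 0.8, `kmcc,bb` 0.083 h⁻¹, `kmcc,BB` 0.417 h⁻¹,
ELF volumes 0.2459 / 2.1 / 2.1 / 20.8 mL and tissue volumes 2.829 (from
geometry) / 38 / 38 / 381 mL for Nose / BB / bb / AL.

Derived quantities:

* `V_Nose-tissue = S_Nose · D_Nose` (0.0246 m² × 1.15e-4 m = 2.829 mL).
* `Peff = Peff,ref · Papp,drug / Papp,ref`; for varenicline scaled from
  budesonide, 2.228e-6 × 26.145/11.4 = 5.1097e-6 cm/s. The unrounded
  value is carried into the PS products (rounding first changes PS_AL in
  the fourth digit).
* `PS_x = Peff · S_x` with S = 0.0246 / 0.75 / 0.75 / 140 m², giving
  4.53 / 138 / 138 / 25 753 mL/h.

Two derivation quirks are worth recording. First, the thin-film product
`S_Nose · H_Nose` (H = 1e-6 m) gives a nasal ELF volume of 0.0246 mL,
whereas the tabulated literature value is 0.2459 mL — an order of
magnitude apart; the two cannot both be right. The package ships the
tabulated value as the default (the downstream reference results were
produced with it; it also corresponds to H = 1e-5 m, a plausible mucus
thickness) and exposes the geometric computation via
`build_physiology(nose_elf = "geometry")`. Second, the published PS_Nose
(0.0045 L/h) is printed to two significant digits; the full-precision
computation gives 0.004525 L/h, 0.56% away from the printed value but
rounding to it exactly.

## Fitting

`fit_systemic()` estimates (tlag, ka, Vc, CL) from a mean oral profile;
`fit_deposition()` estimates (F1, F2) from a mean intranasal profile with
the systemic parameters held at their oral-fit values and F3 = F4 = F5 = 0
(spray droplets of 30–120 µm do not reach the lower airways). Both
minimize a weighted sum of squares with prediction-based weights, default
`1/ŷ²`: the data span two orders of magnitude (0.05–5 ng/mL) and a
proportional error model is the natural default; it also makes the
objective scale-invariant. Observations recorded as 0 (below the limit of
quantitation) are excluded — a zeroed mean carries no least-squares
information, and the reference analysis itself shows its fitted curve
passing above zeroed late-time means.

The optimizer is a bounded derivative-free simplex: parameters are
transformed (log for positive parameters, logit for the lag on [0, 2] h
and the fractions on [0, 1]), Nelder–Mead is restarted from jittered
starts (5 by default, seeded), and the incumbent is polished once more.
The accepted-objective trace is recorded and is non-increasing by
construction. With 2–4 parameters and a lag-induced kink this is more
robust than gradient methods; on noise-free synthetic data all
identifiable parameters are recovered to ~1e-6 relative.

F2 deserves a note: its true value (≈7.6e-7) contributes of the order of
0.1 ng·h/mL to plasma exposure and is identifiable only up to "negligibly
small" (< 1e-3); tests assert exactly that, not its value.

## Virtual populations

Inter-individual variability is lognormal on `CL` and `Vc` only
(independent, CV 38% by default), with `tlag`, `ka`, the deposition
fractions and all physiology held fixed. The lognormal is parameterized
with **mean = typical value**: `X_i = X_typ · exp(η − σ²/2)`,
`σ² = log(1 + CV²)`. The alternative convention (median = typical) was
considered and rejected on moment grounds: the reference population means
imply `E[1/CL] = (1 + CV²)/CL_typ` — the mean-centred moment — for AUC
(e.g. 0.9e6/10001 × 1.1444 ≈ 103 h·ng/mL against the reported 105.8),
whereas median-centring predicts means ~9% lower than reported.
Accumulation ratios are insensitive to the choice (the centring constant
cancels in ratios). The same mean-one convention is used for the residual
error in the synthetic-data generator, so averaging noisy replicates is
unbiased.

`popsim()` runs every subject through the full simulator, attaches
per-subject NCA of both the plasma and the nasal tissue series, and
accumulates the population mean profile. Evaluation runs use n = 300 and
regimen analyses n = 500, the sizes of the reference study; all draws are
reproducible from a single seed (default 20220707, an arbitrary but
documented constant).

## Noncompartmental analysis

* AUC: linear trapezoid (not lin-up/log-down), with interpolation at
  interval bounds. Linearity keeps AUC exactly additive over abutting
  intervals, which the tests exploit; on the sharply peaked nasal tissue
  curve the chords overestimate AUC0–∞ by ~4% relative to the analytic
  flux identity (below) — a known, documented property of the grid, not a
  model error.
* Cmax/Tmax are read off the observation grid without interpolation (the
  reference nasal Tmax of 0.08 h is itself a grid node).
* λz: unweighted log-linear regression; candidate windows are the last
  3–6 positive points strictly after Tmax, the window with the best
  adjusted R² wins, ties go to fewer points. Degenerate (flat or
  non-declining) windows are rejected, and λz-dependent parameters are
  reported missing when no window qualifies.
* `CL/F = dose/AUC0–∞` and `V/F = CL/F/λz` use the administered device
  dose, not the deposited fraction — that is the convention under which
  the reference nasal CL/F (8.38 mL/h ≈ 60 000 ng / 7165 h·ng/mL) back-
  calculates.
* Multidose: Cmax and AUC0–12 are computed within the first and the final
  dosing interval; `R_Cmax` and `R_AUC` are final/first ratios. For
  population runs the ratios are computed on the population **mean
  profile** (equivalently: ratios of mean exposures). This matters: mean
  profiles weight slow-clearance subjects by their larger AUC, which is
  why the systemic R_AUC (≈2.3–2.4) exceeds the typical-subject
  superposition value 1/(1 − e^(−λτ)) ≈ 2.17.
* Time to steady state: first dosing day whose morning pre-dose trough
  reaches 95% of the final morning trough. This is evaluated on the
  **typical-subject** profile: steady-state attainment is a property of
  the kinetics (trough fraction 1 − e^(−nλτ), reaching 0.95 on day 4 for
  these parameters), and the AUC-weighting of slow subjects in a mean
  profile would push the apparent day to 5 without describing any actual
  subject. Threshold 0.95 reproduces day 4 for both populations; the
  trough algebra shows day 3 requires relaxing the threshold to ≈0.88.

A useful analytic anchor used in the tests: integrating the nasal tissue
balance gives `AUC0–∞(nasal) = deposited dose / (fu_tissue · PS_Nose)`
(plus a negligible plasma-return term, ~0.2%), i.e. ≈ 32 820 ng / 4.525
mL/h ≈ 7 253 h·ng/mL for a 0.06 mg dose — independent of the shape of the
release.

## Synthetic data

`generate_observed()` emulates the structure of the clinical mean
profiles: the clinical sampling grid (0, 0.08, 0.25, 0.5, 1, 2, 3, 4, 6,
8, 12 h per dose plus 16–72 h washout), multiplicative lognormal error
with mean 1 (default CV 10%), optional additive error, and LLOQ-to-zero
censoring (default 0.05 ng/mL — a plausible bioanalytical limit; the
true assay LLOQ is not public and the value is configurable and recorded
in the series metadata). Under the defaults, an intranasal profile loses
its post-24 h tail (and occasionally the 0.08 h absorption-phase sample)
below the LLOQ, mimicking the reported pattern of zeroed late means.

What the generator does **not** emulate: between-subject variability
within a mean profile (it produces mean-level noise, as the reference
fits are to means), assay heteroscedasticity beyond the proportional
term, sampling-time deviations, and any model misspecification — passing
recovery tests therefore demonstrates estimator correctness under the
model's own assumptions, not robustness to structural error in real data.

## Numerical choices

* Integrator: `deSolve::lsoda` with rtol 1e-8, atol 1e-6 ng, compiled C
  right-hand side (the R implementation `pbpk_rhs()` is the cross-checked
  reference); hard restart at every dose event. The fastest rate in the
  system (alveolar ELF → tissue, ~1 240 h⁻¹) makes the problem stiff.
* Reported states at a dose instant are pre-dose (the integrator
  convention); mass-balance bookkeeping follows the same convention.
* Concentrations are clipped at 0 for reporting; any state more negative
  than the integrator tolerance aborts the run.
* Simulation problem sizes in the shipped tests: n = 300 and n = 500
  population runs (matching the reference study sizes), 2 000 subjects for
  the mean-vs-typical profile property, 50 Monte-Carlo replicates for the
  estimator-bias study, 50 000 draws for distributional checks.

## Known limitations

* The fine structure of the nasal peak depends on unpublished detail of
  the source model. This implementation peaks at 0.25 h (grid) at
  ~8 390 ng/mL versus the reported 7 984 ng/mL at 0.08 h — agreement to
  ~5%, checked loosely at ±10%.
* The reference nasal AUC0–12 (≈1 815 h·ng/mL, with a ~240 ng/mL 12-h
  plateau) is not reproduced — and, with symmetric PS exchange, cannot
  be: it implies a tissue:plasma partition of ~2 000 at late times where
  the stated physiology gives `fu_p/fu_tissue = 0.8`. The quantities that
  do not depend on this plateau (nasal AUC0–∞, CL/F, V/F, terminal t½,
  accumulation ratios) all reproduce.
* Peripheral distribution compartments are carried as parameters
  (k12/k21/k13/k31) but fixed at 0, as in the reference analysis; the
  simulator refuses nonzero values rather than silently ignoring them.
* Fits are to mean profiles; there is no mixed-effects machinery, no
  covariate model, and no correlation between CL and Vc in the population
  sampler.
* No enterohepatic recirculation, first-pass metabolism, nonlinear
  binding, or particle-size-resolved deposition physics; deposition
  fractions are inputs (or fitted), not predicted from droplet spectra.
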