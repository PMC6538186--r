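---
title: "Methods: the PBTK model, the concordance statistic, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PBTK model, the concordance statistic, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models and
their assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical
choices, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. The PBTK model

The rat model has eight states: gut lumen (amount), gut, liver, kidney,
lung, rest-of-body, arterial plasma and venous plasma. Oral boluses
enter the gut lumen and are absorbed into gut tissue at a first-order
rate `k_gutabs`; the fraction absorbed is 100%. Tissues exchange with
plasma in a perfusion-limited fashion: the plasma leaving tissue *t*
carries total concentration `C_t / (Kp_t · fup)`, where `Kp_t` is the
tissue:unbound-plasma partition coefficient. The liver receives the gut
venous outflow plus its arterial supply (so oral doses are subject to
first-pass extraction) and eliminates chemical at the well-stirred
hepatic plasma clearance; the kidney eliminates by glomerular
filtration. The lung sits between venous and arterial plasma and is
non-eliminating.

**Assumptions.** Plasma-only description (no blood:plasma partition
ratio; "tissue concentration" means the total concentration of the
named compartment); no enterohepatic recirculation, transporters,
metabolite tracking, or gut metabolism; linear (non-saturable)
clearance throughout. Intravenous dosing is structurally possible but
unused.

**Renal convention.** Renal clearance is `CLr = GFR · fup`. The
filtration flux is taken from the *incoming arterial plasma*
(glomerular filtration physically samples afferent plasma) rather than
from the equilibrated kidney-outflow concentration. Both conventions
appear in the literature; the arterial convention was chosen because
(a) it is at least as defensible physiologically, (b) it preserves the
cooperative structure of the system matrix (`GFR` is well below the
kidney plasma flow), and (c) it makes the renal part of the analytic
steady-state oracle exact, so oracle deviations isolate hepatic
first-pass effects. This choice was made after observing that the
kidney-outflow convention produces an *effective* renal clearance
materially below `GFR · fup` for high-`fup` chemicals (renal extraction
ratios up to 0.6), which is a modeling convention artifact rather than
toxicokinetics we intend to represent.

**Exact integration.** Between boluses the system is linear and
time-invariant, so each dosing interval is propagated by one matrix
exponential; running integrals (AUC per compartment) and the cumulative
cleared amount are augmented states propagated by the same exponential.
Consequences: dose linearity and mass balance hold to machine precision
(the test suite asserts 1e-6 and 1e-9 where an adaptive solver would
need tuned tolerances), and the mean concentration (AUC divided by the
dosing-window length) is exact, not a quadrature.

**Maxima.** All off-diagonal entries of the system matrix are
nonnegative (a Metzler/cooperative system), so the propagator is
elementwise nonnegative, and with identical repeated boluses the
post-dose state increases componentwise from interval to interval. The
global concentration maximum therefore occurs in the final dosing
interval, which is scanned on a 0.1 h grid.

**Physiology.** Constants live in `inst/config/rat_physiology.yaml`
(plasma flows L/h/kg: cardiac 3.70, gut 0.52, hepatic artery 0.08,
kidney 0.52, rest 2.58; GFR 0.312 L/h/kg; hepatocellularity 110 × 10⁶
cells/g liver; 34 g liver/kg; `k_gutabs` 2 h⁻¹; 0.25 kg reference
animal). They are rounded literature-class rat values, deliberately
config rather than code. Study-length conventions: chronic 730 d,
subchronic 90 d, subacute 28 d; developmental studies default to 21 d
(a gestational window) because no canonical number exists — users
should review this default for developmental analyses.

**Partitioning.** The default scheme is a Schmitt-style composition
calculator: `Kp = fw + fn·(fnl·10^logP + fpl·10^(0.3 + 0.9·logP)) +
fpr·Ka`, with `fn` the neutral fraction at pH 7.4
(Henderson–Hasselbalch, per-site terms summed independently for
multiprotic chemicals), and `Ka = max(0, 1/fup − 1)/fpr_plasma` a
tissue-protein association constant back-calculated from plasma
binding (plasma binding is assumed protein-dominated). Ionized species
are assumed to stay aqueous. The scheme is pluggable; tissue
compositions are config.

**Clearance scaling.** Measured `Clint` (µL/min/10⁶ cells) is divided
by the unbound fraction in the incubation (Kilford-style relation,
`fu_hep = 1/(1 + 125·VR·10^(0.072·logP² + 0.067·logP − 1.126))`,
VR = 0.005; disable by passing `fu_hep = NULL`), scaled by
hepatocellularity × liver mass, then passed through the well-stirred
model with `fub = fup` (restrictive) or 1 (nonrestrictive). The
published non-specific-binding correction for the plasma-binding assay
is *not* reproduced (the source does not restate the formula);
`correct_fup_nonspecific_binding()` is an identity with a pluggable
hook so the published correction can be installed. The fup
limit-of-detection default (0.005) is applied uniformly, including to
literature-sourced chemicals, with the below-LOD flag recorded.

## 2. The in vitro disposition model

`distribute_in_vitro()` solves the linear equilibrium mass balance of a
dosed amount over aqueous medium, serum lipid, serum protein, cell
storage lipid, cell membrane lipid, cell protein, headspace and
plastic: `C_aq = N / (V_aq + Σ V_i·K_i)`. Partition relations (all
config, `inst/config/assay_wells.yaml`, log10 K = a·logP + b form):
storage lipid (1.00, 0), membrane lipid (1.01, 0.12), serum protein
(0.71, 0.42), cell protein = 0.05 × serum protein, plastic area-based
(0.97, −6.94; K in m), headspace via the dimensionless Henry constant
at 37 °C. Only the neutral species partitions out of the aqueous phase
(config switch). Well geometries for 96/384/1536 formats and
serum/cell compositions are vendor-class config values. The model is
non-saturable, so the aqueous/nominal `factor` is scale-invariant;
kinetic uptake and intracellular endpoints are out of scope — the
comparisons use the aqueous concentration. A chemical with headspace
but no Henry constant falls back to nonvolatile with a warning. The
disposition model is applied uniformly when an assumption set has it
switched on (no per-assay cell-free/cell-based distinction), matching
the aggregate character of the analysis.

## 3. Dosimetry and assumption sets

κ is the selected concentration at 1 mg/kg/day dosed once daily over
the study length (divided by the disposition factor when applicable),
cached per (chemical, study length, assumption label). `C = dose·κ`,
`AED = AC50/κ`; forward and reverse log-residuals are exactly equal and
opposite. The evaluated grid is {restrictive, nonrestrictive} × {total
venous, free venous, tissue(total)} × {mean, max}, plus the disposition
model combined with the mean venous selections only (16 sets). The
tissue compartment defaults to liver — which tissue the aggregate
analyses used per assay is not identifiable, so the pipeline makes it a
parameter. Labels follow the `res.-free-vein-mean-Armitage` grammar.

## 4. The concordance analysis

Comparisons merge clean positive AC50s (positive hit call, no
curve-fit flags; duplicate chemical × assay rows collapse to the
minimum AC50) with in vivo doses (endpoint level: minimum dose per
study × chemical × endpoint, study types separate, multigenerational
studies excluded; a chemical with multiple studies of one endpoint
enters a comparison at its minimum dose — the collapse rule is not
stated by the source analysis, and the minimum matches its conservative
conventions elsewhere). POD level: per-chemical minimum of pooled
LOEL/LOAEL values after filtering to oral rat records with usable
units and durations. Comparisons need ≥ 5 unique chemicals (threshold
configurable; 20 is the stricter reported cut).

Standardization uses the sample (n−1) standard deviation; zero-variance
vectors raise a typed degenerate-comparison condition and the
comparison is skipped and logged. ORMSE is always measured against the
φ = θ line. For standardized inputs, `ORMSE² = ((n−1)/n)(1−r)` exactly
(r = Pearson correlation); the pipeline's batch scorer uses this
identity for speed while the direct `standardize()` + `ormse()` route
is kept independent, and the two are cross-checked in the tests to
1e-10. Near r = 1 the identity amplifies machine epsilon by a square
root, so "zero ORMSE" fixtures assert < 1e-6.

The randomization null resamples the comparison's chemical vector with
replacement, ten times; only TK and physicochemical identity is
randomized — dose, AC50 and study length stay with the original record,
and the randomized κ is looked up at the original record's study length
(nearest simulated length if absent, logged). Per-comparison seeds are
derived from the master seed plus an FNV-1a hash of the comparison
identifier, so comparisons are independently reproducible and the whole
run is deterministic given the config. Wins go to the strictly lowest
ORMSE; exact ties break conservatively *against* the PBTK model
(untransformed > random > PBTK). Win counts are summarized by median ±
SD across the ten sets, plus the PBTK win fraction per assumption set
and direction.

The POD₁₀/AED₁₀ comparison takes per-chemical lower 10th percentiles
(linear interpolation at rank 1 + (n−1)q, R type-7), with AEDs computed
from every clean AC50 at the time scale of the chemical's minimum-dose
POD record; it reports RMSE and ORMSE of the log10 pairs, the
conservatism rate (fraction of chemicals with AED₁₀ ≤ POD₁₀), and
|Pearson correlation| of residuals against fup, Clint, logP, logD and
MW as a bias screen.

## 5. The synthetic world

The generator emulates the four input schemas with the statistical
structure the analysis assumes. Chemicals: fup logit-normal (logit mean
−2.2, sd 1.5) clipped to [0.005, 1]; Clint lognormal (meanlog 2.3,
sdlog 1.2, µL/min/10⁶ cells) with a 20% point mass at zero (chemicals
with no observed parent disappearance), a fifth of nonzero values
measured only at 10 µM to exercise the fallback; logP ~ N(2.5, 1.5²);
acid/base/neutral classes 25/25/50% with one pKa ~ U(3, 10); MW ~
U(100, 500). Bioactivity: each chemical carries a latent log10 potency
~ N(0.5, 1²) shared by all its assays; assays add a fixed shift ~
N(0, 0.5²); a (chemical, assay) pair is active with probability 0.3,
and 10% of positives carry a synthetic curve-fit flag. In vivo
coupling: `dose = (10^potency / κ_true) · 10^ε` with ε ~ N(0,
noise_sd²), κ_true evaluated under the generating assumption set
(default `res.-free-vein-mean`) at the study-type length; study types
chronic/subchronic/developmental 40/40/20% at the endpoint level,
POD records across subacute/subchronic/chronic.

Two deliberate deviations from a literal reading of the statistical
recipe, both needed for internal consistency: (1) AC50s share a
chemical-level potency rather than being independent per (chemical,
assay) pair — otherwise noiseless generation could not be a fixed
point of the pipeline across *all* comparisons, which the acceptance
criteria require; the marginal AC50 distribution stays normal in
log10. (2) The "shuffled labels" null permutes the chemical labels of
the generated in vivo tables after generation, which decouples doses
from both the labelled chemical's TK (PBTK predictor) *and* its
bioactivity (untransformed predictor); shuffling only the κ lookup
would leave the untransformed predictor a systematic edge, and no
permutation scheme short of full label shuffling makes all three
predictors exchangeable.

What a green calibration test establishes: on data whose dose–AC50
coupling follows the stated world (single lognormal noise dial, one
true assumption set, potency-dominated assay structure), the pipeline
ranks the generating assumption set first by median PBTK win fraction
and the PBTK predictor beats both nulls in the stated proportion of
contests. What it does not establish: anything about the real marginal
distributions of public screening/toxicity databases, per-assay
mechanistic mappings, or performance under structured (non-lognormal,
chemical-class-correlated) errors — the generator does not attempt to
emulate those.

## 6. Numerical choices and degenerate inputs

- Matrix exponentials via `Matrix::expm` (dense, 17×17); no ODE solver
  tolerances exist. Exchange/clearance enter one propagator, so mass
  balance is exact by construction.
- Exchangeability of the null world is asserted as all three pooled win
  fractions within ±0.15 of 1/3 — generous because contests sharing
  chemicals are correlated, so a formal i.i.d. binomial band would be
  anti-conservative.
- Zero dose returns the exact zero solution without integrating.
- The steady-state oracle `Css = rate/(CLh + CLr)` is undefined at zero
  total clearance and signals an error. Its validity domain is low
  hepatic extraction (< 5% used in tests; the closed form has no
  first-pass loss) and half-life well under the horizon.
- Degenerate comparisons (zero variance after filtering) are skipped,
  never scored as ties.
- CSVs round-trip doubles at 15 significant digits (`write.csv`
  serialization); κ tables re-read from disk reproduce scores to
  1e-14.
- Seeds: one master seed; everything downstream is a pure function of
  it. Derived per-comparison seeds stay below 2³¹.

## 7. Known limitations

- The PBTK model is perfusion-limited and plasma-based; permeability
  limitation, active transport (hepatic or renal), plasma:blood
  partitioning and gut metabolism are absent. Nonrestrictive-clearance
  results inherit the well-stirred model's known biases.
- The disposition model is equilibrium-only; slow binding kinetics in
  long incubations are not represented.
- The developmental study-length default (21 d) and the liver default
  for tissue metrics are conventions, not fitted values.
- Win counting is sensitive to the ±0.15 exchangeability band at small
  comparison counts; at the calibration scale (hundreds of
  comparisons) it is not.
- No multiple-testing correction is applied anywhere, matching the
  aggregate, descriptive character of the analysis.
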