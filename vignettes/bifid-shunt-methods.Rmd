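---
title: "Methods: stoichiometric and statistical models in bifidshunt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stoichiometric and statistical models in bifidshunt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifidshunt)
```

## The fermentation problem

*Bifidobacterium longum* subsp. *infantis* ferments milk carbohydrates
through the fructose-6-phosphate phosphoketolase (F6PPK) pathway, unique to
the genus: phosphoketolase activity splits hexose phosphates so that every
2 hexose units yield 3 acetyl-phosphate and 2 glyceraldehyde-3-phosphate,
the former dephosphorylated to acetate (one ATP each by acetate kinase), the
latter oxidized to pyruvate. When all pyruvate is reduced to lactate the
classical yield is 3 acetate : 2 lactate per 2 hexose — an acetate:lactate
molar ratio of exactly 1.5. On the human-milk-oligosaccharide
tetrasaccharides LNT and LNnT this ratio shifts upward, for two reasons the
model separates: the GlcNAc residue releases one free acetate upon
deacetylation, and part of the pyruvate pool can be diverted through
pyruvate-formate lyase (PFL) to formate plus acetyl-CoA, which is then
either converted to acetate (gaining ATP) or reduced twice to ethanol
(regenerating NAD⁺).

## The forward model and its parameters

`predict_fluxes()` works in moles per mole of substrate. A substrate is its
composition: `hexose_equivalents` H (every hexose residue, including the
glucosamine backbone of a deacetylated/deaminated GlcNAc), `glcnac_residues`
N, and `carbon_atoms` (6(H−N) + 8N for the built-ins; the two extra carbons
per GlcNAc are the acetyl group that leaves as free acetate). Two
dimensionless fractions partition the lower pathway:

* `f` ∈ [0, 1] — pyruvate routed through PFL; the remainder becomes lactate.
* `g` ∈ [0, 1] — PFL-derived acetyl-CoA converted to acetate; the remainder
  becomes ethanol.

The yields are linear in (f, g): acetate = 3/2·H + H·f·g + N, lactate =
H(1−f), formate = H·f, ethanol = H·f(1−g). Carbon conservation
(2·acetate + 3·lactate + formate + 2·ethanol = carbon count) holds as an
algebraic identity, which the tests exercise over random draws; there is no
CO₂ term because PFL retains the carboxyl carbon in formate.

Three bookkeeping choices were genuinely open and are configurable:

* **ATP per glyceraldehyde-3-phosphate** (`atp_per_gap`, default 1). The
  pathway description we follow counts a single substrate-level
  phosphorylation for the oxidation to pyruvate; the textbook lower-glycolysis
  count is 2 (phosphoglycerate kinase + pyruvate kinase). The default keeps
  the stated convention — ATP per hexose at f = 0 with unit activation cost
  is then exactly 1.5 — and the knob exposes the textbook alternative.
* **Deacetylation acetate carries no ATP**: it is free acetate, not
  acetyl-phosphate, so it contributes to the acetate pool and to carbon but
  not to ATP. The phosphorylation cost of the GlcNAc backbone is folded into
  `activation_atp_per_hexose` (default 1 per hexose equivalent).
* **GlcNAc anabolic diversion** (`glcnac_bypass`, default 0): HMO-bound
  GlcNAc may be siphoned into peptidoglycan and other biosyntheses rather
  than fully catabolized. A diverted residue contributes neither a hexose
  equivalent nor a deacetylation acetate. The default assumes full
  catabolism, the simplest reading of the endproduct data.

`shunt_params(enforce_redox_balance = TRUE)` pins g = 1/2 whenever f > 0:
the NADH residual is H·f(2g−1), and g = 1/2 is the point where the
two-NAD⁺-per-mole ethanol arm exactly replaces the lactate arm's cofactor
recycling.

### Two theoretical ratios with ambiguous published parameterizations

The formate:acetate ratio of 2:5 is reproduced by this model only in the
limit f = 1, g = 1 (formate 2, acetate 3/2·2 + 2·1·1 = 5 per 2 hexose); we
adopt that limiting parameterization as the definition of the theoretical
value. The ethanol:lactate ratio of 1 "when half of acetyl-CoA goes to
ethanol" does not by itself pin f; g = 1/2 makes ethanol = lactate exactly
when f = 2/3, and the package uses that as one consistent solution without
claiming it is the only intended one.

## The inverse problem

`fit_shunt()` estimates (f, g, S) from a measured panel (mM), where S is the
substrate consumed. Because predicted concentrations are S·y(f, g), the
optimal S given (f, g) is the non-negative closed form
Σyᵢoᵢ / Σyᵢ², so the optimizer profiles over (f, g) only: L-BFGS-B within
the unit square from a 5 × 5 multi-start grid (ties broken by smallest
residual, then smallest f), followed by a `nlminb` polish to tight
tolerances. Noiseless forward-generated panels are recovered to 1e-6, which
the tests confirm against an exhaustive 0.01-step grid search written
independently of the optimizer.

Identifiability: when formate and ethanol are both zero or unmeasured the
data contain no information about the acetyl-CoA split, so g is reported
`NA` with `g_identifiable = FALSE` and f = 0. A panel must measure lactate
and at least one other analyte; this admits published mean panels in which
acetate was not reported.

## Growth kinetics

The growth model ΔOD(t) = ΔOD_asym·{1/(1+e^{k(tc−t)}) − 1/(1+e^{k·tc})} is a
logistic with a zero-anchor term making ΔOD(0) = 0 exactly; its attainable
plateau is ΔOD_asym·(1 − 1/(1+e^{k·tc})), slightly below ΔOD_asym, and the
reported asymptote is the fitted ΔOD_asym, matching common usage. Because of
the anchor term the family is *not* closed under time translation, so fits
on offset time axes agree only approximately (closely, once k·tc ≳ 4); the
tests check this as an approximate coordinate-convention property.

Fitting is Levenberg-Marquardt (`minpack.lm::nlsLM`) with data-driven
starts — asymptote from max(OD), inflection from the steepest
finite-difference slope, k from that slope via max slope = ΔOD_asym·k/4 —
plus a small multi-start over perturbed starts. Curves with dynamic range
below 0.05 OD (configurable; no published threshold exists) return a
"no-growth" result rather than an error, since flat wells are expected for
non-utilized substrates. Blank correction subtracts the mean of the
no-carbohydrate control and clips at zero. The replicate-outlier rule
removes at most the single farthest-from-mean replicate, only when its
deviation exceeds 3× the SD of the others and at least three replicates
remain.

## Quantitation

Calibration lines are ordinary least squares with intercept (a zero-intercept
mode is available); the standard series is the six-level 0.5–50 mM dilution
used for organic-acid HPLC, and curves warn below r² = 0.99. Technical
duplicates are averaged per sample × analyte with discordance above 10%
flagged. Sugar consumption is 100·(pre − post)/pre, reported negative (with a
warning) when post exceeds pre. Carbon recovery divides metabolite carbon
(lactate 3, acetate 2, formate 1, ethanol 2 per mole, from molecular
formulas) by consumed substrate carbon (pre-fermentation carbon minus
residual-sugar carbon); it is exactly 100% on any noiseless forward-model
panel — the identity that ties the quantitation and stoichiometry modules
together in the tests — and may legitimately exceed 100% on real data, e.g.
when residual disaccharide hydrolyzes post-fermentation.

## Ratio statistics

Ratios are always computed per replicate, never as ratios of group means,
and zero-denominator ratios carry an explicit undefined flag and are
excluded (not zero-filled) from statistics. One-way ANOVA uses `aov`;
two-way designs fit both factors with interaction and report type II sums of
squares (the designs are near-balanced triplicates, and type II does not
depend on factor order). All pairwise comparisons use Tukey's HSD via the
studentized-range distribution (`ptukey`/`qtukey`, validated in the tests
against published 5% critical values up to k = 6), which reduces to the
Tukey-Kramer adjustment under imbalance and collapses to the pooled-variance
t-test at two groups. Simple effects in two-way designs are within-level
one-way Tukey comparisons. PCA centers (optionally scales) columns and
canonicalizes loading signs so the largest-magnitude element of each
component is positive; encoding absent growth as 0 is the caller's choice —
row exclusion is equally supported. Ward clustering uses Euclidean distances
with the `ward.D2` criterion, whose merge heights are guaranteed monotone;
the test oracle is an independent greedy implementation of the Ward cost
n_a·n_b/(n_a+n_b)·‖c_a − c_b‖². Heatmap-style scaling (per-metabolite
mean-centering and division by SD) is available via `scale_columns`.

## Relative expression

ΔΔCt uses a perfect-doubling efficiency of 2 by default (an `efficiency`
knob admits corrected values), averages technical replicates before any
biological statistics, forms ΔCt against the sample's endogenous control,
and references the mean ΔCt of the reference condition. The biological
summary is the geometric mean fold (2^(−mean ΔΔCt)); dispersion is the SD of
log2 folds, reported on the linear scale as fold·(2^sd − 1), since the
published convention for fold-change error bars is not stated.

## What the synthetic data emulate — and what they do not

The generators produce every input the pipeline consumes, deterministically
under an integer seed: sigmoidal OD600 curves with additive Gaussian noise
(clipped at 0) plus a blank series; endproduct panels as S·yields(f, g)
under multiplicative lognormal noise of configurable CV (concentrations are
positive, and the error model for HPLC areas is plausibly multiplicative;
unit-mean noise keeps the panels unbiased); linear calibration responses
with additive noise; and Ct records built from a common control Ct per
sample so that fold changes are exactly recoverable at zero noise.

Preset parameters are named for the study conditions they emulate: growth
kinetics use the reported type-strain values (lactose 1.27/0.56 h⁻¹,
galactose 1.20/0.61, LNT 1.19/0.51, LNnT 0.85/0.57) with an inflection time
of 8 h — not reported, chosen as realistic for a 1% overnight inoculum — on
the 48 h assay grid; fermentation presets use illustrative flux partitions
(LNnT-like f = 0.5, g = 0.9; near-classical f ≤ 0.05 elsewhere) with
pre-fermentation concentrations corresponding to 2% w/v. These mimic the
direction and rough size of the published shifts, not fitted ground truth.

The generators do **not** emulate several features of real data: lag and
diauxic growth phases, plate-edge and evaporation artifacts, correlated
technical error within HPLC runs, calibration drift, amplification-efficiency
variation between primer pairs, or the carbon-recovery overshoot caused by
residual-disaccharide hydrolysis. Passing parameter-recovery tests therefore
demonstrates correctness of the estimators under the stated error models,
not robustness to these real-world violations.

## Problem sizes and numerical choices in the test suite

Simulation-based checks use 100 replicate datasets (growth-rate recovery at
σ = 0.02 OD; f-recovery at 5% CV), 1000 random draws for carbon
conservation, 50 six-point instances for the clustering oracle, and 50
replicate qPCR simulations — sizes at which the Monte-Carlo error is far
below the asserted tolerances while the whole suite runs in minutes.
Optimizer tolerances (L-BFGS-B `factr = 10` with an `nlminb` polish at
relative tolerance 1e-15) were set to meet the 1e-6 recovery contract on
noiseless data. Ties in the multi-start selection prefer smaller residual,
then smaller f, making fits reproducible.

## Known limitations

The stoichiometric model is a yield model, not a kinetic one: it says
nothing about when endproducts appear, and temporal shifts (e.g. early
lactate later replaced by formate) are outside its scope. Flux estimates
inherit the model's assumption that all consumed substrate carbon leaves
through the four measured endproducts; biomass incorporation biases S
downward. Two-parameter identifiability degrades as f → 0 (formate and
ethanol vanish together), which the boundary and identifiability flags
surface but do not cure. Genome-scale modeling, time-resolved ODE
fermentation models, and transcriptome reanalysis are deliberately out of
scope.
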