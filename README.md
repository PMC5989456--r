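# bifidshunt

Quantitative analysis of *Bifidobacterium longum* subsp. *infantis*
fermentation of milk carbohydrates — galactose, lactose and the isomeric
human-milk-oligosaccharide tetrasaccharides LNT and LNnT — built around a
forward/inverse stoichiometric model of the fructose-6-phosphate
phosphoketolase (F6PPK, "bifid shunt") pathway. It is aimed at microbial
physiologists who profile fermentation endproducts by HPLC, fit microplate
OD600 growth curves, and quantify gene expression by qPCR, and who want those
analyses reproducible and testable end to end.

## The model

The bifid shunt converts 2 hexose units into 3 acetate + 2 lactate
(acetate:lactate = 1.5). Per hexose equivalent *H* of a substrate carrying
*N* GlcNAc residues, with a fraction *f* of pyruvate routed through
pyruvate-formate lyase (PFL) and a fraction *g* of the resulting acetyl-CoA
converted to acetate (the remainder to ethanol):

    acetate  = 3/2·H + H·f·g + N        (N: free acetate from GlcNAc deacetylation)
    lactate  = H·(1 − f)
    formate  = H·f
    ethanol  = H·f·(1 − g)
    ATP      = 3/2·H + H + H·f·g − H    (unit activation cost per hexose)
    NADH     = H·f·(2g − 1)             (residual; 0 iff f = 0 or g = 1/2)

Carbon is conserved exactly: 2·acetate + 3·lactate + formate + 2·ethanol
equals the substrate's carbon count for every (f, g) ∈ [0,1]². The inverse
problem — estimating (f, g) and the substrate consumed *S* (mM) from a
measured endproduct panel — is solved by bounded least squares with the scale
profiled out in closed form.

Around this core the package provides: the three-parameter sigmoidal growth
model ΔOD(t) = ΔOD_asym·{1/(1+e^{k(tc−t)}) − 1/(1+e^{k·tc})} with
Levenberg-Marquardt fitting; external-standard HPLC calibration,
sugar-consumption and carbon-recovery percentages; per-replicate endproduct
ratios with one/two-way ANOVA + Tukey HSD, PCA and Ward/Euclidean
clustering; ΔΔCt relative expression against an endogenous control; and
seeded synthetic-data generators for every input.

## Worked example

```r
library(bifidshunt)

# Forward model: an LNnT-like shift (half of pyruvate through PFL,
# 90% of acetyl-CoA to acetate)
flux <- predict_fluxes(get_substrate("lnnt"), shunt_params(f = 0.5, g = 0.9))
theoretical_ratios(flux)
#>   substrate   f   g aa_la ... fa_aa  ... et_la
#> 1      lnnt 0.5 0.9   4.4     0.2273      0.1

# Inverse model on a noisy synthetic panel generated from (f=0.5, g=0.9, S=14.75)
panels <- simulate_fermentation(cv = 0.05, seed = 42)
lnnt1  <- dplyr::filter(panels, substrate == "lnnt")[1, ]
fit_shunt(lnnt1, get_substrate("lnnt"))
#> Bifid-shunt flux-partition fit
#>   f (pyruvate -> PFL)        : 0.4857
#>   g (acetyl-CoA -> acetate)  : 0.911
#>   substrate consumed (mM)    : 14.156
#>   residual norm (mM)         : 1.794

# Growth kinetics on a lactose-like curve (truth: 1.27, 0.56 h^-1, 8 h)
g <- simulate_growth(growth_presets()[2, ], noise_sd = 0.02, seed = 42)
fit_growth(dplyr::filter(g, substrate == "lactose", replicate == "rep1"))
#> Growth fit: od_asym = 1.264, k = 0.5642 h^-1, tc = 7.859 h (RSS 0.0226, n 49)
```

The flux prediction says a mole of LNnT fermented under that partition yields
4.4 moles of acetate per mole of lactate (versus the classical 1.5),
measurable formate, and a little ethanol; the inverse fit recovers the
generating parameters from the noisy concentrations to within a few percent,
and the growth fit recovers the configured kinetics.

Fitted objects support `tidy()`/`glance()`, and `autoplot()`/`plot_*()`
functions draw growth curves, ratio bar charts and PCA biplots.
`run_pipeline()` chains all stages and writes provenance-stamped CSV tables
plus a Newick dendrogram.

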