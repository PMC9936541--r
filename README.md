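# amylokin

Kinetic analysis of small-molecule modulators of amyloid-beta (Abeta42)
aggregation from thioflavin-T (ThT) plate-reader data.

Compounds that speed up or slow down amyloid formation are screened by
the half-time of the sigmoidal ThT curve, and their mechanism is
resolved into the three microscopic steps of quiescent Abeta42
aggregation — primary nucleation (k_n), fibril-catalysed secondary
nucleation (k_2) and elongation (k_+) — using the two-moment master
equation

    dP/dt = k_n m^nc + k_2 m^n2 M        (fibril number)
    dM/dt = 2 k_+ m P,   m = m_tot - M   (fibril mass)

Unseeded kinetics identify only the products k_+ k_n and k_+ k_2;
high-seeded assays expose k_+ through early growth rates, and
low-seeded assays then pin down k_2 at doses where elongation is
untouched. The package implements that full decoupling workflow, a
Dunnett-based screen caller, and a two-compound mixture analysis that
locates the dose region where an inhibitor and an accelerator cancel
to a near-zero net effect. A synthetic-data module generates
plate-reader-like datasets (dose-dependent modulators, a
micellar-switch amphiphile, seeded arms, replicate and noise
structure) with a ground-truth sidecar, so every estimator is testable
end to end without external data.

## Worked example

Screen 18 vitamin metabolites (packaged annotation table) at 10 molar
equivalents against 2 uM Abeta42, triplicate wells, and call hits
against the DMSO vehicle control with ANOVA + Dunnett at alpha = 0.05:

```r
library(amylokin)
ann <- read_metabolite_annotations()
ds  <- generate_screen(ann, seed = 1)          # 60 wells, truth sidecar
res <- analyze_screen(ds, control = "DMSO", alpha = 0.05)
subset(as.data.frame(res), call != "no-effect",
       select = c(compound, mean_halftime, delta, p_adj, call))
```

```
          compound mean_halftime   delta     p_adj        call
1 positive-control        0.3461 -0.4175 2.009e-12 accelerator
2        cobalamin        0.3403 -0.4233 2.009e-12 accelerator
3  cholecalciferol        0.3436 -0.4200 2.009e-12 accelerator
4   ergocalciferol        0.3488 -0.4148 2.009e-12 accelerator
5      menaquinone        1.7058  0.9422 2.009e-12   inhibitor
6        menadione        1.7104  0.9468 2.009e-12   inhibitor
7    retinoic acid        1.7277  0.9640 2.009e-12   inhibitor
8 alpha-tocopherol        0.3439 -0.4197 2.009e-12 accelerator
```

Half-times are in hours; `delta` is the difference to the control mean
(0.764 h at this seed), and `p_adj` the Dunnett-adjusted p-value
(floored at the quadrature resolution). The three
inhibition-annotated metabolites come out as significant delayers and
the four acceleration-annotated ones as significant accelerators
(exact values vary with the simulation seed).

Mechanistic dose series and mixture analysis:

```r
mod <- retinoid_like()                       # nucleation inhibitor
ds  <- generate_dose_series(mod, seed = 1)   # unseeded + 2% + 30% arms
df  <- fit_dose_series(ds)                   # r_primary, r_secondary per dose
el  <- elongation_from_high_seed(ds)         # r_plus from early slopes
sec <- secondary_from_low_seed(ds, attr(df, "baseline"), el)
attribute_mechanism(df, el, sec)             # which of k_n, k_2, k_+ changed
```

The mechanism report flags primary and secondary nucleation at 1-7 ME,
and at 10 ME — where elongation itself is affected (r_plus ~ 0.5) —
declines to attribute nucleation, mirroring how seeded assays lose
their decoupling power once k_+ moves.

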