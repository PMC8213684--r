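# tetrixmra

Morphometric species delimitation by **multivariate ratio analysis (MRA)**,
built for the classic problem posed by the *Tetrix bipunctata* pygmy
grasshopper complex: two widely sympatric wing morphs, *bipunctata*
(long-winged) and *kraussi* (short-winged), that taxonomists have
alternately treated as forms, subspecies, or species. The package is for
taxonomists and morphometricians who work with tables of linear distance
measurements (mm) and want to answer, quantitatively:

* Is there more than one character separating the groups, once isometric
  size is removed?
* Which body **ratios** separate them best?
* Could the difference be mere **allometric scaling** — a shift along a
  shared allometric axis — rather than a real shape difference?
* Do the morphs differ in microhabitat niche, altitude, and do they
  co-occur (syntopy)?

## The method

For a specimen with measurements *x*₁…*x*ₚ, MRA defines

* **isosize** = (∏ᵢ *x*ᵢ)^(1/p), the geometric mean — the scalar measure of
  isometric size;
* **log-shape values** log *x*ᵢ − log(isosize), which are invariant to
  isometric rescaling and sum to zero within each specimen;
* the **shape PCA**, an eigendecomposition of the covariance matrix of the
  log-shape values: each component is a pure shape contrast;
* the **PCA ratio spectrum**, the eigenvector coefficients of a shape PC
  arranged along an axis with bootstrap confidence intervals — characters at
  opposite extremes form the most influential body ratios;
* the **ratio extractor**, which scores every log-ratio
  log *x*ᵢ − log *x*ⱼ by its standardised group separation
  δ = |mean difference| / pooled within-group SD, and extracts successive
  ratios that are both discriminating and least correlated with earlier
  picks (score δ·(1 − max|ρ|));
* the **allometry/ANCOVA stage**: per-group regressions of a shape axis on
  log-isosize plus a common-slope model whose group offset at common size,
  with its 95% interval, operationalises the test against pure allometric
  scaling.

Around this core sit the canonical 20-character dictionary (17 retained),
chained-equations imputation of missing body parts (log scale, predictive
mean matching), the standard hind-wing/tegmen ratio classifier
(ratio ≥ 2.5 → *bipunctata*), two-way niche ANOVAs, great-circle syntopy
detection, altitudinal profiles, and a synthetic-data generator that
reproduces the two-morph structure so every stage is testable end to end.

## Worked example

```r
library(tetrixmra)

# synthetic two-morph data: 100 + 100 specimens, 17 characters,
# a +0.35 log-unit contrast on hind wing length only, 5% missing cells
m   <- gen_morphometrics(morpho_sim_config(missing_rate = 0.05, seed = 1))
res <- mra_analysis(m, seed = 1)
print(res)
```

```
Measurement matrix: 200 specimens x 17 characters (mm)
  morphs:     bipunctata (100), kraussi (100)
  missing:    0 cells in 0 specimens
Imputation: 176 cells in 122 specimens filled (10 sweeps, seed 1)
Shape PCA
  variance explained (%): PC1 75.3, PC2 2.6, PC3 2.4, PC4 2.1 ...
  PC1 ratio spectrum extremes: hwi.l (top) vs fro.h (bottom)
Best discriminating ratios (bipunctata vs kraussi)
  1. hwi.l / eye.h   delta = 5.76
  2. hwi.l / vrt.b   delta = 5.75  (max |rho| with earlier = 0.81)
  3. hwi.l / eye.b   delta = 5.67  (max |rho| with earlier = 0.81)
Allometry analysis
  per-group slopes:
      group   n      slope  intercept
 bipunctata 100 0.04871193  0.1442305
    kraussi 100 0.13481449 -0.2150629
  common slope: 0.0936
  group offset at common size: -0.3245  [-0.3428, -0.3063] (95%)
  size ANOVA: F_1,198 = 75.29, p = 1.48e-15
```

Reading this: the first shape PC carries three quarters of the shape
variance and its ratio spectrum isolates hind wing length (`hwi.l`) at one
end — every ratio formed with it separates the morphs, which is why the
extractor's top ratios all involve `hwi.l` with δ far above anything else
(compare `extract_ratios(m, exclude = "hwi.l")`, whose best δ collapses
below 0.5). Within-morph allometric slopes are small (weak static
allometry), the morphs overlap in isosize yet differ on average
(size ANOVA), and the ANCOVA offset at common size excludes zero — so the
shape difference is not explained by allometric scaling.

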