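# kdrmonitor

Tools for monitoring pyrethroid resistance in the soybean aphid, *Aphis
glycines*, through voltage-gated sodium channel (vgsc) markers. Pyrethroid
resistance in this pest tracks two amino-acid substitutions in the vgsc-h1
heterodimer — L1014F (*kdr*; CTT→TTT, a C→T transition at transcript position
3070) and M918I (*super-kdr* in combination with 1014F; ATG→ATA, G→A at 2784).
The package is written for resistance-monitoring analysts: it reimplements, as
tested code over plain-text inputs, the full chain from sequences to
management-relevant statistics.

What it does:

- **In-silico genotyping.** Simulates the BstEII PCR-RFLP assay for L1014F
  (bands {154, 285} → L/L, {439} → F/F, {154, 285, 439} → L/F on the 439 bp
  amplicon) and the ligase-chain-reaction (LCR) assay for M918I (141 bp
  wild-type / 165 bp mutant products) on IUPAC consensus sequences, plus
  direct codon calling; `genotype_sample()` cross-checks all three routes.
- **Two-locus genotype classes.** The nine diploid classes `L/L:M/M` …
  `F/F:I/I` are labelled wild type, kdr het/hom, super-kdr het/hom, or
  918-only.
- **Association and trend statistics.** Resistant allele frequency
  RAF = 100·(2·hom_mut + het)/(2n); exact two-sided 2×k tests by full
  enumeration; allele-count odds ratios with Wald CIs; a binomial logit GLM
  (`time * location`) whose equal-weight marginal contrast pools per-location
  odds ratios (the geometric mean of raw ORs, with model-based CIs).
- **Dose-response phenotyping.** Three-parameter log-logistic mortality
  p(x) = d / (1 + (x/e)^(−b)) fitted by binomial maximum likelihood: LC50
  with delta-method CI, Pearson lack-of-fit, resistance/synergist ratios with
  the CI-non-overlap significance rule.
- **Synthetic data.** A deterministic reference transcript with working assay
  geometry, cohorts drawn from four-haplotype frequencies, consensus-sequence
  rendering, genotype-dependent selection, and LL.3 bioassay tables — every
  pipeline input, with ground truth.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, each a thin
script over the package functions, writing tables to `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic reference, cohort, bioassays
Rscript analysis/02_genotype.R      # three-route genotyping vs ground truth
Rscript analysis/03_dose_response.R # LL.3 fits, LC50s, resistance ratio
Rscript analysis/04_association.R   # glass-vial exact association tests
Rscript analysis/05_raf_trend.R     # pre/post RAF and pooled odds ratios
```

Stage 3 output (simulated susceptible and resistant populations generated at
LC50 0.38 and 18.33 µg ml⁻¹):

```
   population   n   lc50  ci_lo  ci_hi slope slope_se  chi2 df     d d_fixed    rr
1   resistant 480 19.469 16.701 22.238  2.26     0.23 13.95  6 1.000    TRUE 50.05
2 susceptible 480  0.389  0.340  0.439  4.20     0.96  1.14  5 0.964   FALSE  1.00
resistance ratio 50.0 (generating truth 48.2), significant by CI non-overlap
```

Each row is one fitted dose-mortality curve: `lc50` with its 95% interval,
the positive slope at the LC50, Pearson lack-of-fit `chi2` on `df` degrees of
freedom, the fitted upper mortality limit `d` (flagged when driven to 1), and
the resistance ratio against the susceptible reference.

Stage 5 output, computed from the packaged pre/post field genotype counts:

```
  year locus odds_ratio or_lo or_hi      p_value
1 2019  1014       1.73  1.36  2.21 1.007523e-05
2 2019   918       2.15  1.44  3.20 1.850731e-04
3 2020  1014       1.56  1.08  2.25 1.744004e-02
4 2020   918       3.63  2.09  6.30 4.850737e-06
```

These are the pooled post-vs-pre odds of carrying the resistant allele: after
a field application of lambda-cyhalothrin, the 1014F allele was 1.73× (2019)
and 1.56× (2020) more likely among sampled aphids, and the 918I allele 2.15×
and 3.63× — evidence of strong in-field selection on both loci, strongest on
the super-kdr-associated 918I.

The same numbers are available programmatically:

```r
library(kdrmonitor)
out <- run_experiment()           # both experiments from the packaged counts
out$trend$pooled                  # pooled RAFs, odds ratios, CIs, p-values
out$trend$by_location             # per-location RAF pre/post and raw ORs
out$association$association      # exact 2xk genotype-phenotype tests
```

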