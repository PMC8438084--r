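# tfgwas

Detects trait-associated transcription factors (TFs) from GWAS summary
statistics and ChIP-seq peak annotations, and carries the hits through a
TF-restricted transcriptome-wide association study (TWAS) and CRISPR-screen
essentiality follow-up. Everything runs on tabular inputs (tibbles in,
tibbles out) and ships with a synthetic-data generator so the full pipeline
is testable offline.

## The model

For variant *j* in LD block *i*, the per-variant 1-df GWAS chi-square
*Y*<sub>ij</sub> = (β̂/se)² is modelled against binding annotations with an
LD-block random intercept:

> *Y*<sub>ij</sub> = β₀ + β₁ TF<sub>ij</sub> + *V*<sub>i</sub> + ε<sub>ij</sub>,  *V*<sub>i</sub> ~ N(0, σ²_b),  ε<sub>ij</sub> ~ N(0, σ²_e)

where TF<sub>ij</sub> ∈ {0,1} marks occupancy of the variant by the TF's
ChIP-seq peaks and blocks are non-overlapping 100 kb windows. The slope β₁
is the mean chi-square difference Δχ̄² between bound and unbound variants;
a Wald z-test against a Bonferroni threshold (α/m) calls risk-associated
TFs. Extensions of the same model give pairwise co-occupancy interactions
(β₃ of TF1 × TF2), TF-score trends (0 / 1–5 / 6–max categories), and
chromatin-state contrasts against the quiescent state. Estimation is REML
with the variance ratio profiled out block-wise, so fitting is linear in
the number of variants.

Robustness uses a **deflated genome**: a seeded subsample with an
approximately uniform p-value distribution, removing preferentially
small-p variants, on which surviving enrichment cannot be driven by
genome-wide-significant loci alone.

Downstream, per-gene elastic-net models (mixing 0.5, 10-fold CV) trained
only on TF-occupied variants with GWAS p < 0.01 within ±1 Mb of the TSS
feed the summary-level association

> *Z*<sub>g</sub> ≈ Σ<sub>l∈Model_g</sub> w<sub>lg</sub> (σ̂<sub>l</sub>/σ̂<sub>g</sub>) (β̂<sub>l</sub>/se(β̂<sub>l</sub>)),

with gene-level significance requiring CV R² > 0.01 in two of three
expression datasets and min p < 1e-5. Essentiality follow-up tests the
count of negative gene-effect (CERES-style) scores across cell lines with
a one-sided binomial test and flags genes with median score < −0.5.

## Worked example

```r
library(tfgwas)

study <- simulate_study("smoke", seed = 3, lambda = 1)  # 500 blocks x 20 variants, 5 TFs
fit <- test_single_tf(study$variants, study$annotation, "tf1")
fit
#> LD-block random-intercept model: 10000 variants in 500 blocks
#> var_block = 0.08848, var_resid = 2.286
#>          term estimate std_error statistic   p_value low_support
#> 1 (Intercept)    1.037   0.02045     50.70 0.000e+00       FALSE
#> 2         tf1    1.053   0.06992     15.06 2.991e-51       FALSE
```

The planted enrichment shifts bound z-scores by λ = 1, so the true mean
chi-square excess is λ² = 1; the fit recovers Δχ̄² = 1.053 (SE 0.070), and
σ²_b = 0.088 absorbs the within-block correlation (ρ = 0.2 on the z scale).
The p-value 3e-51 is far below the 113-test Bonferroni threshold
`bonferroni_threshold(0.05, 113)` = 4.4e-4.

```r
defl <- build_deflated_genome(study$variants, seed = 3)
defl
#> Deflated genome: kept 9610 of 10000 variants (96.1%), mode=per_block, seed=3
#> KS uniformity of kept p-values: D=0.0057, p=0.91
tidy(test_single_tf(study$variants[defl$keep, ],
                    study$annotation[defl$keep, , drop = FALSE], "tf1"))
#>   term        estimate std_error statistic  p_value
#> 2 tf1            0.944    0.0678      13.9 4.14e-44
```

The kept p-values are indistinguishable from uniform (KS p = 0.91) and the
enrichment survives, attenuated — the conservativeness the subsample is
designed to provide. `autoplot(defl, study$variants)` draws the QQ plot of
the whole vs deflated genome; `tidy()`/`glance()` work on every fit and
`autoplot(fit)` draws the coefficient intervals.

## Command line

A thin Rscript front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","tfgwas.R",package="tfgwas"))')" \
    simulate --profile smoke --seed 5 --out sim/
# then: annotate, fit, deflate, interact, score, chromatin,
#       twas-train, twas-assoc, essentiality
```

All outputs are plain text and byte-identical under a repeated seed.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the main pipeline against the installed package — simulated study,
all-TF scan, deflation and re-scan, score trend, chromatin contrasts,
elastic-net training, summary-level association on a simulated cohort, and
the essentiality screen — and writes its JSON report to `--out`.
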