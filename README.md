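# hetrad

Intratumoral habitat radiomics for paired recurrent and non-recurrent
tumor subregions.

## The problem

After curative radiotherapy, local recurrences often arise *inside* the
irradiated tumor volume, suggesting radio-resistant subregions that
existed before treatment. `hetrad` implements the paired analysis that
probes this: partition each subject's pre-treatment gross tumor volume
(GTV) into the **recurrent habitat** (the recurrence volume GTVr mapped
back onto the pre-treatment image) and the **non-recurrent habitat**
(GTV − GTVr), quantify both with 47 radiomic features, and test which
features differ systematically between habitats across subjects.

It is aimed at radiation-oncology imaging researchers who want a tested,
reproducible reference implementation of this workflow — including a
synthetic MRI-like phantom generator, so the whole pipeline is exercisable
without patient data.

## The method

Per habitat, 47 features:

| family | count | computed on |
|---|---|---|
| intensity histogram (mean, variance, skewness, kurtosis, MAD, hyperskewness, hyperflatness) | 7 | raw intensities |
| GLCM (energy, contrast, entropy, homogeneity, correlation, sum average, variance, dissimilarity, autocorrelation) | 9 | Lloyd–Max levels |
| GLRLM (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV) | 13 | Lloyd–Max levels |
| GLSZM (SZE, LZE, GLN, ZSN, ZP, LGZE, HGZE, SZLGE, SZHGE, LZLGE, LZHGE, GLV, ZSV) | 13 | Lloyd–Max levels |
| NGTDM (coarseness, contrast, busyness, complexity, strength) | 5 | Lloyd–Max levels |

Texture matrices use all 13 unique 3D directions at Chebyshev distance 1
(26-connectivity for zones and neighborhoods). Gray levels come from a
Lloyd–Max quantizer (`Ng = 256` by default) fit per habitat — the
MSE-optimal scalar quantizer, alternating conditional-mean and midpoint
updates.

The statistical stage works on paired differences
`d_f(k) = f(rec, k) − f(nonrec, k)`: Shapiro–Wilk at 0.05 branches each
feature to a paired t-test or a Wilcoxon signed-rank test; significance is
Bonferroni-corrected (`0.05/47`, displayed as 0.001); significant features
feed a Pearson correlation matrix of differences and a PCA of the pooled
z-scored region vectors (2n rows).

## Worked example

```r
library(hetrad)

run <- run_pipeline(
  list(phantom = list(n_subjects = 14), seed = 7),
  out_dir = "hetrad_out"
)
print(run)
```

```
<hetrad_run> 14 subjects (0 excluded), 28 feature rows
<habitat_study> n = 14 subjects, 47 features tested, 35 significant at p < 0.00106
  significant: Intensity_Mean, Intensity_Kurtosis, ..., NGTDM_Busyness, NGTDM_Coarseness, NGTDM_Strength
```

The phantom's recurrent habitat has a coarser texture (longer spatial
correlation) and a +60 intensity shift, so at n = 14 most texture families
separate decisively. The per-feature table and the cohort summary follow
broom conventions:

```r
glance(run$study)
#>   n_subjects n_features n_significant threshold threshold_display pc1_variance_fraction ...
#> 1         14         47            35   0.00106             0.001                 0.803

tidy(run$study) |> dplyr::filter(feature == "NGTDM_Busyness")
#>   feature        n shapiro_p test_used mean_diff  sd_diff  p_value significant
#> 1 NGTDM_Busyness 14     0.911  paired_t  -0.00755  0.00117 3.36e-12        TRUE
```

`mean_diff < 0` reads "busyness is lower in the recurrent habitat" —
coarse, patchy texture rather than fine-grained variation.
`autoplot(run$study, "pca")` plots the 28 region vectors on PC1/PC2;
`autoplot(run$study, "correlation")` draws the masked correlation heatmap.
All outputs (features, tests, correlations, PCA scores/variance, a run
report, per-subject verdicts) are also written as CSV/text into `out_dir`.

A thin command-line wrapper lives at `inst/scripts/hetrad.R`:

```sh
Rscript inst/scripts/hetrad.R run --phantom-default --n 14 --seed 7 --out out/
```

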