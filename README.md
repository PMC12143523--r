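# GeoAssign

Continuous spatial-genetic assignment: predicting the geographic origin of
an individual from its SNP genotype when genetic variation is continuous
across the landscape rather than clustered into discrete populations.

Forest trees are the motivating case: range-wide collections of
georeferenced individuals (provenance trials, timber-tracking reference
sets) show isolation by distance — allele frequencies drift smoothly with
latitude and longitude — so the origin of a sample is better treated as a
regression target than as a class label. Comparing the *declared* origin of
a sample with its *genetically predicted* origin then exposes mislabelled
accessions and historical long-distance seed transfer.

## Methods

Five continuous assigners share one interface (`Assigner` classes,
`assignOrigin`, `looCrossval`):

| Method | Idea | Uncertainty |
|---|---|---|
| `nnAssigner()` | mean coordinates of the k = 5 genetically most similar reference individuals (mean absolute allele difference) | pairwise distances among the k neighbours, r95 = m + 1.96 s |
| `gblupAssigner()` | gBLUP: latitude and longitude as quantitative traits, y = μ + g + e with g ~ N(0, σ²g K), VanRaden kinship, REML variance components | prediction error variance from the mixed model |
| `gprDirectAssigner()` | exact GP regression of each coordinate on the genotype vector, RBF kernel σ²exp(−‖xi−xj‖²/2l²), hyperparameters by random search over [0.001, 400] × [1e−4, 1] scored on five 90/10 splits | GP posterior sd |
| `gprGridAssigner()` | per-SNP allele-frequency surfaces over a fixed geographic grid (Matérn ν = 2.5, 10 Adam steps on the marginal likelihood), then maximum-likelihood cell assignment under Hardy–Weinberg genotype probabilities | likelihood-weighted spread of cell centers |
| `dlAssigner()` | ensemble of five feedforward networks (100-100-100-50-50, ReLU + dropout, L1/L2 1e−6, early stopping on RMSE) | pairwise distances among member predictions |

Around them: coded-table and VCF genotype input, the <5% missingness
filter, mean imputation, Bonferroni clinal-SNP selection, leave-one-out
cross-validation with Haversine-distance summaries and relative errors
(distance / maximum pairwise distance), and two-tier outlier detection
(individuals: Q3 + 3·IQR; groups: Q3 + 1.5·IQR; both additionally gated by
the method's 95% distance radius). A simulator of clinal SNP landscapes
with injected translocations provides the test bed. See the methods
vignette (`vignettes/continuous-assignment-methods.Rmd`) for the models,
parameter meanings and design choices.

## Worked example

```r
library(GeoAssign)

# a 10-site, 60-individual landscape with 80 clinal SNPs, one individual
# recorded 800+ km from its genetic origin
sim <- simulateLandscape(simConfig(n_sites = 10, n_per_site = 6,
                                   n_snps = 80, seed = 42))
tr  <- injectTranslocations(sim$samples, sim$truth,
                            n_individuals = 1, n_groups = 0,
                            min_km = 800, seed = 1)

preds  <- looCrossval(nnAssigner(), sim$geno, tr$samples, seed = 1)
report <- summarizeEval(preds, tr$samples)
report$summary
#>   method  n  mean_km median_km    sd_km     r_lat     r_lon    r_mean
#> 1     NN 60 143.6075  92.52248 170.7445 0.9822848 0.8984398 0.9403623
#>   max_pairwise_km median_relative_error
#> 1        1514.935            0.06107356

detectIndividualOutliers(report)
#>   sample_id group_id distance_km threshold   r95_km
#> 1     s0057     g010    1188.233  550.9075 415.3237
```

Reading: the leave-one-out median error is 93 km, 6.1% of the 1515 km
maximum pairwise distance among the samples; the correlation between
given and predicted coordinates is 0.98 (latitude) and 0.90 (longitude).
The injected translocation (`s0057`) is the one individual whose distance
between declared and predicted origin (1188 km) exceeds both the IQR
threshold over all distances (551 km) and its own 95% radius (415 km).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/geoassign.R simulate --out simdata --seed 42
Rscript inst/cli/geoassign.R crossval --genotypes simdata/genotypes.tsv \
    --samples simdata/samples.tsv --markers simdata/markers.tsv \
    --method nn,gp --out cv --seed 1
Rscript inst/cli/geoassign.R outliers --per-sample cv/nn_per_sample.tsv --out outl
```

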