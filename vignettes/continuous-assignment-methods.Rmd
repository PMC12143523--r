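---
title: "Continuous spatial-genetic assignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous spatial-genetic assignment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Many tree species (and other widespread organisms) show *continuous* genetic
variation across their range: allele frequencies change gradually with
geography because gene flow is distance-limited (isolation by distance).
Discrete assignment — classifying a sample into one of a set of predefined
populations — is then poorly posed, because the populations are an artefact
of the sampling design. Continuous assignment instead treats latitude and
longitude as quantities to be *predicted* from a genotype. GeoAssign
implements five such predictors behind one interface, a leave-one-out
evaluation protocol, and a two-tier outlier screen that flags individuals
and whole provenances whose declared (passport) origin is incompatible with
their genotype — the signature of mislabelling or historical seed transfer.

## Data model

Genotypes are biallelic SNPs coded on the unit interval: 1 = homozygote for
the reference allele, 0.5 = heterozygote, 0 = homozygote for the
alternative allele (`GenoMatrix`). Plastid (chloroplast or mitochondrial)
markers behave as haploid and are stored as 0/1 pseudo-homozygotes. A
second, affinely equivalent coding 1/0/−1 (`recodeGeno(..., "signed")`) is
used by the kinship- and kernel-based methods. Pre-processing follows a
fixed recipe: markers and then samples with ≥ 5% missing calls are dropped
(`filterMissingness`); the remaining missing calls are either kept as `NA`
(nearest neighbour, gBLUP) or replaced by the marker mean (`imputeMean`;
Gaussian-process and network methods); and for the latter group only SNPs
with a Bonferroni-significant Pearson correlation with latitude or
longitude are retained (`selectClinalSnps`, threshold α/(2p) because each
marker is tested against both axes — the two codings give identical
p-values, so the choice between them is immaterial here).

# The five methods

**Nearest neighbour (NN).** The genetic distance between two individuals is
the mean absolute difference of their unit-coded values over shared
non-missing loci. A test sample is placed at the arithmetic mean of the
coordinates of its k = 5 genetically closest reference individuals (k = 5
is the cross-validated optimum of the approach; ties at rank k keep
training order for determinism). Averaging raw degrees is a deliberate
simplification — adequate at continental scale, wrong near the
antimeridian, and documented as such. By construction the prediction can
never leave the bounding box of the reference coordinates.

**Genomic prediction (GP / gBLUP).** Latitude and longitude are treated as
two independent quantitative traits in the mixed model y = μ + g + e with
g ~ N(0, σ²g K). K is the VanRaden genomic relationship matrix (centred
signed genotypes, normalised by Σ 2pq; missing entries load zero after
centring). Variance components are estimated by REML, profiling the
restricted likelihood over the ratio δ = σ²e/σ²g after a single spectral
decomposition of the training block, with a log-grid fallback if the 1-D
optimisation fails. Predictions for held-out individuals use the
train–test kinship blocks; the prediction error variance (PEV) includes
the uncertainty of the estimated intercept. In the leave-one-out loop K is
computed once on all individuals and the held-out coordinates are set to
missing, mirroring the "set to NA" protocol of the kin.blup-style
analysis.

**Direct GPR (GPR-D).** Exact Gaussian-process regression of each
coordinate on the imputed signed genotype vector, with RBF kernel
k(xi, xj) = σ² exp(−‖xi−xj‖²/(2l²)). Targets are standardised internally
and back-transformed; on that scale σ² is confounded with the target
variance and is fixed at 1, so only the lengthscale and observation noise
are free. They are tuned by pure random search: configurations
(lengthscale_lat, noise_lat, lengthscale_lon, noise_lon) are drawn
uniformly from [0.001, 400] × [1e−4, 1], and each is scored by the mean
Haversine error over five 90/10 train/test splits. The same five splits
(fixed by the seed) are reused for every configuration — common random
numbers reduce selection noise; the method itself does not prescribe a
split-sharing rule, so this is a package choice. The reference
configuration count is 10,000; desk-scale runs in the tests use 20–100,
which on the simulated landscapes already finds lengthscales within the
informative range.

**Grid-based GPR (GPR-G).** The study area is divided into a fixed lattice
whose edges span exactly the min–max training coordinates, with square
cells of a configurable edge length (20 km and 50 km are the presets used
at sub-continental and continental scale; cells are converted to degrees
via 111.32 km/degree and cos(mean latitude) for longitude — the method
mixes a km cell size with a degree-spanned grid, and this is the simplest
consistent reading, exposed as configuration). Reference-allele
frequencies are aggregated per occupied cell, and one exact GP per SNP —
Matérn ν = 5/2 kernel k(r) = σ²(1 + √5r/l + 5r²/(3l²))e^{−√5r/l} on cell
centers, learned constant mean — is fitted by exactly 10 Adam steps (lr
0.1) on the marginal log-likelihood from deterministic data-derived
starting values; hyperparameters are not otherwise tuned. Frequencies are
modelled on the raw [0,1] scale and the posterior means are clamped to
[1e−4, 1−1e−4] rather than logit-transformed, matching the plain
aggregation the method describes. A test genotype is scored against every
cell under Hardy–Weinberg equilibrium (p², 2pq, q²; haploid p/q for
plastid markers) and assigned to the maximum-likelihood cell. Per-cell
sample sizes are not used as heteroscedastic noise — a possible extension,
not implemented.

**Deep learning (DL).** A feedforward network with hidden layers
100-100-100-50-50 (ReLU), dropout 0.1 on the input and 0.3/0.3/0.3/0.2/0.2
on the hidden layers, and L1 = L2 = 1e−6, trained on imputed signed
genotypes with both standardised coordinates as a two-output shared trunk
(the per-coordinate alternative exists in the configuration). Training
runs up to 500 epochs with early stopping when the RMSE monitored on a 10%
member-specific validation split fails to improve by 0.001 for ten
consecutive rounds. Five networks differing only in derived member seeds
form the ensemble; the prediction is the member mean. Optimiser details
are framework-level defaults that the original description leaves hidden;
here they are explicit: Adam, mini-batches of 32, learning rate 0.01. The
learning rate is the one genuinely open choice — at substantially smaller
rates the early-stopping tolerance of 0.001 fires while the monitored RMSE
is still on its way down, leaving the network underfit, so the default is
the largest rate at which training is stable on standardised targets.

## Uncertainty: the 95% distance radius

Every method reports `r95_km`, an upper 95% radius used as a gate in
outlier detection. GPR-D and gBLUP derive it from their model-based
per-coordinate standard deviations: r95 = 1.96·√(sd²lat·111.32² +
sd²lon·(111.32·cos φ)²). NN and DL use the pairwise Haversine distances
among, respectively, the five nearest neighbours and the five member
predictions: r95 = m + 1.96·s from their mean and standard deviation (the
source states only that a 95% upper limit was derived from these spreads;
the mean-plus-1.96-sd reading is implemented as the default policy, with
pure 1.96·s available as an alternative). GPR-G converts its
log-likelihood surface into cell weights w ∝ exp(ll − max ll) and uses the
likelihood-weighted spatial standard deviation of cell centers — the
method's own uncertainty is not specified anywhere, so this policy is a
documented package choice.

## Evaluation and outliers

`looCrossval` predicts every individual from a model trained without it.
Accuracy summaries report Haversine distances (mean/median/sd), Pearson
correlations between given and predicted latitude and longitude, and
relative errors — distance divided by the maximum pairwise distance among
the samples, which makes studies on different spatial scales comparable.
Correlations on a coordinate with zero variance are reported as missing,
never as zero. Failed folds are excluded and counted.

Outlier detection is two-tier. Individuals: flagged when their distance
exceeds Q3 + 3·IQR of all distances *and* their own r95. Groups: member
predictions and member r95 values are averaged; a group is flagged when
the distance between its mean predicted and mean given location exceeds
Q3 + 1.5·IQR of the group distances *and* the mean r95. Quartiles use
linear interpolation (R type 7) — the convention matters at small n and is
therefore pinned down here. The IQR rule is applied to raw km distances by
default; a `relative = TRUE` switch applies it to relative errors instead,
because the original phrasing ("quotient distribution") is ambiguous about
which was used.

# The synthetic landscape

Real reference datasets are not shipped; the simulator provides the test
bed. It emulates a provenance-style design: `n_sites` sampling locations
on a jittered grid inside a European-scale window (default latitude 44–54,
longitude 4–24 — about 1100 × 1500 km), `n_per_site` individuals each
(default 10, within the 6–10 range typical of provenance collections;
default 40 sites give 400 individuals), and `n_snps` biallelic markers
(default 300). Per SNP the allele-frequency surface is
logistic(a + b·zlat + c·zlon + f), with intercepts U(−1.5, 1.5), slopes
N(0, cline_strength²) on standardised site coordinates and f a smooth
Matérn-5/2 random field (sd `surface_roughness`, lengthscale 0.75 in
standardised units). The defaults cline_strength = 1.5 and
surface_roughness = 0.5 give individual SNPs strong geographic signal —
isolation by distance of the kind seen in range-wide tree collections,
which is the regime the methods are designed for. Genotypes are drawn under HWE (Binomial(2, p)/2; Bernoulli for
plastid markers), and calls go missing independently at 2% (safely under
the 5% filter). Translocations move only the *recorded* coordinates of
individuals or whole sites to another existing site at least `min_km`
away; genotypes keep their true-origin structure, which is exactly what a
mislabelled accession looks like.

What the simulator does *not* emulate: linkage disequilibrium between
markers, coalescent genealogies, drift-driven discontinuities (refugial
lineages), selection, introgression, and spatially varying sampling
density. Passing tests therefore show that the methods recover smooth
frequency surfaces from HWE genotypes — they do not certify performance on
data whose structure is dominated by those processes.

# Numerical choices and degenerate inputs

* Great-circle distances use a sphere of radius 6371.0 km.
* Cholesky factorisations of kernel matrices retry with jitter 1e−6, then
  1e−4, then fail hard; the Matérn fits carry a permanent 1e−6 diagonal
  stabiliser; BLUP covariance solves fall back to a 1e−8 ridge.
* Grid cells are half-open [low, high) with the last cell per axis closed;
  a point on an interior edge belongs to the cell whose lower edge it is.
* Ties in the NN ranking and in the maximum-likelihood cell are broken by
  training order / lowest cell id, for determinism.
* Zero-variance markers are excluded from clinal selection (correlation
  undefined); fully missing columns are a hard error at imputation.
* All randomness flows from one integer seed per entry point; derived
  seeds stay inside the 32-bit range. The compiled network trainer uses
  its own Mersenne Twister stream, so ensembles are bit-reproducible.

# Problem sizes used by the test suite

The checks in `tests/testthat/` run at desk scale, chosen so the complete
suite finishes in well under half an hour on a single core: the full
five-method evaluation uses the default 400-individual landscape with the
random search reduced to 100 configurations and the network capped at 50
epochs; the two expensive methods are evaluated on random subsets of
leave-one-out folds (120 for GPR-G, 20 for DL — every evaluated fold is a
complete fit, so the subset is an unbiased sample of the per-individual
errors). The marker-count comparison (30 versus 300 SNPs) uses ten
84-individual replicate landscapes for the four analytic methods and
full-size 400-individual replicates (5-fold subsets) for the network —
below a few hundred training samples its optimisation-noise floor sits
above both marker counts and hides the effect that is clearly present at
the default scale. Outlier recovery uses twenty 144-individual replicates
(24 sites, 150 SNPs, 50-km cells; 2 of 24 sites and 5 further individuals
translocated, a contamination rate comparable to real provenance
collections). HWE calibration uses 50 individuals per site, where the
1-df chi-square test is size-calibrated, with the usual
minimum-expected-count-of-5 rule. `scripts/acceptance.R` re-runs the
pipeline on a 240-individual landscape with the same scalings.

# Known limitations

* Coordinate averaging (NN, DL ensemble, group means) is Euclidean in
  degrees; predictions that straddle the antimeridian would be wrong.
* GPR-G assigns to cell centers, so its error is bounded below by half a
  cell diagonal; its likelihood-weighted uncertainty ignores per-cell
  sample sizes.
* The random search does not model interactions between the latitude and
  longitude hyperparameters beyond the shared splits.
* REML assumes a single genetic variance component; hierarchical or
  multi-trait (bivariate) models are out of scope, as are sparse GP
  approximations and per-SNP relevance lengthscales.
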