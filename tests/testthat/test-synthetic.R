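# Landscape simulator: determinism, spatial structure, HWE sampling,
# translocation bookkeeping.

test_that("identical seeds reproduce the landscape exactly", {
  cfg <- simConfig(n_sites = 8, n_per_site = 5, n_snps = 40, seed = 80,
                   frac_plastid = 0.2)
  s1 <- simulateLandscape(cfg)
  s2 <- simulateLandscape(cfg)
  expect_identical(genotypes(s1$geno), genotypes(s2$geno))
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth$surface, s2$truth$surface)
  s3 <- simulateLandscape(simConfig(n_sites = 8, n_per_site = 5,
                                    n_snps = 40, seed = 81,
                                    frac_plastid = 0.2))
  expect_false(identical(genotypes(s1$geno), genotypes(s3$geno)))
})

test_that("counts, domains and coding domains are respected", {
  sim <- simulateLandscape(simConfig(n_sites = 7, n_per_site = c(6L, 10L),
                                     n_snps = 30, seed = 82,
                                     frac_plastid = 0.3, missing_rate = 0.04))
  v <- genotypes(sim$geno)
  expect_equal(length(unique(sim$samples$group_id)), 7L)
  perSite <- table(sim$samples$group_id)
  expect_true(all(perSite >= 6 & perSite <= 10))
  expect_true(all(v[!is.na(v)] %in% c(0, 0.5, 1)))
  pl <- markerPloidy(sim$geno) == "plastid"
  expect_equal(sum(pl), 9L)
  expect_false(any(v[, pl] == 0.5, na.rm = TRUE))   # plastid: no heterozygotes
  expect_lt(mean(is.na(v)), 0.06)
  expect_true(all(sim$samples$lat >= 44 & sim$samples$lat <= 54))
})

test_that("clines create genotype-coordinate correlation and spatial autocorrelation", {
  strong <- simulateLandscape(simConfig(n_sites = 15, n_per_site = 6,
                                        n_snps = 120, seed = 83,
                                        cline_strength = 1.5))
  flat <- simulateLandscape(simConfig(n_sites = 15, n_per_site = 6,
                                      n_snps = 120, seed = 83,
                                      cline_strength = 0,
                                      surface_roughness = 0))
  absCor <- function(sim) {
    v <- genotypes(sim$geno)
    median(abs(apply(v, 2, function(x)
      cor(x, sim$samples$lat, use = "complete.obs"))), na.rm = TRUE)
  }
  expect_gt(absCor(strong), 2 * absCor(flat))
  expect_gt(spatialAutocorrelation(strong$geno, strong$samples), 0.1)
  expect_lt(abs(spatialAutocorrelation(flat$geno, flat$samples)), 0.1)
})

test_that("without spatial structure NN does no better than guessing the centroid", {
  flat <- simulateLandscape(simConfig(n_sites = 12, n_per_site = 6,
                                      n_snps = 100, seed = 84,
                                      cline_strength = 0,
                                      surface_roughness = 0))
  preds <- looCrossval(nnAssigner(), flat$geno, flat$samples, seed = 1)
  rep <- summarizeEval(preds, flat$samples)
  s <- flat$samples
  centroidErr <- median(haversineKm(s$lat, s$lon, mean(s$lat), mean(s$lon)))
  expect_gt(rep$summary$median_km, centroidErr * 0.9)
})

test_that("simulated genotypes are HWE-consistent at the true frequencies", {
  sim <- simulateLandscape(simConfig(n_sites = 10, n_per_site = 10,
                                     n_snps = 200, seed = 85,
                                     frac_plastid = 0.1))
  chk <- hweConsistencyCheck(sim$geno, sim$samples, sim$truth)
  expect_gte(chk$coverage, 0.9)
  # observed per-site heterozygosity tracks 2p(1-p) on average
  expect_lt(chk$mean_abs_dev, 0.15)
})

test_that("translocations move recorded coordinates only, respecting min_km", {
  sim <- simulateLandscape(simConfig(n_sites = 12, n_per_site = 6,
                                     n_snps = 20, seed = 87))
  tr <- injectTranslocations(sim$samples, sim$truth, n_individuals = 3L,
                             n_groups = 2L, min_km = 600, seed = 2)
  rec <- tr$truth$translocations
  expect_equal(sum(rec$scope == "individual"), 3L)
  expect_equal(sum(rec$scope == "group"), 2L)
  moved <- rec[rec$scope != "group", ]
  d <- haversineKm(moved$true_lat, moved$true_lon,
                   moved$recorded_lat, moved$recorded_lon)
  expect_true(all(d >= 600))
  # recorded coordinates changed in the sample table; ids disjoint
  ind <- rec$id[rec$scope == "individual"]
  grpMembers <- rec$id[rec$scope == "group_member"]
  expect_length(intersect(ind, grpMembers), 0L)
  for (id in ind) {
    i <- match(id, tr$samples$sample_id)
    expect_equal(tr$samples$lat[i], rec$recorded_lat[match(id, rec$id)])
  }
  # no-op call leaves the table untouched
  tr0 <- injectTranslocations(sim$samples, sim$truth, 0L, 0L, 600, seed = 2)
  expect_identical(tr0$samples, sim$samples)
  expect_error(injectTranslocations(sim$samples, sim$truth, 1L, 0L,
                                    min_km = 99999, seed = 2), "no site")
})
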