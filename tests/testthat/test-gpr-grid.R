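# Grid-based GPR: cell frequencies, Matern surfaces, HWE likelihood,
# maximum-likelihood cell assignment.

make_grid_fixture <- function(seed = 40, n_sites = 9, n_per_site = 6,
                              n_snps = 25, cellKm = 150, ...) {
  sim <- small_landscape(seed = seed, n_sites = n_sites,
                         n_per_site = n_per_site, n_snps = n_snps, ...)
  grid <- buildGrid(sim$samples, cellKm)
  enc <- recodeGeno(sim$geno, "unit")
  cf <- aggregateCellFrequencies(enc, sim$samples, grid)
  list(sim = sim, grid = grid, enc = enc, cf = cf)
}

test_that("cell frequencies are the mean unit value of informative calls", {
  v <- matrix(c(1, 0.5, 0,
                1, NA, 1,
                1, 1, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("m1", "m2", "m3")))
  s <- data.frame(sample_id = c("a", "b", "c"), group_id = "g",
                  lat = c(45, 45, 52), lon = c(8, 8, 16))
  grid <- buildGrid(s, 400)
  cf <- aggregateCellFrequencies(recodeGeno(GenoMatrix(v), "unit"), s, grid)
  cellAB <- cellMembership(grid)[["a"]]
  cellC <- cellMembership(grid)[["c"]]
  expect_equal(cf$freq[cellAB, "m1"], 1)        # mean of {1, 1}
  expect_equal(cf$n_obs[cellAB, "m2"], 1)
  expect_equal(cf$freq[cellAB, "m2"], 0.5)      # single informative call
  expect_equal(cf$freq[cellAB, "m3"], 0.5)      # mean of {0, 1}
  expect_equal(cf$freq[cellC, "m3"], 1)
})

test_that("all-missing cell-SNP combinations are absent (NA)", {
  v <- matrix(c(1, 0, NA, 1), 2, 2,
              dimnames = list(c("a", "b"), c("m1", "m2")))
  s <- data.frame(sample_id = c("a", "b"), group_id = "g",
                  lat = c(45, 52), lon = c(8, 16))
  grid <- buildGrid(s, 400)
  cf <- aggregateCellFrequencies(recodeGeno(GenoMatrix(v), "unit"), s, grid)
  expect_true(is.na(cf$freq[cellMembership(grid)[["a"]], "m2"]))
})

test_that("surface fits are deterministic, flat for constant data, monotone in likelihood", {
  fx <- make_grid_fixture(seed = 41)
  cf <- fx$cf
  cf$freq[, 1] <- 0.62                      # constant observed frequencies
  cf$freq[, 3] <- cf$freq[, 2]              # duplicated SNP
  model <- fitSnpSurfaces(cf, epochs = 10L)
  out <- predictFrequencies(model)
  expect_equal(unname(out$freq[, 1]), rep(0.62, nrow(out$freq)),
               tolerance = 1e-3)
  expect_equal(out$freq[, 2], out$freq[, 3], ignore_attr = TRUE)
  out2 <- predictFrequencies(fitSnpSurfaces(cf, epochs = 10L))
  expect_identical(out$freq, out2$freq)

  # Adam ascent on the marginal likelihood: mostly non-decreasing steps
  # (plain Adam oscillates slightly around the optimum) and a net gain
  tr <- out$ll_trace
  steps <- diff(tr[, 2])
  expect_gte(mean(steps > -1e-6), 0.6)
  expect_gt(tr[nrow(tr), 2], tr[1, 2])      # net improvement
})

test_that("predicted surfaces interpolate occupied cells on smooth fields", {
  fx <- make_grid_fixture(seed = 42, n_snps = 20, n_per_site = 10,
                          surface_roughness = 0, missing_rate = 0)
  model <- fitSnpSurfaces(fx$cf, epochs = 10L)
  out <- predictFrequencies(model)
  occ <- fx$cf$cells
  err <- abs(out$freq[occ, ] - fx$cf$freq[occ, ])
  expect_lt(median(err), 0.05)
  expect_true(all(out$freq >= 1e-4 & out$freq <= 1 - 1e-4))
  expect_equal(dim(out$freq), c(nrow(gridCells(fx$grid)), 20L))
})

test_that("HWE log-likelihood matches hand computations and sums to one", {
  expect_equal(hweLogLik(0.5, 0.5), log(0.5))
  expect_equal(hweLogLik(c(1, 0.5), c(0.8, 0.3)),
               log(0.64) + log(0.42), tolerance = 1e-12)
  expect_equal(hweLogLik(c(1, 0.5), c(0.8, 0.3)), -1.3137, tolerance = 1e-4)
  expect_equal(hweLogLik(0, 1e-4), 2 * log(1 - 1e-4))  # ~0 contribution
  expect_equal(hweLogLik(c(1, NA), c(0.5, 0.9)), 2 * log(0.5))
  # plastid: haploid probabilities
  expect_equal(hweLogLik(c(1, 0), c(0.7, 0.7), rep("plastid", 2)),
               log(0.7) + log(0.3))
  # genotype probabilities sum to 1 at any p
  for (p in c(0.01, 0.3, 0.77)) {
    probs <- exp(c(hweLogLik(0, p), hweLogLik(0.5, p), hweLogLik(1, p)))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    expect_equal(exp(hweLogLik(0, p, "plastid")) +
                   exp(hweLogLik(1, p, "plastid")), 1, tolerance = 1e-12)
  }
})

test_that("vectorised cell scoring equals the exhaustive oracle (3x3 grid, 5 SNPs)", {
  set.seed(43)
  freq <- matrix(runif(45, 0.05, 0.95), 9, 5,
                 dimnames = list(sprintf("c%03d_%03d",
                                         rep(1:3, 3), rep(1:3, each = 3)),
                                 sprintf("m%d", 1:5)))
  ploidy <- c("nuclear", "nuclear", "plastid", "nuclear", "plastid")
  for (rep in 1:5) {
    g <- ifelse(ploidy == "plastid",
                sample(c(0, 1), 5, replace = TRUE),
                sample(c(0, 0.5, 1), 5, replace = TRUE))
    if (rep == 3) g[2] <- NA
    ours <- GeoAssign:::hweLogLikAllCells(freq, g, ploidy)
    oracle <- oracle_grid_argmax(freq, g, ploidy)
    expect_equal(unname(ours), unname(oracle$scores), tolerance = 1e-10)
    expect_equal(which.max(ours), oracle$idx)
  }
})

test_that("gridAssign picks the argmax cell and is shift-invariant", {
  fx <- make_grid_fixture(seed = 44, n_snps = 30)
  model <- fitSnpSurfaces(fx$cf, epochs = 10L)
  out <- predictFrequencies(model)
  g <- genotypes(fx$enc)[5, ]
  pred <- gridAssign(out$freq, fx$grid, g, fx$enc@ploidy,
                     sampleId = "x", keepSurface = TRUE)
  ll <- pred$extras[[1]]$loglik
  cells <- gridCells(fx$grid)
  best <- which.max(ll)
  expect_equal(pred$pred_lat, cells$center_lat[best])
  expect_equal(pred$pred_lon, cells$center_lon[best])
  expect_true(pred$r95_km >= 0)
  # invariance of the argmax/weights under a constant log-likelihood shift
  w1 <- exp(ll - max(ll)); w2 <- exp((ll + 123) - max(ll + 123))
  expect_equal(w1, w2)

  # degenerate single-cell grid
  s1 <- data.frame(sample_id = c("a", "b"), group_id = "g",
                   lat = c(47, 47.01), lon = c(9, 9.01))
  g1 <- buildGrid(s1, 500)
  f1 <- matrix(0.5, 1, 3, dimnames = list(gridCells(g1)$cell_id[1],
                                          c("m1", "m2", "m3")))
  p1 <- gridAssign(f1, g1, c(1, 0.5, 0))
  expect_equal(p1$r95_km, 0)
})

test_that("genotypes drawn from a cell's frequencies are assigned near that cell", {
  fx <- make_grid_fixture(seed = 45, n_sites = 12, n_per_site = 8,
                          n_snps = 200, cellKm = 150,
                          surface_roughness = 0, missing_rate = 0)
  model <- fitSnpSurfaces(fx$cf, epochs = 10L)
  out <- predictFrequencies(model)
  cells <- gridCells(fx$grid)
  occ <- fx$cf$cells
  set.seed(99)
  hits <- replicate(50, {
    cellA <- sample(occ, 1)
    p <- out$freq[cellA, ]
    g <- rbinom(length(p), 2, p) / 2
    pred <- gridAssign(out$freq, fx$grid, g)
    a <- cells[cells$cell_id == cellA, ]
    b <- cells[cells$cell_id == pred$extras[[1]]$cell_id, ]
    max(abs(a$lat_bin - b$lat_bin), abs(a$lon_bin - b$lon_bin)) <= 1
  })
  expect_gte(mean(hits), 0.9)
})
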