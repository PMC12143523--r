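# Kinship construction, REML variance components and BLUP prediction.

test_that("kinship matrix has the VanRaden structure", {
  g <- toy_geno(6, 30, seed = 3)
  v <- genotypes(g)
  v[2, ] <- v[1, ]                      # two identical individuals
  kin <- kinshipMatrix(recodeGeno(GenoMatrix(v), "signed"))
  K <- kin$K
  expect_equal(K, t(K))
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])

  # permutation equivariance
  perm <- c(3, 1, 6, 2, 5, 4)
  kinP <- kinshipMatrix(recodeGeno(GenoMatrix(v[perm, ]), "signed"))
  expect_equal(kinP$K, K[perm, perm], tolerance = 1e-12)

  mono <- GenoMatrix(matrix(1, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3])))
  expect_error(kinshipMatrix(recodeGeno(mono, "signed")), "monomorphic")
})

test_that("unstructured markers give near-zero mean off-diagonal kinship", {
  set.seed(14)
  v <- matrix(rbinom(200 * 500, 2, runif(200 * 500, 0.2, 0.8)) / 2, 200, 500,
              dimnames = list(sprintf("s%03d", 1:200), sprintf("m%03d", 1:500)))
  K <- kinshipMatrix(recodeGeno(GenoMatrix(v), "signed"))$K
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("REML recovers variance ratios and is scale-equivariant", {
  set.seed(15)
  n <- 300
  Z <- matrix(rnorm(n * 40), n, 40)
  K <- tcrossprod(Z) / 40                       # structured PSD kinship
  dimnames(K) <- list(sprintf("s%03d", 1:n), sprintf("s%03d", 1:n))
  L <- t(chol(K + diag(1e-8, n)))
  ratios <- replicate(20, {
    y <- drop(L %*% rnorm(n)) * 2 + rnorm(n)    # s2g = 4, s2e = 1
    vc <- remlVarianceComponents(K, y)
    vc$delta                                     # true delta = 0.25
  })
  expect_lt(abs(log(median(ratios) / 0.25)), log(2))

  y <- drop(L %*% rnorm(n)) * 2 + rnorm(n)
  vc1 <- remlVarianceComponents(K, y)
  vc2 <- remlVarianceComponents(K, 2 * y)
  expect_equal(sqrt(vc2$sigma2_g), 2 * sqrt(vc1$sigma2_g), tolerance = 1e-3)
  expect_equal(sqrt(vc2$sigma2_e), 2 * sqrt(vc1$sigma2_e), tolerance = 1e-3)

  vc0 <- remlVarianceComponents(K, rep(5, n))
  expect_equal(vc0$sigma2_g, 0)
  expect_equal(vc0$sigma2_e, 0)
})

test_that("BLUP solve equals the explicit GLS oracle on a 5-individual toy", {
  set.seed(16)
  g <- toy_geno(5, 40, seed = 16)
  K <- kinshipMatrix(recodeGeno(g, "signed"))$K
  y <- c(48.2, 49.1, NA, 50.3, 47.5)
  names(y) <- rownames(K)
  for (vc in list(c(1, 1), c(4, 0.5), c(0.2, 3))) {
    ours <- gblupSolve(K, y, vc[1], vc[2])
    oracle <- oracle_gblup(K, y, vc[1], vc[2])
    expect_equal(unname(ours$pred), unname(oracle$pred), tolerance = 1e-8)
    expect_equal(unname(ours$pev), unname(oracle$pev), tolerance = 1e-8)
    expect_equal(ours$mu, oracle$mu, tolerance = 1e-8)
  }
})

test_that("predictions from (K, lambda) and (2K, lambda/2) coincide", {
  set.seed(17)
  g <- toy_geno(8, 50, seed = 17)
  K <- kinshipMatrix(recodeGeno(g, "signed"))$K
  y <- c(rnorm(7, 48), NA)
  names(y) <- rownames(K)
  a <- gblupSolve(K, y, sigma2g = 1, sigma2e = 0.5)
  b <- gblupSolve(2 * K, y, sigma2g = 0.5, sigma2e = 0.5)
  expect_equal(a$pred, b$pred, tolerance = 1e-10)
})

test_that("total shrinkage returns the training mean; swapped targets swap predictions", {
  set.seed(18)
  g <- toy_geno(8, 50, seed = 18)
  K <- kinshipMatrix(recodeGeno(g, "signed"))$K
  y <- c(rnorm(7, 48), NA)
  names(y) <- rownames(K)
  s <- gblupSolve(K, y, sigma2g = 0, sigma2e = 1)
  expect_equal(unname(s$pred), mean(y[1:7]), tolerance = 1e-10)

  sim <- small_landscape(seed = 19, n_sites = 8, n_per_site = 5, n_snps = 60)
  kin <- kinshipMatrix(recodeGeno(sim$geno, "signed"))
  samples <- sim$samples
  pred1 <- gblupPredict(kin, samples[-1, ], samples$sample_id[1])
  swapped <- samples
  swapped$lat <- samples$lon
  swapped$lon <- samples$lat
  pred2 <- gblupPredict(kin, swapped[-1, ], samples$sample_id[1])
  expect_equal(pred1$pred_lat, pred2$pred_lon, tolerance = 1e-10)
  expect_equal(pred1$pred_lon, pred2$pred_lat, tolerance = 1e-10)
})

test_that("a test clone of a training individual is predicted at its location", {
  # near-noiseless clinal signal: coordinates are smooth functions of the
  # genotype, so a genotypic duplicate must land on its twin
  sim <- small_landscape(seed = 20, n_sites = 10, n_per_site = 6,
                         n_snps = 150, missing_rate = 0)
  v <- genotypes(sim$geno)
  v[1, ] <- v[25, ]                     # sample 1 becomes a clone of 25
  geno <- GenoMatrix(v, ploidy = sim$geno@ploidy)
  samples <- sim$samples
  samples$lat[1] <- samples$lat[25]
  samples$lon[1] <- samples$lon[25]
  K <- kinshipMatrix(recodeGeno(geno, "signed"))$K
  pred <- gblupPredict(K, samples[-1, ], samples$sample_id[1])
  expect_lt(abs(pred$pred_lat - samples$lat[25]), 0.5)
  expect_lt(abs(pred$pred_lon - samples$lon[25]), 0.8)
})

test_that("PEV decreases as the test individual's kinship to training grows", {
  base <- diag(5)
  dimnames(base) <- list(letters[1:5], letters[1:5])
  y <- c(1, 2, 3, 4, NA)
  pevAt <- function(kin) {
    K <- base
    K[5, 1:4] <- K[1:4, 5] <- kin
    gblupSolve(K, y, sigma2g = 1, sigma2e = 0.5)$pev
  }
  expect_gt(pevAt(rep(0, 4))[1], pevAt(rep(0.3, 4))[1])
  expect_gt(pevAt(rep(0.3, 4))[1], pevAt(rep(0.45, 4))[1])
})
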