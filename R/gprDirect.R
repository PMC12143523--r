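#' Radial basis function (squared-exponential) kernel
#'
#' K[i, j] = sigma2 * exp(-||x_i - x_j||^2 / (2 l^2)).
#'
#' @param X1,X2 numeric matrices with matching column count (no missing
#'   values).
#' @param sigma2 kernel variance (> 0).
#' @param l lengthscale (> 0), in genotype-space units.
#' @return nrow(X1) x nrow(X2) covariance matrix.
#' @export
rbfKernel <- function(X1, X2, sigma2 = 1, l = 1) {
  if (l <= 0 || sigma2 <= 0) stop("rbfKernel: sigma2 and l must be positive")
  sq <- sqDistMatrix(X1, X2)
  sigma2 * exp(-sq / (2 * l^2))
}

# pairwise squared Euclidean distances between rows.
sqDistMatrix <- function(X1, X2) {
  n1 <- rowSums(X1^2); n2 <- rowSums(X2^2)
  sq <- outer(n1, n2, "+") - 2 * tcrossprod(X1, X2)
  pmax(sq, 0)
}

# Cholesky with escalating jitter (1e-6 then 1e-4), per the numerical policy.
cholJitter <- function(A) {
  out <- tryCatch(chol(A), error = function(e) NULL)
  for (j in c(1e-6, 1e-4)) {
    if (!is.null(out)) return(out)
    out <- tryCatch(chol(A + diag(j, nrow(A))), error = function(e) NULL)
  }
  if (is.null(out)) stop("Cholesky failed even with jitter 1e-4")
  out
}

# Exact GP posterior given precomputed kernel blocks (unit signal variance
# assumed by the caller on standardised targets).
gprPosteriorCore <- function(Ktr, Kcross, kdiag, y, noise) {
  L <- cholJitter(Ktr + diag(noise, nrow(Ktr)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  mean <- drop(Kcross %*% alpha)
  v <- forwardsolve(t(L), t(Kcross))
  var <- pmax(kdiag - colSums(v^2), 0)
  list(mean = mean, sd = sqrt(var))
}

#' Exact GP regression of one coordinate on genotypes
#'
#' Fits a zero-mean GP with RBF kernel on internally standardised targets and
#' returns the back-transformed posterior mean and standard deviation at the
#' test genotypes. The signal variance is fixed at 1 on the standardised
#' scale (it is confounded with the target scale); only the lengthscale and
#' observation noise are free.
#'
#' @param Xtr,Xte imputed genotype matrices (training / test) in signed
#'   coding.
#' @param y training targets (one coordinate, degrees).
#' @param lengthscale RBF lengthscale.
#' @param noise observation-noise variance (standardised-target scale).
#' @return list with \code{mean} and \code{sd} (degrees) per test row.
#' @export
gprFitPredict <- function(Xtr, y, Xte, lengthscale, noise) {
  m <- mean(y); s <- stats::sd(y)
  if (!is.finite(s) || s < 1e-12) s <- 1
  ys <- (y - m) / s
  Ktr <- rbfKernel(Xtr, Xtr, 1, lengthscale)
  Kcr <- rbfKernel(Xte, Xtr, 1, lengthscale)
  post <- gprPosteriorCore(Ktr, Kcr, rep(1, nrow(Xte)), ys, noise)
  list(mean = m + s * post$mean, sd = s * post$sd)
}

#' Random-search tuning of the RBF hyperparameters
#'
#' Draws \code{nConfigs} configurations (lengthscale_lat, noise_lat,
#' lengthscale_lon, noise_lon) uniformly within the boxes, scores each by the
#' mean Haversine distance between predicted and actual locations over
#' \code{nRepeats} random 90/10 train/test splits (the same splits, fixed by
#' \code{seed}, are reused for every configuration), and returns the
#' configuration with the smallest mean error.
#'
#' @param X imputed signed genotype matrix.
#' @param samples aligned sample table.
#' @param nConfigs number of random configurations.
#' @param lengthscaleBox,noiseBox sampling ranges (defaults [0.001, 400] and
#'   [1e-4, 1]).
#' @param nRepeats number of random splits per configuration (default 5).
#' @param testFrac held-out fraction per split (default 0.1).
#' @param seed integer seed fixing draws and splits.
#' @return list with \code{best} (named hyperparameter list) and \code{log}
#'   (data.frame of all configurations with mean/sd split error).
#' @export
randomSearchHyperparams <- function(X, samples, nConfigs = 10000L,
                                    lengthscaleBox = c(0.001, 400),
                                    noiseBox = c(1e-4, 1),
                                    nRepeats = 5L, testFrac = 0.1, seed = 1L) {
  stopifnot(nConfigs >= 1L)
  n <- nrow(X)
  nTest <- max(1L, round(testFrac * n))
  cfgSplit <- withSeed(seed, {
    cfg <- data.frame(
      lengthscale_lat = stats::runif(nConfigs, lengthscaleBox[1], lengthscaleBox[2]),
      noise_lat = stats::runif(nConfigs, noiseBox[1], noiseBox[2]),
      lengthscale_lon = stats::runif(nConfigs, lengthscaleBox[1], lengthscaleBox[2]),
      noise_lon = stats::runif(nConfigs, noiseBox[1], noiseBox[2]))
    splits <- lapply(seq_len(nRepeats), function(i) sample(n, nTest))
    list(cfg = cfg, splits = splits)
  })
  cfg <- cfgSplit$cfg; splits <- cfgSplit$splits
  sq <- sqDistMatrix(X, X)
  scoreCfg <- function(i) {
    errs <- vapply(splits, function(te) {
      tr <- setdiff(seq_len(n), te)
      pl <- gprPosteriorStd(sq, tr, te, samples$lat,
                            cfg$lengthscale_lat[i], cfg$noise_lat[i])
      po <- gprPosteriorStd(sq, tr, te, samples$lon,
                            cfg$lengthscale_lon[i], cfg$noise_lon[i])
      mean(haversineKm(samples$lat[te], samples$lon[te], pl$mean, po$mean))
    }, numeric(1))
    c(mean(errs), stats::sd(errs))
  }
  sc <- vapply(seq_len(nConfigs), scoreCfg, numeric(2))
  cfg$err_mean <- sc[1, ]; cfg$err_sd <- sc[2, ]
  best <- which.min(cfg$err_mean)
  list(best = as.list(cfg[best, c("lengthscale_lat", "noise_lat",
                                  "lengthscale_lon", "noise_lon")]),
       log = cfg)
}

# GP posterior for one coordinate from a precomputed squared-distance matrix.
gprPosteriorStd <- function(sq, tr, te, y, lengthscale, noise) {
  m <- mean(y[tr]); s <- stats::sd(y[tr])
  if (!is.finite(s) || s < 1e-12) s <- 1
  ys <- (y[tr] - m) / s
  Ktr <- exp(-sq[tr, tr, drop = FALSE] / (2 * lengthscale^2))
  Kcr <- exp(-sq[te, tr, drop = FALSE] / (2 * lengthscale^2))
  post <- gprPosteriorCore(Ktr, Kcr, rep(1, length(te)), ys, noise)
  list(mean = m + s * post$mean, sd = s * post$sd)
}

#' Direct GPR assigner (coordinates regressed on genotypes, RBF kernel)
#'
#' Two independent GP models (latitude, longitude) on mean-imputed
#' signed-coded genotypes. Hyperparameters are either supplied or tuned once
#' by \code{\link{randomSearchHyperparams}} before the cross-validation loop.
#'
#' @param hyperparams optional named list (lengthscale_lat, noise_lat,
#'   lengthscale_lon, noise_lon); when NULL the random search runs first.
#' @param nConfigs,nRepeats,testFrac,lengthscaleBox,noiseBox search settings.
#' @return a \code{GPRDirectAssigner}.
#' @export
gprDirectAssigner <- function(hyperparams = NULL, nConfigs = 100L,
                              lengthscaleBox = c(0.001, 400),
                              noiseBox = c(1e-4, 1),
                              nRepeats = 5L, testFrac = 0.1) {
  new("GPRDirectAssigner", method = "GPR-D",
      hyperparams = if (is.null(hyperparams)) list() else hyperparams,
      search = list(nConfigs = as.integer(nConfigs),
                    lengthscaleBox = lengthscaleBox, noiseBox = noiseBox,
                    nRepeats = as.integer(nRepeats), testFrac = testFrac))
}

setMethod("precomputeState", "GPRDirectAssigner", function(object, geno, samples, seed = 1L) {
  samples <- alignSamples(geno, samples)
  X <- genotypes(imputeMean(recodeGeno(geno, "signed")))
  hp <- object@hyperparams
  searchLog <- NULL
  if (length(hp) == 0L) {
    s <- object@search
    res <- randomSearchHyperparams(X, samples, nConfigs = s$nConfigs,
                                   lengthscaleBox = s$lengthscaleBox,
                                   noiseBox = s$noiseBox,
                                   nRepeats = s$nRepeats,
                                   testFrac = s$testFrac,
                                   seed = deriveSeed(seed, 101L))
    hp <- res$best
    searchLog <- res$log
  }
  list(sq = sqDistMatrix(X, X), samples = samples, hp = hp,
       searchLog = searchLog)
})

setMethod("predictFold", "GPRDirectAssigner", function(object, state, testIdx, seed = 1L) {
  n <- nrow(state$samples)
  tr <- setdiff(seq_len(n), testIdx)
  hp <- state$hp
  pl <- gprPosteriorStd(state$sq, tr, testIdx, state$samples$lat,
                        hp$lengthscale_lat, hp$noise_lat)
  po <- gprPosteriorStd(state$sq, tr, testIdx, state$samples$lon,
                        hp$lengthscale_lon, hp$noise_lon)
  predictionRow(state$samples$sample_id[testIdx], "GPR-D", pl$mean, po$mean,
                sd_lat = pl$sd, sd_lon = po$sd,
                r95_km = 1.96 * latlonSdToKm(pl$sd, po$sd, pl$mean),
                extras = state$hp)
})

#' @rdname assignOrigin
#' @export
setMethod("assignOrigin", "GPRDirectAssigner",
  function(object, geno, samples, newGeno, seed = 1L, ...) {
    samples <- alignSamples(geno, samples)
    nTr <- nrow(genotypes(geno))
    all <- GenoMatrix(rbind(genotypes(geno), genotypes(newGeno)),
                      ploidy = geno@ploidy)
    X <- genotypes(imputeMean(recodeGeno(all, "signed")))
    hp <- object@hyperparams
    if (length(hp) == 0L) {
      s <- object@search
      hp <- randomSearchHyperparams(X[seq_len(nTr), , drop = FALSE], samples,
                                    nConfigs = s$nConfigs,
                                    lengthscaleBox = s$lengthscaleBox,
                                    noiseBox = s$noiseBox,
                                    nRepeats = s$nRepeats,
                                    testFrac = s$testFrac,
                                    seed = deriveSeed(seed, 101L))$best
    }
    sq <- sqDistMatrix(X, X)
    tr <- seq_len(nTr); te <- nTr + seq_len(nrow(genotypes(newGeno)))
    yLat <- c(samples$lat, rep(NA_real_, length(te)))
    yLon <- c(samples$lon, rep(NA_real_, length(te)))
    pl <- gprPosteriorStd(sq, tr, te, yLat, hp$lengthscale_lat, hp$noise_lat)
    po <- gprPosteriorStd(sq, tr, te, yLon, hp$lengthscale_lon, hp$noise_lon)
    ids <- rownames(genotypes(newGeno))
    bindPredictions(lapply(seq_along(te), function(i) {
      predictionRow(ids[i], "GPR-D", pl$mean[i], po$mean[i],
                    sd_lat = pl$sd[i], sd_lon = po$sd[i],
                    r95_km = 1.96 * latlonSdToKm(pl$sd[i], po$sd[i], pl$mean[i]),
                    extras = hp)
    }))
  })
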