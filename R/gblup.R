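#' Genomic relationship (kinship) matrix
#'
#' VanRaden method-1 construction: signed-coded markers are centred by their
#' column means (missing entries contribute their column mean, i.e. zero after
#' centring) and K = W W' / c with c = sum_j 2 p_j (1 - p_j), where p_j is the
#' reference-allele frequency of marker j.
#'
#' @param enc an \linkS4class{EncodedGeno} in signed coding (keep_na allowed).
#' @return list of class \code{KinshipMatrix}: \code{K} (n x n symmetric
#'   matrix with sample ids as dimnames) and \code{c} (the 2pq normaliser).
#' @export
kinshipMatrix <- function(enc) {
  stopifnot(encodingScheme(enc) == "signed")
  V <- genotypes(enc)
  if (nrow(V) < 2L || ncol(V) < 2L)
    stop("kinshipMatrix: need >= 2 samples and >= 2 markers")
  cm <- colMeans(V, na.rm = TRUE)           # in [-1, 1]
  pHat <- (cm + 1) / 2                      # reference-allele frequency
  cNorm <- sum(2 * pHat * (1 - pHat))
  if (cNorm <= 0)
    stop("kinshipMatrix: all markers monomorphic (sum 2pq = 0)")
  W <- sweep(V, 2, cm, "-")
  W[is.na(W)] <- 0
  K <- tcrossprod(W) / cNorm
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(V), rownames(V))
  structure(list(K = K, c = cNorm), class = "KinshipMatrix")
}

#' Write / read a kinship matrix as TSV
#' @param kin a \code{KinshipMatrix} (or plain matrix).
#' @param path TSV path; header row carries the sample ids.
#' @export
writeKinship <- function(kin, path) {
  K <- if (inherits(kin, "KinshipMatrix")) kin$K else kin
  utils::write.table(data.frame(id = rownames(K), K, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKinship
#' @export
readKinship <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  structure(list(K = K, c = NA_real_), class = "KinshipMatrix")
}

# eigendecomposition with eigenvalues clipped at zero (K is PSD up to
# round-off).
kinshipEigen <- function(Kt) {
  e <- eigen(Kt, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

#' REML variance components for y = mu + g + e with g ~ N(0, sigma2_g K)
#'
#' Profiles the restricted likelihood over the ratio delta = sigma2_e /
#' sigma2_g using a single spectral decomposition of the training-block
#' kinship, then 1-D optimisation over log delta. Entries of \code{y} that
#' are NA mark individuals to exclude from the fit (the held-out test
#' entries).
#'
#' @param K n x n kinship matrix (or \code{KinshipMatrix}).
#' @param y response vector (coordinate in degrees) with NA for test entries.
#' @param eig optional precomputed \code{eigen} of the training block.
#' @return list with sigma2_g, sigma2_e, delta, mu, loglik, converged.
#' @export
remlVarianceComponents <- function(K, y, eig = NULL) {
  if (inherits(K, "KinshipMatrix")) K <- K$K
  t <- which(!is.na(y))
  if (length(t) < 3L) stop("remlVarianceComponents: need >= 3 training entries")
  yt <- y[t]
  n <- length(t)
  if (stats::var(yt) < 1e-12) {
    return(list(sigma2_g = 0, sigma2_e = 0, delta = 1, mu = mean(yt),
                loglik = NA_real_, converged = TRUE))
  }
  if (is.null(eig)) eig <- kinshipEigen(K[t, t, drop = FALSE])
  ystar <- drop(crossprod(eig$vectors, yt))
  xstar <- drop(crossprod(eig$vectors, rep(1, n)))
  d <- eig$values
  profile <- function(logDelta) {
    V <- d + exp(logDelta)
    xv <- sum(xstar^2 / V)
    beta <- sum(xstar * ystar / V) / xv
    r <- ystar - xstar * beta
    s2g <- sum(r^2 / V) / (n - 1)
    ll <- -0.5 * ((n - 1) * log(s2g) + sum(log(V)) + log(xv) + (n - 1))
    list(ll = ll, s2g = s2g, beta = beta)
  }
  obj <- function(ld) -profile(ld)$ll
  opt <- tryCatch(stats::optimize(obj, interval = c(-12, 12)),
                  error = function(e) NULL)
  converged <- !is.null(opt) && is.finite(opt$objective)
  if (!converged) {      # fall back to a grid over log delta
    grid <- seq(-6, 6, length.out = 121)
    vals <- vapply(grid, obj, numeric(1))
    opt <- list(minimum = grid[which.min(vals)], objective = min(vals))
  }
  pr <- profile(opt$minimum)
  delta <- exp(opt$minimum)
  list(sigma2_g = pr$s2g, sigma2_e = pr$s2g * delta, delta = delta,
       mu = pr$beta, loglik = pr$ll, converged = converged)
}

#' BLUP solve with fixed variance components
#'
#' Mixed-model prediction of the genetic values of test individuals from the
#' train-test blocks of the kinship matrix, with the prediction error
#' variance (PEV) accounting for the estimated intercept.
#'
#' @param K full kinship matrix.
#' @param y response with NA at test entries.
#' @param sigma2g,sigma2e variance components.
#' @param eig optional precomputed eigen of the training block.
#' @param ridge diagonal jitter applied if the covariance solve fails.
#' @return list with \code{pred} and \code{pev} for the NA entries (named),
#'   and \code{mu}.
#' @export
gblupSolve <- function(K, y, sigma2g, sigma2e, eig = NULL, ridge = 1e-8) {
  if (inherits(K, "KinshipMatrix")) K <- K$K
  t <- which(!is.na(y)); u <- which(is.na(y))
  yt <- y[t]
  n <- length(t)
  if (sigma2g + sigma2e < 1e-12) {
    mu <- mean(yt)
    pred <- rep(mu, length(u)); pev <- rep(0, length(u))
    names(pred) <- names(pev) <- rownames(K)[u]
    return(list(pred = pred, pev = pev, mu = mu))
  }
  if (is.null(eig)) eig <- kinshipEigen(K[t, t, drop = FALSE])
  V <- sigma2g * eig$values + sigma2e
  if (any(V < ridge)) V <- V + ridge
  U <- eig$vectors
  Vinv <- function(x) U %*% ((crossprod(U, x)) / V)
  one <- rep(1, n)
  Vi1 <- Vinv(one)
  oVo <- sum(one * Vi1)
  mu <- sum(yt * Vi1) / oVo
  r <- yt - mu
  Vir <- Vinv(r)
  Wtu <- sigma2g * K[t, u, drop = FALSE]     # cov(y_train, g_test)
  pred <- mu + drop(crossprod(Wtu, Vir))
  ViW <- apply(Wtu, 2, Vinv)
  quad <- colSums(Wtu * ViW)
  dAdj <- 1 - drop(crossprod(Wtu, Vi1))
  pev <- sigma2g * diag(K)[u] - quad + dAdj^2 / oVo
  pev <- pmax(pev, 0)
  names(pred) <- names(pev) <- rownames(K)[u]
  list(pred = pred, pev = pev, mu = mu)
}

#' gBLUP prediction of coordinates for test individuals
#'
#' Fits REML variance components per coordinate (latitude, longitude fitted
#' independently) on the training entries, solves the mixed model, and
#' converts the per-coordinate PEV into a 95% distance radius:
#' r95 = 1.96 * \code{\link{latlonSdToKm}}(sd_lat, sd_lon, pred_lat).
#'
#' @param K full kinship over training + test individuals
#'   (\code{KinshipMatrix} or matrix).
#' @param samples sample table for the training individuals (ids matching K).
#' @param testIds ids (in K) of the individuals to predict.
#' @return prediction data.frame, one row per test id.
#' @export
gblupPredict <- function(K, samples, testIds) {
  if (inherits(K, "KinshipMatrix")) K <- K$K
  ids <- rownames(K)
  stopifnot(all(testIds %in% ids))
  trainIds <- setdiff(ids, testIds)
  yLat <- yLon <- stats::setNames(rep(NA_real_, length(ids)), ids)
  m <- match(trainIds, samples$sample_id)
  if (anyNA(m)) stop("training ids missing from the sample table")
  yLat[trainIds] <- samples$lat[m]
  yLon[trainIds] <- samples$lon[m]
  t <- which(!is.na(yLat))
  eig <- kinshipEigen(K[t, t, drop = FALSE])
  vcLat <- remlVarianceComponents(K, yLat, eig = eig)
  vcLon <- remlVarianceComponents(K, yLon, eig = eig)
  sLat <- gblupSolve(K, yLat, vcLat$sigma2_g, vcLat$sigma2_e, eig = eig)
  sLon <- gblupSolve(K, yLon, vcLon$sigma2_g, vcLon$sigma2_e, eig = eig)
  bindPredictions(lapply(testIds, function(id) {
    sdLat <- sqrt(sLat$pev[id]); sdLon <- sqrt(sLon$pev[id])
    predictionRow(id, "GP", unname(sLat$pred[id]), unname(sLon$pred[id]),
                  sd_lat = unname(sdLat), sd_lon = unname(sdLon),
                  r95_km = 1.96 * latlonSdToKm(unname(sdLat), unname(sdLon),
                                               unname(sLat$pred[id])),
                  extras = list(sigma2_g_lat = vcLat$sigma2_g,
                                sigma2_e_lat = vcLat$sigma2_e,
                                sigma2_g_lon = vcLon$sigma2_g,
                                sigma2_e_lon = vcLon$sigma2_e))
  }))
}

#' gBLUP assigner (genomic prediction of coordinates)
#'
#' @return a \code{GBLUPAssigner}.
#' @export
gblupAssigner <- function() new("GBLUPAssigner", method = "GP")

setMethod("precomputeState", "GBLUPAssigner", function(object, geno, samples, seed = 1L) {
  samples <- alignSamples(geno, samples)
  enc <- recodeGeno(geno, "signed")      # keep_na: missing load zero in K
  kin <- kinshipMatrix(enc)
  list(K = kin$K, samples = samples)
})

setMethod("predictFold", "GBLUPAssigner", function(object, state, testIdx, seed = 1L) {
  id <- state$samples$sample_id[testIdx]
  gblupPredict(state$K, state$samples[-testIdx, , drop = FALSE], id)
})

#' @rdname assignOrigin
#' @export
setMethod("assignOrigin", "GBLUPAssigner",
  function(object, geno, samples, newGeno, seed = 1L, ...) {
    samples <- alignSamples(geno, samples)
    all <- GenoMatrix(rbind(genotypes(geno), genotypes(newGeno)),
                      ploidy = geno@ploidy)
    kin <- kinshipMatrix(recodeGeno(all, "signed"))
    gblupPredict(kin$K, samples, rownames(genotypes(newGeno)))
  })
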