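#' Aggregate per-cell allele frequencies
#'
#' For every occupied grid cell and SNP, the mean of the unit-coded values of
#' the member individuals with non-missing calls. Because 1/0.5/0 code the
#' reference-allele dosage halves, this mean equals the cell's
#' reference-allele frequency; plastid markers (coded 0/1) contribute as
#' haploid homozygotes.
#'
#' @param enc an \linkS4class{EncodedGeno} in unit coding (keep_na or
#'   imputed).
#' @param samples aligned sample table.
#' @param grid a \linkS4class{GeoGrid} built from the training samples.
#' @return list of class \code{CellFrequencies}: \code{freq} (occupied cells
#'   x SNPs, NA where a cell has no informative call), \code{n_obs}
#'   (informative-call counts), \code{cells} (occupied cell ids) and
#'   \code{grid}.
#' @export
aggregateCellFrequencies <- function(enc, samples, grid) {
  stopifnot(encodingScheme(enc) == "unit")
  V <- genotypes(enc)
  memb <- cellMembership(grid)[samples$sample_id]
  cells <- sort(unique(memb))
  G <- matrix(0, length(cells), ncol(V), dimnames = list(cells, colnames(V)))
  Nobs <- G
  for (ci in seq_along(cells)) {
    rows <- which(memb == cells[ci])
    sub <- V[rows, , drop = FALSE]
    Nobs[ci, ] <- colSums(!is.na(sub))
    G[ci, ] <- colSums(sub, na.rm = TRUE)
  }
  freq <- G / Nobs
  freq[Nobs == 0] <- NA_real_
  structure(list(freq = freq, n_obs = Nobs, cells = cells, grid = grid),
            class = "CellFrequencies")
}

#' Fit per-SNP allele-frequency surfaces
#'
#' One exact GP per SNP on the occupied-cell centers (degrees): Matern 5/2
#' kernel k(r) = s2 (1 + sqrt(5) r / l + 5 r^2 / (3 l^2)) exp(-sqrt(5) r / l)
#' plus observation noise, with a learned constant mean. Hyperparameters are
#' not tuned by search; each model runs exactly \code{epochs} Adam steps on
#' the marginal log-likelihood from fixed (data-derived, deterministic)
#' initial values.
#'
#' @param cf a \code{CellFrequencies} object.
#' @param epochs Adam steps (default 10).
#' @param lr Adam learning rate (default 0.1).
#' @param jitter diagonal stabiliser added to the kernel (default 1e-6).
#' @return list of class \code{SurfaceModel}: per-SNP hyperparameters
#'   (\code{log_var, log_lengthscale, log_noise, mean}), the marginal
#'   log-likelihood trace, and the fitting inputs needed for prediction.
#' @export
fitSnpSurfaces <- function(cf, epochs = 10L, lr = 0.1, jitter = 1e-6) {
  occ <- cf$cells
  if (length(occ) < 3L) stop("fitSnpSurfaces: need >= 3 occupied cells")
  cells <- gridCells(cf$grid)
  ctr <- cells[match(occ, cells$cell_id), c("center_lat", "center_lon")]
  F <- cf$freq
  if (anyNA(F)) {   # cells lacking informative calls for a SNP: column mean
    cm <- colMeans(F, na.rm = TRUE)
    idx <- which(is.na(F), arr.ind = TRUE)
    F[idx] <- cm[idx[, 2]]
  }
  structure(list(centers = as.matrix(ctr), freq = F, epochs = as.integer(epochs),
                 lr = lr, jitter = jitter, snp_ids = colnames(F),
                 grid = cf$grid),
            class = "SurfaceModel")
}

# distance matrix between coordinate sets, degrees (Euclidean in lat/lon,
# matching the degree-spanned grid geometry).
degDistMatrix <- function(A, B) {
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(pmax(d2, 0))
}

#' Predict allele-frequency surfaces at every grid cell
#'
#' Runs the per-SNP GP fits of \code{\link{fitSnpSurfaces}} and evaluates the
#' posterior mean at every cell center (occupied or not), clamped to
#' [eps, 1 - eps].
#'
#' @param model a \code{SurfaceModel}.
#' @param eps clamp width (default 1e-4).
#' @return list: \code{freq} (all cells x SNPs matrix of clamped predicted
#'   frequencies), \code{params} (per-SNP hyperparameters), \code{ll_trace}
#'   (epochs+1 x SNPs marginal log-likelihood trace).
#' @export
predictFrequencies <- function(model, eps = 1e-4) {
  cells <- gridCells(model$grid)
  target <- as.matrix(cells[, c("center_lat", "center_lon")])
  Rtr <- degDistMatrix(model$centers, model$centers)
  Rcr <- degDistMatrix(target, model$centers)
  fit <- cpp_fit_predict_surfaces(Rtr, model$freq, Rcr, model$epochs,
                                  model$lr, model$jitter)
  pred <- pmin(pmax(fit$pred, eps), 1 - eps)
  dimnames(pred) <- list(cells$cell_id, model$snp_ids)
  params <- fit$params
  colnames(params) <- c("log_var", "log_lengthscale", "log_noise", "mean")
  rownames(params) <- model$snp_ids
  list(freq = pred, params = params, ll_trace = fit$ll_trace)
}

#' Hardy-Weinberg log-likelihood of a genotype row given frequencies
#'
#' Sum over non-missing SNPs of log P(g | p) with P = p^2 for g = 1,
#' 2 p (1 - p) for g = 0.5 and (1 - p)^2 for g = 0 at nuclear markers;
#' plastid markers are haploid: P = p for g = 1, (1 - p) for g = 0.
#'
#' @param g unit-coded genotype vector (NA allowed).
#' @param p allele-frequency vector in (0, 1) (same length).
#' @param ploidy per-marker flags ("nuclear"/"plastid").
#' @return the log-likelihood (scalar).
#' @export
hweLogLik <- function(g, p, ploidy = rep("nuclear", length(g))) {
  ok <- !is.na(g)
  g <- g[ok]; p <- p[ok]; pl <- ploidy[ok]
  lp <- log(p); lq <- log1p(-p)
  nuc <- pl == "nuclear"
  ll <- 0
  if (any(nuc)) {
    gn <- g[nuc]
    ll <- ll + sum(2 * lp[nuc] * (gn == 1)) +
      sum((log(2) + lp[nuc] + lq[nuc]) * (gn == 0.5)) +
      sum(2 * lq[nuc] * (gn == 0))
  }
  if (any(!nuc)) {
    gp <- g[!nuc]
    ll <- ll + sum(lp[!nuc] * (gp == 1)) + sum(lq[!nuc] * (gp == 0))
  }
  ll
}

# log-likelihood of one genotype against every cell's frequency row,
# vectorised over cells: contributions reduce to two matrix-vector products.
hweLogLikAllCells <- function(predFreq, g, ploidy) {
  ok <- !is.na(g)
  P <- predFreq[, ok, drop = FALSE]
  g <- g[ok]; pl <- ploidy[ok]
  lp <- log(P); lq <- log1p(-P)
  nuc <- pl == "nuclear"
  wp <- ifelse(nuc, 2 * (g == 1) + (g == 0.5), g == 1)
  wq <- ifelse(nuc, 2 * (g == 0) + (g == 0.5), g == 0)
  nHet <- sum(nuc & g == 0.5)
  drop(lp %*% wp + lq %*% wq) + nHet * log(2)
}

#' Maximum-likelihood grid-cell assignment
#'
#' Scores the test genotype against every cell's predicted allele-frequency
#' row under HWE and predicts the center of the argmax cell (ties broken by
#' lowest cell id). The uncertainty converts the likelihood surface into
#' cell-probability weights w_c proportional to exp(loglik_c - max) and takes
#' the likelihood-weighted spatial sd of the cell centers;
#' r95 = 1.96 * \code{\link{latlonSdToKm}}.
#'
#' @param predFreq all-cells x SNPs matrix of clamped frequencies.
#' @param grid the \linkS4class{GeoGrid}.
#' @param g unit-coded test genotype vector.
#' @param ploidy per-marker flags.
#' @param sampleId id for the prediction row.
#' @param keepSurface store the full log-likelihood surface in extras.
#' @return one-row prediction data.frame.
#' @export
gridAssign <- function(predFreq, grid, g, ploidy = rep("nuclear", length(g)),
                       sampleId = "test", keepSurface = FALSE) {
  ll <- hweLogLikAllCells(predFreq, g, ploidy)
  cells <- gridCells(grid)
  stopifnot(length(ll) == nrow(cells))
  bestIdx <- which(ll == max(ll))[1L]   # ties -> lowest cell index/id
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  mLat <- sum(w * cells$center_lat)
  mLon <- sum(w * cells$center_lon)
  sdLat <- sqrt(max(sum(w * (cells$center_lat - mLat)^2), 0))
  sdLon <- sqrt(max(sum(w * (cells$center_lon - mLon)^2), 0))
  predLat <- cells$center_lat[bestIdx]
  predLon <- cells$center_lon[bestIdx]
  extras <- list(cell_id = cells$cell_id[bestIdx],
                 weighted_lat = mLat, weighted_lon = mLon)
  if (keepSurface)
    extras$loglik <- stats::setNames(ll, cells$cell_id)
  predictionRow(sampleId, "GPR-G", predLat, predLon,
                sd_lat = sdLat, sd_lon = sdLon,
                r95_km = 1.96 * latlonSdToKm(sdLat, sdLon, predLat),
                extras = extras)
}

#' Grid-based GPR assigner
#'
#' Per-SNP Matern 5/2 GP surfaces over a fixed geographic grid, followed by
#' Hardy-Weinberg maximum-likelihood assignment of the test genotype to a
#' cell.
#'
#' @param cellKm grid cell edge length in km (20 and 50 km are the presets
#'   used at sub-continental and continental scale).
#' @param epochs Adam steps per SNP surface (default 10).
#' @param lr Adam learning rate (default 0.1).
#' @param eps frequency clamp (default 1e-4).
#' @return a \code{GPRGridAssigner}.
#' @export
gprGridAssigner <- function(cellKm = 50, epochs = 10L, lr = 0.1, eps = 1e-4) {
  new("GPRGridAssigner", method = "GPR-G", cellKm = cellKm,
      epochs = as.integer(epochs), lr = lr, eps = eps)
}

gprGridPipeline <- function(object, encUnit, samplesTrain, gTest, ids) {
  grid <- buildGrid(samplesTrain, object@cellKm)
  cf <- aggregateCellFrequencies(encUnit, samplesTrain, grid)
  model <- fitSnpSurfaces(cf, epochs = object@epochs, lr = object@lr)
  pf <- predictFrequencies(model, eps = object@eps)
  ploidy <- encUnit@ploidy
  bindPredictions(lapply(seq_along(ids), function(i) {
    gridAssign(pf$freq, grid, gTest[i, ], ploidy, sampleId = ids[i])
  }))
}

setMethod("precomputeState", "GPRGridAssigner", function(object, geno, samples, seed = 1L) {
  samples <- alignSamples(geno, samples)
  list(enc = recodeGeno(geno, "unit"), samples = samples)
})

setMethod("predictFold", "GPRGridAssigner", function(object, state, testIdx, seed = 1L) {
  samplesTr <- state$samples[-testIdx, , drop = FALSE]
  V <- genotypes(state$enc)
  encTr <- new("EncodedGeno", values = V[-testIdx, , drop = FALSE],
               scheme = "unit", missingPolicy = state$enc@missingPolicy,
               columnMeans = numeric(0), ploidy = state$enc@ploidy)
  gprGridPipeline(object, encTr, samplesTr,
                  V[testIdx, , drop = FALSE],
                  state$samples$sample_id[testIdx])
})

#' @rdname assignOrigin
#' @export
setMethod("assignOrigin", "GPRGridAssigner",
  function(object, geno, samples, newGeno, seed = 1L, ...) {
    samples <- alignSamples(geno, samples)
    enc <- recodeGeno(geno, "unit")
    Vte <- genotypes(newGeno)
    gprGridPipeline(object, enc, samples, Vte, rownames(Vte))
  })
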