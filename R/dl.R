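#' Configuration of the neural-network ensemble
#'
#' Defaults follow the published setup: five ReLU hidden layers of 100, 100,
#' 100, 50 and 50 neurons with dropout (0.1 on the input, 0.3/0.3/0.3/0.2/0.2
#' on the hidden layers), L1 and L2 penalties of 1e-6, up to 500 training
#' epochs with early stopping when the monitored RMSE fails to improve by at
#' least 0.001 for ten consecutive rounds, and an ensemble of five networks.
#' Optimiser settings and the 10% validation split that the RMSE is monitored
#' on are framework-level defaults exposed here; the Adam learning rate
#' defaults to 0.01, at which training reaches its early-stopping plateau
#' within a few dozen epochs on standardised targets (at much smaller rates
#' the 0.001 tolerance triggers while the model is still underfit).
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param input_dropout input-layer dropout ratio.
#' @param hidden_dropouts per-hidden-layer dropout ratios (same length as
#'   \code{hidden_sizes}).
#' @param l1,l2 regularisation strengths.
#' @param max_epochs training-epoch cap.
#' @param early_stop_tol minimum RMSE improvement counted as progress.
#' @param patience_rounds consecutive non-improving rounds before stopping.
#' @param ensemble_size number of networks in the ensemble.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param val_frac fraction of training rows held out to monitor RMSE.
#' @return a validated list of class \code{DLConfig}.
#' @export
dlConfig <- function(hidden_sizes = c(100L, 100L, 100L, 50L, 50L),
                     input_dropout = 0.1,
                     hidden_dropouts = c(0.3, 0.3, 0.3, 0.2, 0.2),
                     l1 = 1e-6, l2 = 1e-6, max_epochs = 500L,
                     early_stop_tol = 0.001, patience_rounds = 10L,
                     ensemble_size = 5L, lr = 0.01, batch_size = 32L,
                     val_frac = 0.1) {
  stopifnot(length(hidden_sizes) == length(hidden_dropouts),
            all(hidden_dropouts >= 0), all(hidden_dropouts < 1),
            input_dropout >= 0, input_dropout < 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 input_dropout = input_dropout,
                 hidden_dropouts = hidden_dropouts,
                 l1 = l1, l2 = l2, max_epochs = as.integer(max_epochs),
                 early_stop_tol = early_stop_tol,
                 patience_rounds = as.integer(patience_rounds),
                 ensemble_size = as.integer(ensemble_size),
                 lr = lr, batch_size = as.integer(batch_size),
                 val_frac = val_frac),
            class = "DLConfig")
}

#' Train the neural-network ensemble
#'
#' Trains \code{ensemble_size} two-output networks (standardised latitude and
#' longitude, shared trunk) that differ only in the member seeds derived from
#' \code{seed} (initialisation, dropout masks and validation split). A member
#' whose loss diverges is restarted once with a fresh derived seed.
#'
#' @param X imputed signed-coded genotype matrix (n x p).
#' @param samples aligned sample table supplying the target coordinates.
#' @param cfg a \code{DLConfig}.
#' @param seed integer master seed; identical seeds give identical ensembles.
#' @return list of class \code{DLEnsemble}: members (weights, epochs, RMSE
#'   traces), target standardisation, config and seed.
#' @export
trainDlEnsemble <- function(X, samples, cfg = dlConfig(), seed = 1L) {
  stopifnot(nrow(X) == nrow(samples))
  if (anyNA(X)) stop("trainDlEnsemble: X must be imputed (no missing values)")
  Y <- cbind(samples$lat, samples$lon)
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Ys <- sweep(sweep(Y, 2, mu, "-"), 2, sdv, "/")
  members <- vector("list", cfg$ensemble_size)
  for (m in seq_len(cfg$ensemble_size)) {
    ms <- deriveSeed(seed, 1000L + m)
    fit <- cpp_mlp_train(X, Ys, cfg$hidden_sizes, cfg$input_dropout,
                         cfg$hidden_dropouts, cfg$l1, cfg$l2, cfg$lr,
                         cfg$batch_size, cfg$max_epochs, cfg$early_stop_tol,
                         cfg$patience_rounds, cfg$val_frac, ms)
    if (isTRUE(fit$diverged)) {
      fit <- cpp_mlp_train(X, Ys, cfg$hidden_sizes, cfg$input_dropout,
                           cfg$hidden_dropouts, cfg$l1, cfg$l2, cfg$lr,
                           cfg$batch_size, cfg$max_epochs, cfg$early_stop_tol,
                           cfg$patience_rounds, cfg$val_frac,
                           deriveSeed(seed, 2000L + m))
      if (isTRUE(fit$diverged))
        stop("trainDlEnsemble: member ", m, " diverged twice")
    }
    members[[m]] <- fit
  }
  structure(list(members = members, target_mean = mu, target_sd = sdv,
                 config = cfg, seed = as.integer(seed)),
            class = "DLEnsemble")
}

#' Per-member back-transformed predictions
#'
#' @param ensemble a \code{DLEnsemble}.
#' @param X imputed signed genotype matrix of test individuals.
#' @return list of two matrices (\code{lat}, \code{lon}), n x members.
#' @export
dlMemberPredictions <- function(ensemble, X) {
  preds <- lapply(ensemble$members, function(m) cpp_mlp_predict(m$W, m$b, X))
  lat <- sapply(preds, function(P) ensemble$target_mean[1] +
                  ensemble$target_sd[1] * P[, 1])
  lon <- sapply(preds, function(P) ensemble$target_mean[2] +
                  ensemble$target_sd[2] * P[, 2])
  if (nrow(X) == 1L) { lat <- matrix(lat, 1); lon <- matrix(lon, 1) }
  list(lat = lat, lon = lon)
}

#' Aggregate ensemble member predictions for one individual
#'
#' Ensemble mean of the member coordinates, plus the uncertainty policy
#' shared with the nearest-neighbour method: the pairwise Haversine distances
#' among the member predictions give mean m and sd s, and r95 = m + 1.96 s.
#'
#' @param lat,lon numeric vectors of member predictions (degrees).
#' @param sampleId id for the prediction row.
#' @return one-row prediction data.frame.
#' @export
aggregateEnsemble <- function(lat, lon, sampleId = "test") {
  k <- length(lat)
  predLat <- mean(lat); predLon <- mean(lon)
  if (k >= 2L) {
    pr <- utils::combn(k, 2)
    pairKm <- haversineKm(lat[pr[1, ]], lon[pr[1, ]], lat[pr[2, ]], lon[pr[2, ]])
  } else pairKm <- numeric(0)
  predictionRow(sampleId, "DL", predLat, predLon,
                sd_lat = stats::sd(lat), sd_lon = stats::sd(lon),
                r95_km = radiusFromPairwise(pairKm),
                extras = list(member_lat = lat, member_lon = lon,
                              pair_km = pairKm))
}

#' Predict origins with a trained ensemble
#'
#' @param ensemble a \code{DLEnsemble}.
#' @param X imputed signed genotype matrix of test individuals (rownames used
#'   as sample ids).
#' @return prediction data.frame, one row per test individual.
#' @export
dlPredict <- function(ensemble, X) {
  mp <- dlMemberPredictions(ensemble, X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("test", seq_len(nrow(X)))
  bindPredictions(lapply(seq_len(nrow(X)), function(i) {
    aggregateEnsemble(mp$lat[i, ], mp$lon[i, ], sampleId = ids[i])
  }))
}

#' Deep-learning assigner (feedforward ensemble)
#'
#' @param config a \code{\link{dlConfig}}.
#' @return a \code{DLAssigner}.
#' @export
dlAssigner <- function(config = dlConfig()) {
  new("DLAssigner", method = "DL", config = unclass(config))
}

setMethod("precomputeState", "DLAssigner", function(object, geno, samples, seed = 1L) {
  samples <- alignSamples(geno, samples)
  X <- genotypes(imputeMean(recodeGeno(geno, "signed")))
  list(X = X, samples = samples)
})

setMethod("predictFold", "DLAssigner", function(object, state, testIdx, seed = 1L) {
  cfg <- do.call(dlConfig, object@config)
  ens <- trainDlEnsemble(state$X[-testIdx, , drop = FALSE],
                         state$samples[-testIdx, , drop = FALSE],
                         cfg, seed = deriveSeed(seed, testIdx))
  dlPredict(ens, state$X[testIdx, , drop = FALSE])
})

#' @rdname assignOrigin
#' @export
setMethod("assignOrigin", "DLAssigner",
  function(object, geno, samples, newGeno, seed = 1L, ...) {
    samples <- alignSamples(geno, samples)
    all <- GenoMatrix(rbind(genotypes(geno), genotypes(newGeno)),
                      ploidy = geno@ploidy)
    Xall <- genotypes(imputeMean(recodeGeno(all, "signed")))
    nTr <- nrow(genotypes(geno))
    cfg <- do.call(dlConfig, object@config)
    ens <- trainDlEnsemble(Xall[seq_len(nTr), , drop = FALSE], samples, cfg,
                           seed = seed)
    dlPredict(ens, Xall[nTr + seq_len(nrow(genotypes(newGeno))), ,
                        drop = FALSE])
  })
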