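#' Leave-one-out cross-validation over an assigner
#'
#' Each individual in turn is held out and predicted from a model trained on
#' the remaining individuals (for the gBLUP variant its coordinates are set
#' to missing in the response while the kinship, computed once over all
#' individuals, is reused). Deterministic given \code{seed}. A failing fold
#' is recorded and the run continues.
#'
#' @param assigner an \linkS4class{Assigner}.
#' @param geno a \linkS4class{GenoMatrix} covering all individuals.
#' @param samples aligned sample table (the passport data).
#' @param seed integer seed.
#' @param verbose print fold progress every 50 folds.
#' @param folds optional integer vector of fold indices to evaluate (default
#'   all). Each evaluated fold is still a full leave-one-out fit; a subset
#'   gives an unbiased sample of the per-individual errors when the complete
#'   loop is too expensive.
#' @return prediction data.frame with one row per successful fold; failed
#'   fold ids are stored in \code{attr(, "failed_folds")}.
#' @export
looCrossval <- function(assigner, geno, samples, seed = 1L, verbose = FALSE,
                        folds = NULL) {
  samples <- alignSamples(geno, samples)
  n <- nrow(samples)
  if (is.null(folds)) folds <- seq_len(n)
  stopifnot(all(folds >= 1L), all(folds <= n))
  state <- precomputeState(assigner, geno, samples, seed = seed)
  rows <- vector("list", length(folds))
  failed <- character(0)
  for (fi in seq_along(folds)) {
    i <- folds[fi]
    rows[[fi]] <- tryCatch(
      predictFold(assigner, state, i, seed = seed),
      error = function(e) {
        warning("fold ", samples$sample_id[i], " failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(rows[[fi]])) failed <- c(failed, samples$sample_id[i])
    if (verbose && fi %% 50L == 0L)
      message(assigner@method, ": fold ", fi, "/", length(folds))
  }
  preds <- bindPredictions(Filter(Negate(is.null), rows))
  attr(preds, "failed_folds") <- failed
  preds
}

#' Summarise prediction accuracy
#'
#' Per-sample Haversine distances between passport and predicted locations,
#' their mean/median/sd, Pearson correlations between given and predicted
#' latitude and longitude (and their mean), the maximum pairwise distance
#' among the samples, and the sorted relative-error vector (distance divided
#' by that maximum).
#'
#' @param preds prediction data.frame.
#' @param samples sample table with the passport coordinates.
#' @return list of class \code{EvalReport}: \code{per_sample} data.frame and
#'   \code{summary} one-row data.frame, plus \code{relative_errors} (sorted)
#'   and \code{n_failed}.
#' @export
summarizeEval <- function(preds, samples) {
  stopifnot(nrow(preds) >= 2L)
  m <- match(preds$sample_id, samples$sample_id)
  if (anyNA(m)) stop("summarizeEval: predictions for unknown sample ids")
  truth <- samples[m, , drop = FALSE]
  dist <- haversineKm(truth$lat, truth$lon, preds$pred_lat, preds$pred_lon)
  maxPair <- pairwiseDistanceStats(samples)$max_km
  per <- data.frame(sample_id = preds$sample_id,
                    group_id = truth$group_id,
                    method = preds$method,
                    true_lat = truth$lat, true_lon = truth$lon,
                    pred_lat = preds$pred_lat, pred_lon = preds$pred_lon,
                    distance_km = dist,
                    r95_km = preds$r95_km,
                    relative_error = dist / maxPair,
                    stringsAsFactors = FALSE)
  corSafe <- function(a, b) {
    if (stats::sd(b) < 1e-12 || stats::sd(a) < 1e-12) NA_real_
    else stats::cor(a, b)
  }
  rLat <- corSafe(truth$lat, preds$pred_lat)
  rLon <- corSafe(truth$lon, preds$pred_lon)
  summary <- data.frame(
    method = preds$method[1],
    n = nrow(per),
    mean_km = mean(dist), median_km = stats::median(dist),
    sd_km = stats::sd(dist),
    r_lat = rLat, r_lon = rLon, r_mean = mean(c(rLat, rLon)),
    max_pairwise_km = maxPair,
    median_relative_error = stats::median(per$relative_error),
    stringsAsFactors = FALSE)
  failed <- attr(preds, "failed_folds")
  structure(list(per_sample = per, summary = summary,
                 relative_errors = sort(per$relative_error),
                 n_failed = length(failed)),
            class = "EvalReport")
}

#' Pairwise geographic distance statistics of a sample set
#'
#' All n(n-1)/2 Haversine distances, summarised.
#'
#' @param samples sample table (>= 2 rows).
#' @param breaks histogram bin count or break vector (passed to
#'   \code{\link[graphics]{hist}} semantics via \code{\link{cut}}).
#' @return list: mean_km, sd_km, max_km, histogram (data.frame of bin
#'   mid/count).
#' @export
pairwiseDistanceStats <- function(samples, breaks = 20L) {
  n <- nrow(samples)
  stopifnot(n >= 2L)
  pr <- utils::combn(n, 2)
  d <- haversineKm(samples$lat[pr[1, ]], samples$lon[pr[1, ]],
                   samples$lat[pr[2, ]], samples$lon[pr[2, ]])
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(mean_km = mean(d), sd_km = if (length(d) > 1) stats::sd(d) else 0,
       max_km = max(d),
       histogram = data.frame(mid_km = h$mids, count = h$counts))
}

#' Correlation matrix of per-sample errors across methods
#'
#' Pearson correlations of the per-sample distances between given and
#' predicted locations, across methods run on the same individuals.
#'
#' @param reports named list of \code{EvalReport}s (one per method).
#' @return correlation matrix (methods x methods).
#' @export
methodDistanceCorrelation <- function(reports) {
  stopifnot(length(reports) >= 2L)
  ids <- Reduce(intersect, lapply(reports, function(r) r$per_sample$sample_id))
  D <- sapply(reports, function(r) {
    ps <- r$per_sample
    ps$distance_km[match(ids, ps$sample_id)]
  })
  stats::cor(D)
}

#' Write an evaluation report as two TSVs
#'
#' @param report an \code{EvalReport}.
#' @param perSamplePath,summaryPath output TSV paths.
#' @export
writeEvalReport <- function(report, perSamplePath, summaryPath) {
  utils::write.table(report$per_sample, perSamplePath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, summaryPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
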