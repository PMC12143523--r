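#' Genetic distance between coded genotype rows
#'
#' Mean absolute difference of unit-coded allele values over the loci that are
#' non-missing in both individuals; a dissimilarity in [0, 1].
#'
#' @param gi,gj numeric genotype vectors in unit coding (0/0.5/1/NA).
#' @return mean absolute difference over shared loci.
#' @export
geneticDistance <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) stop("geneticDistance: no shared non-missing locus")
  mean(abs(gi[ok] - gj[ok]))
}

#' All-pairs genetic distance matrix
#'
#' Computes \code{\link{geneticDistance}} between every pair of rows using
#' masked cross-products. For unit-coded values the absolute difference d over
#' \{0, 0.5, 1\} satisfies |d| = (7/3) d^2 - (4/3) d^4, which turns the
#' computation into a handful of matrix products.
#'
#' @param V numeric matrix in unit coding (individuals x markers, NA allowed).
#' @return symmetric n x n dissimilarity matrix (NaN where a pair shares no
#'   locus).
#' @export
geneticDistanceMatrix <- function(V) {
  M <- (!is.na(V)) * 1
  A <- V; A[is.na(A)] <- 0
  A2 <- A * A; A3 <- A2 * A; A4 <- A2 * A2
  C <- tcrossprod(M)
  S2 <- tcrossprod(A2, M) + tcrossprod(M, A2) - 2 * tcrossprod(A)
  S4 <- tcrossprod(A4, M) + tcrossprod(M, A4) -
    4 * (tcrossprod(A3, A) + tcrossprod(A, A3)) + 6 * tcrossprod(A2)
  D <- ((7 / 3) * S2 - (4 / 3) * S4) / C
  D[C == 0] <- NaN
  D <- (D + t(D)) / 2        # enforce exact symmetry
  diag(D) <- 0
  dimnames(D) <- list(rownames(V), rownames(V))
  D
}

# cross distances: rows of Vtest vs rows of Vtrain (same marker columns).
geneticCrossDistance <- function(Vtest, Vtrain) {
  D <- geneticDistanceMatrix(rbind(Vtest, Vtrain))
  D[seq_len(nrow(Vtest)), nrow(Vtest) + seq_len(nrow(Vtrain)), drop = FALSE]
}

#' Nearest-neighbour continuous assignment for one test genotype
#'
#' Averages the coordinates of the k genetically most similar training
#' individuals. The uncertainty is derived from the k(k-1)/2 pairwise
#' Haversine distances among those neighbours: r95 = mean + 1.96 sd
#' (policy \code{"mean_plus_1.96sd"}) or 1.96 sd (policy \code{"1.96sd"}).
#'
#' @param dist distances from the test genotype to each training individual
#'   (e.g. a row of \code{\link{geneticDistanceMatrix}}).
#' @param samplesTrain training sample table aligned with \code{dist}.
#' @param k number of neighbours (ties at rank k broken by training order).
#' @param sampleId id reported in the prediction row.
#' @param radiusPolicy uncertainty policy (see above).
#' @return one-row prediction data.frame.
#' @export
nnAssign <- function(dist, samplesTrain, k = 5L, sampleId = "test",
                     radiusPolicy = "mean_plus_1.96sd") {
  n <- length(dist)
  stopifnot(k >= 1L, k <= n)
  # rank on distances rounded to 1e-9 so that exact ties (common with few
  # markers) break by training order regardless of how the distances were
  # accumulated in floating point
  nb <- order(round(dist, 9))[seq_len(k)]
  lat <- samplesTrain$lat[nb]
  lon <- samplesTrain$lon[nb]
  predLat <- mean(lat); predLon <- mean(lon)
  if (k >= 2L) {
    pr <- utils::combn(k, 2)
    pairKm <- haversineKm(lat[pr[1, ]], lon[pr[1, ]], lat[pr[2, ]], lon[pr[2, ]])
    r95 <- radiusFromPairwise(pairKm, radiusPolicy)
    flagged <- FALSE
  } else {
    pairKm <- numeric(0); r95 <- 0; flagged <- TRUE
  }
  predictionRow(sampleId, "NN", predLat, predLon,
                sd_lat = stats::sd(lat), sd_lon = stats::sd(lon), r95_km = r95,
                extras = list(neighbour_ids = samplesTrain$sample_id[nb],
                              neighbour_dist = unname(dist[nb]),
                              pair_km_mean = if (length(pairKm)) mean(pairKm) else 0,
                              pair_km_sd = if (length(pairKm) > 1) stats::sd(pairKm) else 0,
                              uncertainty_disabled = flagged))
}

#' Nearest-neighbour assigner
#'
#' @param k neighbour count (the cross-validation optimum of the method is
#'   k = 5, the default).
#' @param radiusPolicy \code{"mean_plus_1.96sd"} (default) or \code{"1.96sd"}.
#' @return an \code{NNAssigner}.
#' @export
nnAssigner <- function(k = 5L, radiusPolicy = c("mean_plus_1.96sd", "1.96sd")) {
  new("NNAssigner", method = "NN", k = as.integer(k),
      radiusPolicy = match.arg(radiusPolicy))
}

setMethod("precomputeState", "NNAssigner", function(object, geno, samples, seed = 1L) {
  samples <- alignSamples(geno, samples)
  V <- genotypes(recodeGeno(geno, "unit"))
  list(D = geneticDistanceMatrix(V), samples = samples)
})

setMethod("predictFold", "NNAssigner", function(object, state, testIdx, seed = 1L) {
  train <- setdiff(seq_len(nrow(state$samples)), testIdx)
  nnAssign(state$D[testIdx, train], state$samples[train, , drop = FALSE],
           k = object@k, sampleId = state$samples$sample_id[testIdx],
           radiusPolicy = object@radiusPolicy)
})

#' @rdname assignOrigin
#' @export
setMethod("assignOrigin", "NNAssigner",
  function(object, geno, samples, newGeno, seed = 1L, ...) {
    samples <- alignSamples(geno, samples)
    Vtr <- genotypes(recodeGeno(geno, "unit"))
    Vte <- genotypes(recodeGeno(newGeno, "unit"))
    D <- geneticCrossDistance(Vte, Vtr)
    bindPredictions(lapply(seq_len(nrow(Vte)), function(i) {
      nnAssign(D[i, ], samples, k = object@k, sampleId = rownames(Vte)[i],
               radiusPolicy = object@radiusPolicy)
    }))
  })
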