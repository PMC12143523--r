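#' Filter markers and samples by missingness
#'
#' Drops markers whose fraction of missing calls is >= \code{maxRate}, then
#' samples whose missing fraction over the retained markers is >=
#' \code{maxRate} (one pass each, markers first). The retained data therefore
#' have less than \code{maxRate} missingness per marker and per sample.
#'
#' @param geno a \linkS4class{GenoMatrix}.
#' @param maxRate maximum tolerated missing fraction (default 0.05).
#' @param verbose print dropped ids.
#' @return filtered \linkS4class{GenoMatrix} with attributes
#'   \code{dropped_markers} and \code{dropped_samples}.
#' @export
filterMissingness <- function(geno, maxRate = 0.05, verbose = FALSE) {
  stopifnot(maxRate >= 0, maxRate < 1)
  v <- genotypes(geno)
  mrate <- colMeans(is.na(v))
  dropM <- colnames(v)[mrate >= maxRate]
  keepM <- mrate < maxRate
  v2 <- v[, keepM, drop = FALSE]
  if (ncol(v2) == 0L) stop("all markers dropped by the missingness filter")
  srate <- rowMeans(is.na(v2))
  dropS <- rownames(v2)[srate >= maxRate]
  v3 <- v2[srate < maxRate, , drop = FALSE]
  if (nrow(v3) == 0L) stop("all samples dropped by the missingness filter")
  if (verbose && (length(dropM) || length(dropS)))
    message("dropped ", length(dropM), " marker(s), ",
            length(dropS), " sample(s)")
  out <- GenoMatrix(v3, ploidy = geno@ploidy[keepM])
  attr(out, "dropped_markers") <- dropM
  attr(out, "dropped_samples") <- dropS
  out
}

#' Recode genotypes for a learning method
#'
#' \code{unit} keeps the 0/0.5/1 coding; \code{signed} applies the affine map
#' x -> 2x - 1, giving 1 (homozygote reference), 0 (heterozygote), -1
#' (homozygote alternative). Missing entries are preserved.
#'
#' @param geno a \linkS4class{GenoMatrix} or \linkS4class{EncodedGeno}.
#' @param scheme \code{"unit"} or \code{"signed"}.
#' @return an \linkS4class{EncodedGeno} with \code{missingPolicy = "keep_na"}
#'   (imputation status is preserved when re-coding an already imputed
#'   matrix).
#' @export
recodeGeno <- function(geno, scheme = c("unit", "signed")) {
  scheme <- match.arg(scheme)
  if (is(geno, "GenoMatrix")) {
    v <- genotypes(geno)
    from <- "unit"
    policy <- "keep_na"
    cm <- numeric(0)
  } else {
    v <- genotypes(geno)
    from <- encodingScheme(geno)
    policy <- missingPolicy(geno)
    cm <- columnMeans(geno)
  }
  if (from == "unit" && scheme == "signed") v <- 2 * v - 1
  if (from == "signed" && scheme == "unit") v <- (v + 1) / 2
  new("EncodedGeno", values = v, scheme = scheme, missingPolicy = policy,
      columnMeans = cm, ploidy = geno@ploidy)
}

#' Mean-impute missing genotype calls
#'
#' Each missing entry is replaced by the mean of the non-missing entries of
#' its marker (the average allele value over all other individuals).
#'
#' @param enc an \linkS4class{EncodedGeno} (any scheme).
#' @return an \linkS4class{EncodedGeno} with \code{missingPolicy =
#'   "mean_imputed"} and the column means recorded.
#' @export
imputeMean <- function(enc) {
  v <- genotypes(enc)
  nMiss <- colSums(!is.na(v))
  if (any(nMiss == 0L))
    stop("fully missing marker column(s): ",
         paste(utils::head(colnames(v)[nMiss == 0L], 5), collapse = ", "),
         " (filter first)")
  cm <- colMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- cm[idx[, 2]]
  new("EncodedGeno", values = v, scheme = encodingScheme(enc),
      missingPolicy = "mean_imputed", columnMeans = unname(cm),
      ploidy = enc@ploidy)
}

#' Select SNPs with significant spatial clines
#'
#' For each marker, two-sided Pearson correlation tests of the genotype
#' against latitude and against longitude; a marker is kept when
#' \code{min(p_lat, p_lon) <= alpha / (2 * nMarkers)} (Bonferroni over the
#' family of 2 tests per marker). Zero-variance markers are excluded (their
#' correlation is undefined). P-values are invariant to affine recoding, so
#' either encoding scheme can be supplied.
#'
#' @param enc an \linkS4class{EncodedGeno}; missing entries are handled by
#'   pairwise-complete correlation.
#' @param samples sample table aligned with \code{enc}.
#' @param alpha family-wise significance level (default 0.05).
#' @return list with \code{keep} (integer marker indices) and \code{report}
#'   (per-marker data.frame: marker_id, r_lat, r_lon, p_lat, p_lon, kept).
#' @export
selectClinalSnps <- function(enc, samples, alpha = 0.05) {
  v <- genotypes(enc)
  stopifnot(nrow(v) == nrow(samples))
  p <- ncol(v)
  corP <- function(x, y) {
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3L) return(c(NA_real_, NA_real_))
    sx <- stats::sd(x[ok])
    if (!is.finite(sx) || sx == 0) return(c(NA_real_, NA_real_))
    r <- stats::cor(x[ok], y[ok])
    r <- max(min(r, 1), -1)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r, 2 * stats::pt(-abs(tt), df = n - 2))
  }
  resLat <- vapply(seq_len(p), function(j) corP(v[, j], samples$lat), numeric(2))
  resLon <- vapply(seq_len(p), function(j) corP(v[, j], samples$lon), numeric(2))
  thr <- alpha / (2 * p)
  pmin2 <- pmin(resLat[2, ], resLon[2, ])
  kept <- which(!is.na(pmin2) & pmin2 <= thr)
  report <- data.frame(
    marker_id = colnames(v),
    r_lat = resLat[1, ], r_lon = resLon[1, ],
    p_lat = resLat[2, ], p_lon = resLon[2, ],
    kept = seq_len(p) %in% kept,
    stringsAsFactors = FALSE)
  list(keep = kept, report = report, threshold = thr)
}

#' Subset a GenoMatrix
#'
#' @param geno a \linkS4class{GenoMatrix}.
#' @param i sample indices or ids (optional).
#' @param j marker indices or ids (optional).
#' @return the subsetted \linkS4class{GenoMatrix}.
#' @export
subsetGeno <- function(geno, i = NULL, j = NULL) {
  v <- genotypes(geno)
  pl <- geno@ploidy
  if (!is.null(j)) {
    if (is.character(j)) j <- match(j, colnames(v))
    v <- v[, j, drop = FALSE]
    pl <- pl[j]
  }
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  GenoMatrix(v, ploidy = pl)
}
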