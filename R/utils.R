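# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

predictionRow <- function(sample_id, method, pred_lat, pred_lon,
                          sd_lat = NA_real_, sd_lon = NA_real_,
                          r95_km = NA_real_, extras = list()) {
  df <- data.frame(sample_id = sample_id, method = method,
                   pred_lat = pred_lat, pred_lon = pred_lon,
                   sd_lat = sd_lat, sd_lon = sd_lon, r95_km = r95_km,
                   stringsAsFactors = FALSE)
  df$extras <- list(extras)
  df
}

bindPredictions <- function(rows) {
  extras <- lapply(rows, function(r) r$extras[[1]])
  df <- do.call(rbind, lapply(rows, function(r) r[setdiff(names(r), "extras")]))
  rownames(df) <- NULL
  df$extras <- extras
  df
}

# mean + 1.96 sd policy shared by the NN and DL 95% radii; `policy`
# "mean_plus_1.96sd" (default) or "1.96sd".
radiusFromPairwise <- function(pairKm, policy = "mean_plus_1.96sd") {
  if (length(pairKm) == 0L) return(0)
  m <- mean(pairKm)
  s <- if (length(pairKm) > 1L) stats::sd(pairKm) else 0
  if (policy == "1.96sd") 1.96 * s else m + 1.96 * s
}

alignSamples <- function(geno, samples) {
  v <- genotypes(geno)
  if (!identical(rownames(v), samples$sample_id)) {
    idx <- match(rownames(v), samples$sample_id)
    if (anyNA(idx))
      stop("sample table does not cover all genotyped individuals")
    samples <- samples[idx, , drop = FALSE]
    rownames(samples) <- NULL
  }
  samples
}
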