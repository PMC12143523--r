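# Shared fixture builders (generated in code; nothing stored on disk).

toy_geno <- function(n = 6, p = 8, seed = 42, missing = 0, plastid = 0) {
  set.seed(seed)
  v <- matrix(sample(c(0, 0.5, 1), n * p, replace = TRUE), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("m%02d", 1:p)))
  ploidy <- rep("nuclear", p)
  if (plastid > 0) {
    pj <- seq_len(plastid)
    v[, pj] <- round(v[, pj])          # no heterozygotes
    ploidy[pj] <- "plastid"
  }
  if (missing > 0) v[sample(n * p, missing)] <- NA
  GenoMatrix(v, ploidy = ploidy)
}

toy_samples <- function(n = 6, seed = 42) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%02d", 1:n),
             group_id = sprintf("g%02d", rep(1:max(1, n %/% 2), length.out = n)),
             lat = runif(n, 44, 54), lon = runif(n, 4, 24),
             stringsAsFactors = FALSE)
}

# small clinal landscape shared by several test files
small_landscape <- function(seed = 11, n_sites = 10, n_per_site = 6,
                            n_snps = 80, ...) {
  simulateLandscape(simConfig(n_sites = n_sites, n_per_site = n_per_site,
                              n_snps = n_snps, seed = seed, ...))
}
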