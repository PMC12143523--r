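#' Configuration of the synthetic SNP landscape
#'
#' The generator emulates a provenance-trial style design: sampling sites on
#' a jittered grid over a continental window, a fixed number of individuals
#' per site, and biallelic SNPs whose allele frequencies follow smooth
#' spatial clines (logistic link over standardised coordinates) plus a
#' smooth random field, with Hardy-Weinberg genotype sampling, optional
#' plastid-like haploid markers and a small missing-call rate.
#'
#' @param domain named vector lat_min/lat_max/lon_min/lon_max (decimal
#'   degrees).
#' @param n_sites number of sampling locations.
#' @param n_per_site individuals per site: a scalar, or a length-2 range
#'   sampled uniformly per site.
#' @param n_snps number of SNPs.
#' @param frac_plastid fraction of haploid-behaving plastid markers.
#' @param cline_strength sd of the per-SNP latitude/longitude slopes on the
#'   logit scale (standardised coordinates).
#' @param surface_roughness sd of the smooth non-linear logit component.
#' @param field_lengthscale Matern 5/2 lengthscale of that component, in
#'   standardised coordinate units.
#' @param missing_rate per-call missing probability (must stay below 0.05,
#'   the pre-processing threshold).
#' @param seed integer seed.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(domain = c(lat_min = 44, lat_max = 54,
                                 lon_min = 4, lon_max = 24),
                      n_sites = 40L, n_per_site = 10L, n_snps = 300L,
                      frac_plastid = 0, cline_strength = 1.5,
                      surface_roughness = 0.5, field_lengthscale = 0.75,
                      missing_rate = 0.02, seed = 1L) {
  stopifnot(n_sites >= 2L, n_snps >= 1L, all(n_per_site >= 1L),
            missing_rate >= 0, missing_rate <= 0.05,
            frac_plastid >= 0, frac_plastid <= 1,
            domain["lat_max"] > domain["lat_min"],
            domain["lon_max"] > domain["lon_min"])
  structure(list(domain = domain, n_sites = as.integer(n_sites),
                 n_per_site = as.integer(n_per_site),
                 n_snps = as.integer(n_snps), frac_plastid = frac_plastid,
                 cline_strength = cline_strength,
                 surface_roughness = surface_roughness,
                 field_lengthscale = field_lengthscale,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "SimConfig")
}

# Matern 5/2 correlation between site coordinate rows (standardised units).
maternCorr <- function(Z, l) {
  R <- degDistMatrix(Z, Z)
  S <- sqrt(5) * R / l
  (1 + S + S^2 / 3) * exp(-S)
}

#' Simulate a georeferenced SNP landscape
#'
#' Per SNP j the allele-frequency surface is
#' p_j(site) = plogis(a_j + b_j z_lat + c_j z_lon + f_j(site)), with
#' intercepts a_j ~ U(-1.5, 1.5), slopes b_j, c_j ~ N(0, cline_strength^2)
#' on standardised site coordinates and f_j a smooth Matern 5/2 random field
#' scaled by \code{surface_roughness}. Diploid genotypes are sampled as
#' Binomial(2, p_j)/2 in unit coding; plastid markers as Bernoulli(p_j) in
#' \{0, 1\}; calls go missing independently with \code{missing_rate}.
#' Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list: \code{geno} (\linkS4class{GenoMatrix}), \code{samples}
#'   (passport table; group = site) and \code{truth} (\code{SimTruth}: the
#'   surface parameters, per-site true frequencies, site table and an empty
#'   translocation record).
#' @export
simulateLandscape <- function(cfg) {
  withSeed(cfg$seed, {
    dom <- cfg$domain
    nS <- cfg$n_sites
    # jittered grid of sites
    aspect <- (dom["lat_max"] - dom["lat_min"]) / (dom["lon_max"] - dom["lon_min"])
    nr <- max(1L, round(sqrt(nS * aspect)))
    nc <- ceiling(nS / nr)
    latStep <- (dom["lat_max"] - dom["lat_min"]) / nr
    lonStep <- (dom["lon_max"] - dom["lon_min"]) / nc
    cellIdx <- sample(nr * nc, nS)
    ri <- (cellIdx - 1L) %% nr; ci <- (cellIdx - 1L) %/% nr
    siteLat <- dom["lat_min"] + (ri + 0.5 + stats::runif(nS, -0.35, 0.35)) * latStep
    siteLon <- dom["lon_min"] + (ci + 0.5 + stats::runif(nS, -0.35, 0.35)) * lonStep
    sites <- data.frame(site_id = sprintf("g%03d", seq_len(nS)),
                        lat = unname(siteLat), lon = unname(siteLon),
                        stringsAsFactors = FALSE)
    zLat <- (sites$lat - mean(sites$lat)) / stats::sd(sites$lat)
    zLon <- (sites$lon - mean(sites$lon)) / stats::sd(sites$lon)

    p <- cfg$n_snps
    a <- stats::runif(p, -1.5, 1.5)
    b <- stats::rnorm(p, 0, cfg$cline_strength)
    cc <- stats::rnorm(p, 0, cfg$cline_strength)
    field <- matrix(0, nS, p)
    if (cfg$surface_roughness > 0) {
      C <- maternCorr(cbind(zLat, zLon), cfg$field_lengthscale)
      L <- t(chol(C + diag(1e-8, nS)))
      field <- cfg$surface_roughness * (L %*% matrix(stats::rnorm(nS * p), nS, p))
    }
    logit <- outer(rep(1, nS), a) + outer(zLat, b) + outer(zLon, cc) + field
    siteFreq <- stats::plogis(logit)

    nPer <- if (length(cfg$n_per_site) == 2L)
      sample(cfg$n_per_site[1]:cfg$n_per_site[2], nS, replace = TRUE)
    else rep(cfg$n_per_site, nS)
    siteOf <- rep(seq_len(nS), nPer)
    n <- length(siteOf)
    ploidy <- rep("nuclear", p)
    if (cfg$frac_plastid > 0)
      ploidy[sample(p, round(cfg$frac_plastid * p))] <- "plastid"
    P <- siteFreq[siteOf, , drop = FALSE]
    G <- matrix(NA_real_, n, p)
    nuc <- ploidy == "nuclear"
    if (any(nuc))
      G[, nuc] <- matrix(stats::rbinom(n * sum(nuc), 2, P[, nuc]), n) / 2
    if (any(!nuc))
      G[, !nuc] <- matrix(stats::rbinom(n * sum(!nuc), 1, P[, !nuc]), n)
    if (cfg$missing_rate > 0) {
      G[matrix(stats::runif(n * p) < cfg$missing_rate, n, p)] <- NA_real_
    }
    rownames(G) <- sprintf("s%04d", seq_len(n))
    colnames(G) <- sprintf("snp%04d", seq_len(p))
    samples <- data.frame(sample_id = rownames(G),
                          group_id = sites$site_id[siteOf],
                          lat = sites$lat[siteOf], lon = sites$lon[siteOf],
                          stringsAsFactors = FALSE)
    truth <- structure(
      list(surface = data.frame(marker_id = colnames(G), a = a, b = b, c = cc),
           site_field = field, site_freq = siteFreq, sites = sites,
           site_of = siteOf, ploidy = ploidy,
           translocations = data.frame(id = character(), scope = character(),
                                       true_lat = numeric(), true_lon = numeric(),
                                       recorded_lat = numeric(),
                                       recorded_lon = numeric(),
                                       stringsAsFactors = FALSE)),
      class = "SimTruth")
    list(geno = GenoMatrix(G, ploidy = ploidy),
         samples = validateSampleTable(samples), truth = truth)
  })
}

#' Inject translocated individuals and groups
#'
#' Moves the *recorded* passport coordinates of selected individuals (and of
#' every member of selected sites) to another existing site at least
#' \code{min_km} away, while their genotypes keep the structure of the true
#' origin - emulating mislabelling or historical long-distance seed
#' transfer. Translocated units are disjoint.
#'
#' @param samples sample table from \code{\link{simulateLandscape}}.
#' @param truth matching \code{SimTruth}.
#' @param n_individuals individuals to translocate (from non-translocated
#'   sites).
#' @param n_groups whole sites to translocate.
#' @param min_km minimum displacement.
#' @param seed integer seed.
#' @return list with the modified \code{samples} and updated \code{truth}.
#' @export
injectTranslocations <- function(samples, truth, n_individuals = 5L,
                                 n_groups = 2L, min_km = 1000, seed = 1L) {
  withSeed(seed, {
    sites <- truth$sites
    D <- outer(seq_len(nrow(sites)), seq_len(nrow(sites)),
               function(i, j) haversineKm(sites$lat[i], sites$lon[i],
                                          sites$lat[j], sites$lon[j]))
    recs <- list()
    movedGroups <- character(0)
    hasTarget <- apply(D >= min_km, 1, any)
    if (!any(hasTarget))
      stop("injectTranslocations: no site >= ", min_km, " km away")
    pickTarget <- function(fromIdx) {
      elig <- which(D[fromIdx, ] >= min_km)
      if (!length(elig))
        stop("injectTranslocations: no site >= ", min_km, " km away")
      sample(elig, 1L)
    }
    if (n_groups > 0L) {
      cand <- which(hasTarget)
      if (length(cand) < n_groups)
        stop("injectTranslocations: not enough sites with a target >= ",
             min_km, " km away")
      grpIdx <- if (length(cand) == 1L) cand else sample(cand, n_groups)
      movedGroups <- sites$site_id[grpIdx]
      for (gi in grpIdx) {
        ti <- pickTarget(gi)
        members <- which(samples$group_id == sites$site_id[gi])
        recs[[length(recs) + 1L]] <- data.frame(
          id = c(sites$site_id[gi], samples$sample_id[members]),
          scope = c("group", rep("group_member", length(members))),
          true_lat = sites$lat[gi], true_lon = sites$lon[gi],
          recorded_lat = sites$lat[ti], recorded_lon = sites$lon[ti],
          stringsAsFactors = FALSE)
        samples$lat[members] <- sites$lat[ti]
        samples$lon[members] <- sites$lon[ti]
      }
    }
    if (n_individuals > 0L) {
      pool <- which(!(samples$group_id %in% movedGroups) &
                      hasTarget[match(samples$group_id, sites$site_id)])
      if (length(pool) < n_individuals)
        stop("injectTranslocations: not enough non-translocated candidates")
      sel <- sample(pool, n_individuals)
      for (i in sel) {
        fromIdx <- match(samples$group_id[i], sites$site_id)
        ti <- pickTarget(fromIdx)
        recs[[length(recs) + 1L]] <- data.frame(
          id = samples$sample_id[i], scope = "individual",
          true_lat = samples$lat[i], true_lon = samples$lon[i],
          recorded_lat = sites$lat[ti], recorded_lon = sites$lon[ti],
          stringsAsFactors = FALSE)
        samples$lat[i] <- sites$lat[ti]
        samples$lon[i] <- sites$lon[ti]
      }
    }
    truth$translocations <- if (length(recs)) do.call(rbind, recs)
      else truth$translocations
    list(samples = samples, truth = truth)
  })
}

#' Hardy-Weinberg consistency of simulated genotypes
#'
#' Per site and nuclear SNP, compares the observed heterozygote count with
#' the binomial expectation at 2 p (1 - p) from the true simulated
#' frequency; reports the fraction of site x SNP cells whose observed count
#' lies inside the central 95% binomial interval, and the mean absolute
#' deviation of observed from expected heterozygosity.
#'
#' @param geno simulated \linkS4class{GenoMatrix}.
#' @param samples matching sample table.
#' @param truth matching \code{SimTruth}.
#' @return list: coverage, mean_abs_dev, n_cells.
#' @export
hweConsistencyCheck <- function(geno, samples, truth) {
  V <- genotypes(geno)
  nuc <- which(truth$ploidy == "nuclear")
  siteOf <- truth$site_of
  cov <- 0L; tot <- 0L; devSum <- 0
  for (s in seq_len(nrow(truth$sites))) {
    rows <- which(siteOf == s)
    sub <- V[rows, nuc, drop = FALSE]
    nCalls <- colSums(!is.na(sub))
    het <- colSums(sub == 0.5, na.rm = TRUE)
    pe <- 2 * truth$site_freq[s, nuc] * (1 - truth$site_freq[s, nuc])
    ok <- nCalls > 0
    lo <- stats::qbinom(0.025, nCalls[ok], pe[ok])
    hi <- stats::qbinom(0.975, nCalls[ok], pe[ok])
    cov <- cov + sum(het[ok] >= lo & het[ok] <= hi)
    tot <- tot + sum(ok)
    devSum <- devSum + sum(abs(het[ok] / nCalls[ok] - pe[ok]))
  }
  list(coverage = cov / tot, mean_abs_dev = devSum / tot, n_cells = tot)
}

#' Moran-style spatial autocorrelation of site allele frequencies
#'
#' Inverse-distance-weighted Moran's I of the observed per-site allele
#' frequencies, averaged over SNPs; positive under isolation by distance,
#' near zero for spatially unstructured data.
#'
#' @param geno a \linkS4class{GenoMatrix}.
#' @param samples matching sample table (groups = sites).
#' @return mean Moran's I across SNPs.
#' @export
spatialAutocorrelation <- function(geno, samples) {
  V <- genotypes(recodeGeno(geno, "unit"))
  bySite <- split(seq_len(nrow(V)), samples$group_id)
  Fq <- t(vapply(bySite, function(r) colMeans(V[r, , drop = FALSE], na.rm = TRUE),
                 numeric(ncol(V))))
  loc <- do.call(rbind, lapply(bySite, function(r)
    c(samples$lat[r[1]], samples$lon[r[1]])))
  nS <- nrow(Fq)
  D <- outer(seq_len(nS), seq_len(nS), function(i, j)
    haversineKm(loc[i, 1], loc[i, 2], loc[j, 1], loc[j, 2]))
  W <- 1 / pmax(D, 1)
  diag(W) <- 0
  S0 <- sum(W)
  moran <- vapply(seq_len(ncol(Fq)), function(j) {
    z <- Fq[, j] - mean(Fq[, j])
    denom <- sum(z^2)
    if (denom < 1e-12) return(NA_real_)
    (nS / S0) * sum(W * outer(z, z)) / denom
  }, numeric(1))
  mean(moran, na.rm = TRUE)
}

#' Write simulation truth as JSON
#'
#' @param truth a \code{SimTruth}.
#' @param path output JSON path.
#' @export
writeSimTruth <- function(truth, path) {
  jsonlite::write_json(
    list(surface = truth$surface, sites = truth$sites,
         translocations = truth$translocations),
    path, dataframe = "columns", digits = 10)
  invisible(path)
}
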