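#' IQR-based outlier threshold
#'
#' Q3 + multiplier * (Q3 - Q1) with quartiles by linear interpolation
#' (quantile type 7). The multiplier is 1.5 for group outliers and 3.0 for
#' individual outliers.
#'
#' @param values numeric vector (>= 4 values).
#' @param multiplier IQR multiplier.
#' @return the threshold (scalar).
#' @export
iqrThreshold <- function(values, multiplier) {
  if (length(values) < 4L) stop("iqrThreshold: need >= 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + multiplier * (q[2] - q[1])
}

#' Individual-level outlier detection
#'
#' Flags samples whose distance between given and predicted location exceeds
#' both the IQR threshold over all individual distances (Q3 + 3 IQR) and
#' their own method-specific 95% distance radius.
#'
#' @param report an \code{EvalReport}.
#' @param relative apply the IQR rule to relative errors instead of raw km
#'   distances (the r95 gate always uses km).
#' @return data.frame of flagged individuals (possibly 0 rows) with the
#'   intermediate quantities; the threshold is stored in
#'   \code{attr(, "threshold")}.
#' @export
detectIndividualOutliers <- function(report, relative = FALSE) {
  ps <- report$per_sample
  vals <- if (relative) ps$relative_error else ps$distance_km
  thr <- iqrThreshold(vals, 3.0)
  flag <- vals > thr & ps$distance_km > ps$r95_km
  out <- data.frame(sample_id = ps$sample_id[flag],
                    group_id = ps$group_id[flag],
                    distance_km = ps$distance_km[flag],
                    threshold = rep(thr, sum(flag)),
                    r95_km = ps$r95_km[flag],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "scale") <- if (relative) "relative" else "km"
  out
}

#' Group-level outlier detection
#'
#' Per group: the mean of the members' predicted coordinates, its Haversine
#' distance from the group's given location (mean of the members' passport
#' coordinates) and the mean member r95. Groups are flagged when the group
#' distance exceeds both the IQR threshold over group distances (Q3 + 1.5
#' IQR) and the mean r95.
#'
#' @param report an \code{EvalReport}.
#' @param relative apply the IQR rule to group distance / max pairwise
#'   distance instead of raw km.
#' @return list: \code{groups} (all groups with their statistics),
#'   \code{outliers} (flagged rows), \code{threshold}.
#' @export
detectGroupOutliers <- function(report, relative = FALSE) {
  ps <- report$per_sample
  if (length(unique(ps$group_id)) < 4L)
    stop("detectGroupOutliers: need >= 4 groups")
  agg <- do.call(rbind, lapply(split(ps, ps$group_id), function(g) {
    data.frame(group_id = g$group_id[1],
               n = nrow(g),
               given_lat = mean(g$true_lat), given_lon = mean(g$true_lon),
               pred_lat = mean(g$pred_lat), pred_lon = mean(g$pred_lon),
               mean_r95_km = mean(g$r95_km),
               stringsAsFactors = FALSE)
  }))
  agg$distance_km <- haversineKm(agg$given_lat, agg$given_lon,
                                 agg$pred_lat, agg$pred_lon)
  maxPair <- report$summary$max_pairwise_km
  vals <- if (relative) agg$distance_km / maxPair else agg$distance_km
  thr <- iqrThreshold(vals, 1.5)
  flag <- vals > thr & agg$distance_km > agg$mean_r95_km
  rownames(agg) <- NULL
  list(groups = agg, outliers = agg[flag, , drop = FALSE], threshold = thr,
       scale = if (relative) "relative" else "km")
}

#' Write outlier reports as TSVs
#'
#' @param indOut data.frame from \code{\link{detectIndividualOutliers}}.
#' @param grpOut list from \code{\link{detectGroupOutliers}}.
#' @param indPath,grpPath output TSV paths.
#' @export
writeOutlierReport <- function(indOut, grpOut, indPath, grpPath) {
  utils::write.table(indOut, indPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  grp <- grpOut$outliers
  grp$threshold <- rep(grpOut$threshold, nrow(grp))
  utils::write.table(grp, grpPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
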