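#' Validate a sample table
#'
#' Checks the passport table: unique sample ids, finite coordinates in valid
#' decimal-degree ranges, and non-empty groups.
#'
#' @param samples data.frame with columns sample_id, group_id, lat, lon.
#' @return the validated data.frame (character ids, numeric coordinates).
#' @export
validateSampleTable <- function(samples) {
  need <- c("sample_id", "group_id", "lat", "lon")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$group_id <- as.character(samples$group_id)
  samples$lat <- as.numeric(samples$lat)
  samples$lon <- as.numeric(samples$lon)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(samples$lat) | !is.finite(samples$lon) |
                 abs(samples$lat) > 90 | abs(samples$lon) > 180)
  if (length(bad))
    stop("latitude/longitude out of range or non-finite for row(s): ",
         paste(utils::head(samples$sample_id[bad], 5), collapse = ", "))
  rownames(samples) <- NULL
  samples
}

#' Read a sample (passport) table
#'
#' @param path TSV or CSV file with header columns sample_id, group_id, lat,
#'   lon; coordinates in decimal degrees.
#' @param dialect \code{"tsv"} or \code{"csv"} (default guessed from the file
#'   extension).
#' @return validated sample data.frame.
#' @export
readSampleTable <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validateSampleTable(df)
}

#' Read coded genotypes
#'
#' Two on-disk formats are supported. \code{coded_table} is a TSV/CSV whose
#' first column is the sample id and whose remaining columns hold 0/0.5/1/NA
#' coded genotypes (1 = homozygote reference). \code{vcf} reads GT fields of
#' biallelic records from a VCF: 0/0 -> 1, 0/1 -> 0.5, 1/1 -> 0, ./. -> NA;
#' haploid GT (0 or 1, e.g. plastid markers) flags the marker as plastid and
#' maps 0 -> 1, 1 -> 0. Multi-allelic VCF records are skipped with a warning.
#'
#' @param path input file.
#' @param format \code{"coded_table"} or \code{"vcf"}.
#' @param ploidy optional character vector (or named vector by marker id) of
#'   per-marker flags overriding the default all-nuclear for coded tables.
#' @return a \linkS4class{GenoMatrix}.
#' @export
readGenotypes <- function(path, format = c("coded_table", "vcf"),
                          ploidy = NULL) {
  format <- match.arg(format)
  if (format == "coded_table") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    bad <- m[!is.na(m) & !(m %in% VALID_GENO_VALUES)]
    if (length(bad))
      stop("coded_table contains value(s) outside {0, 0.5, 1, NA}: ",
           paste(utils::head(unique(bad), 5), collapse = ", "))
    if (is.null(ploidy)) ploidy <- rep("nuclear", ncol(m))
    if (!is.null(names(ploidy))) ploidy <- unname(ploidy[colnames(m)])
    return(GenoMatrix(m, ploidy = ploidy))
  }
  readGenotypesVcf(path)
}

# GT-only VCF parsing; biallelic records only, haploid GT => plastid flag.
readGenotypesVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")   # markers x samples
  ids <- paste0(vcfR::getCHROM(vcf), ":", vcfR::getPOS(vcf))
  id_col <- vcfR::getID(vcf)
  ids <- ifelse(is.na(id_col) | id_col == ".", ids, id_col)
  gt_clean <- gsub("\\|", "/", gt)
  map <- c("0/0" = 1, "0/1" = 0.5, "1/0" = 0.5, "1/1" = 0,
           "0" = 1, "1" = 0)
  vals <- map[gt_clean]
  m <- matrix(vals, nrow = nrow(gt), ncol = ncol(gt))
  haploid <- apply(gt_clean, 1, function(r) {
    r <- r[!is.na(r) & r != "./." & r != "."]
    length(r) > 0 && all(r %in% c("0", "1"))
  })
  m <- t(m)                                      # samples x markers
  rownames(m) <- colnames(gt)
  colnames(m) <- make.unique(ids)
  GenoMatrix(m, ploidy = ifelse(haploid, "plastid", "nuclear"))
}

#' Write / read a prediction table
#'
#' TSV with one row per sample; the diagnostics list-column is serialised as
#' a JSON column.
#'
#' @param preds prediction data.frame as returned by the assigners.
#' @param path output TSV path.
#' @export
writePredictions <- function(preds, path) {
  out <- preds[setdiff(names(preds), "extras")]
  out$diagnostics <- vapply(seq_len(nrow(preds)), function(i) {
    ex <- if ("extras" %in% names(preds)) preds$extras[[i]] else NULL
    if (is.null(ex)) "{}" else
      as.character(jsonlite::toJSON(ex, auto_unbox = TRUE, digits = 10))
  }, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if ("diagnostics" %in% names(df)) {
    df$extras <- lapply(df$diagnostics, function(s) jsonlite::fromJSON(s))
    df$diagnostics <- NULL
  }
  df
}

#' Serialise a grid to TSV for inspection
#'
#' @param grid a \linkS4class{GeoGrid}.
#' @param path output TSV path.
#' @export
writeGrid <- function(grid, path) {
  utils::write.table(gridCells(grid)[, c("cell_id", "center_lat", "center_lon")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a GenoMatrix as a coded table
#'
#' Inverse of \code{readGenotypes(format = "coded_table")}; the companion
#' marker metadata TSV (marker_id, ploidy_flag) is written when
#' \code{metaPath} is given.
#'
#' @param geno a \linkS4class{GenoMatrix}.
#' @param path output TSV path.
#' @param metaPath optional marker metadata TSV path.
#' @export
writeGenotypes <- function(geno, path, metaPath = NULL) {
  v <- genotypes(geno)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metaPath))
    utils::write.table(
      data.frame(marker_id = colnames(v), ploidy_flag = geno@ploidy),
      metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample table as TSV
#' @param samples validated sample data.frame.
#' @param path output TSV path.
#' @export
writeSampleTable <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
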