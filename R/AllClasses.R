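#' @import methods
NULL

VALID_GENO_VALUES <- c(0, 0.5, 1)
PLOIDY_LEVELS <- c("nuclear", "plastid")

#' GenoMatrix: coded SNP genotypes for georeferenced individuals
#'
#' Individuals x markers matrix of unit-interval coded biallelic genotypes:
#' 1 = homozygote reference allele, 0.5 = heterozygote, 0 = homozygote
#' alternative allele, \code{NA} = missing call. Plastid (chloroplast /
#' mitochondrial) markers behave as haploid and are stored as pseudo-diploid
#' homozygotes (0 or 1, never 0.5).
#'
#' @slot values numeric matrix with unique rownames (sample ids) and unique
#'   colnames (marker ids); entries in \{0, 0.5, 1, NA\}.
#' @slot ploidy character vector, one of \code{"nuclear"} or \code{"plastid"}
#'   per marker.
#' @exportClass GenoMatrix
setClass("GenoMatrix",
  representation(values = "matrix", ploidy = "character"),
  validity = function(object) {
    v <- object@values
    msgs <- character()
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msgs <- c(msgs, "sample ids (rownames) must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msgs <- c(msgs, "marker ids (colnames) must be present and unique")
    vv <- v[!is.na(v)]
    if (length(vv) && !all(vv %in% VALID_GENO_VALUES))
      msgs <- c(msgs, "non-missing genotype values must be 0, 0.5 or 1")
    if (length(object@ploidy) != ncol(v))
      msgs <- c(msgs, "ploidy must have one entry per marker")
    if (!all(object@ploidy %in% PLOIDY_LEVELS))
      msgs <- c(msgs, "ploidy entries must be 'nuclear' or 'plastid'")
    pl <- object@ploidy == "plastid"
    if (any(pl)) {
      pv <- v[, pl, drop = FALSE]
      if (any(pv == 0.5, na.rm = TRUE))
        msgs <- c(msgs, "plastid markers must not contain heterozygote calls (0.5)")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a GenoMatrix
#'
#' @param values numeric matrix of coded genotypes (individuals x markers)
#'   with rownames and colnames.
#' @param ploidy character vector of per-marker ploidy flags
#'   (\code{"nuclear"}/\code{"plastid"}); recycled default is all-nuclear.
#' @return A validated \linkS4class{GenoMatrix}.
#' @examples
#' m <- matrix(c(1, 0.5, 0, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' GenoMatrix(m)
#' @export
GenoMatrix <- function(values, ploidy = rep("nuclear", ncol(values))) {
  new("GenoMatrix", values = values, ploidy = ploidy)
}

#' EncodedGeno: numeric genotype encoding for a learning method
#'
#' A recoded (and optionally mean-imputed) view of a \linkS4class{GenoMatrix}.
#' The \code{unit} scheme keeps the 0/0.5/1 coding; the \code{signed} scheme
#' maps it affinely to 1/0/-1 (x -> 2x - 1).
#'
#' @slot values numeric matrix (individuals x markers).
#' @slot scheme \code{"unit"} or \code{"signed"}.
#' @slot missingPolicy \code{"keep_na"} or \code{"mean_imputed"}.
#' @slot columnMeans column means recorded at imputation time (length 0 when
#'   not imputed).
#' @slot ploidy per-marker ploidy flags carried through from the source.
#' @exportClass EncodedGeno
setClass("EncodedGeno",
  representation(values = "matrix", scheme = "character",
                 missingPolicy = "character", columnMeans = "numeric",
                 ploidy = "character"),
  validity = function(object) {
    msgs <- character()
    if (!object@scheme %in% c("unit", "signed"))
      msgs <- c(msgs, "scheme must be 'unit' or 'signed'")
    if (!object@missingPolicy %in% c("keep_na", "mean_imputed"))
      msgs <- c(msgs, "missingPolicy must be 'keep_na' or 'mean_imputed'")
    if (object@missingPolicy == "mean_imputed" && anyNA(object@values))
      msgs <- c(msgs, "mean_imputed matrix must not contain missing values")
    if (length(object@ploidy) != ncol(object@values))
      msgs <- c(msgs, "ploidy must have one entry per marker")
    if (length(msgs)) msgs else TRUE
  }
)

#' GeoGrid: fixed geographic assignment lattice
#'
#' Regular latitude/longitude grid spanning exactly the min-max coordinate
#' range of the training samples, with a cell edge length expressed in km
#' (latitude step cell_km / 111.32 degrees; longitude step additionally
#' divided by the cosine of the mean training latitude). Cells are half-open
#' \code{[low, high)} except the last cell per axis, which is closed.
#'
#' @slot cellKm cell edge length in km.
#' @slot latEdges,lonEdges monotone degree vectors bounding the cells.
#' @slot cells data.frame with cell_id, center_lat, center_lon, lat_bin,
#'   lon_bin.
#' @slot membership named character vector mapping training sample_id to
#'   cell_id.
#' @exportClass GeoGrid
setClass("GeoGrid",
  representation(cellKm = "numeric", latEdges = "numeric", lonEdges = "numeric",
                 cells = "data.frame", membership = "character"),
  validity = function(object) {
    msgs <- character()
    if (is.unsorted(object@latEdges) || is.unsorted(object@lonEdges))
      msgs <- c(msgs, "grid edges must be monotone increasing")
    if (object@cellKm <= 0) msgs <- c(msgs, "cellKm must be positive")
    need <- c("cell_id", "center_lat", "center_lon", "lat_bin", "lon_bin")
    if (!all(need %in% names(object@cells)))
      msgs <- c(msgs, "cells must have cell_id, center_lat, center_lon, lat_bin, lon_bin")
    if (length(msgs)) msgs else TRUE
  }
)

#' Assigner: common interface of the continuous assignment methods
#'
#' Virtual parent of the five method classes. Every assigner can be trained on
#' a (\linkS4class{GenoMatrix}, sample table) pair and asked to predict the
#' geographic origin of held-out genotypes; \code{\link{looCrossval}} drives
#' the leave-one-out protocol over any of them.
#'
#' @slot method short method label used in prediction tables.
#' @exportClass Assigner
setClass("Assigner", representation("VIRTUAL", method = "character"))

#' @rdname nnAssigner
#' @exportClass NNAssigner
setClass("NNAssigner", contains = "Assigner",
         representation(k = "integer", radiusPolicy = "character"))

#' @rdname gblupAssigner
#' @exportClass GBLUPAssigner
setClass("GBLUPAssigner", contains = "Assigner")

#' @rdname gprDirectAssigner
#' @exportClass GPRDirectAssigner
setClass("GPRDirectAssigner", contains = "Assigner",
         representation(hyperparams = "list", search = "list"))

#' @rdname gprGridAssigner
#' @exportClass GPRGridAssigner
setClass("GPRGridAssigner", contains = "Assigner",
         representation(cellKm = "numeric", epochs = "integer", lr = "numeric",
                        eps = "numeric"))

#' @rdname dlAssigner
#' @exportClass DLAssigner
setClass("DLAssigner", contains = "Assigner", representation(config = "list"))
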