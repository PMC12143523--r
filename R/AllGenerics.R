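#' Accessors for GeoAssign classes
#'
#' @param object a \linkS4class{GenoMatrix}, \linkS4class{EncodedGeno} or
#'   \linkS4class{GeoGrid}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("markerPloidy", function(object) standardGeneric("markerPloidy"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(object) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("encodingScheme", function(object) standardGeneric("encodingScheme"))

#' @rdname accessors
#' @export
setGeneric("missingPolicy", function(object) standardGeneric("missingPolicy"))

#' @rdname accessors
#' @export
setGeneric("columnMeans", function(object) standardGeneric("columnMeans"))

#' @rdname accessors
#' @export
setGeneric("gridCells", function(object) standardGeneric("gridCells"))

#' @rdname accessors
#' @export
setGeneric("cellMembership", function(object) standardGeneric("cellMembership"))

#' Predict geographic origin of new genotypes
#'
#' Trains the assignment method on the training individuals and predicts the
#' origin of the test individuals. All five methods return the shared
#' prediction table (one row per test sample) with a method-specific
#' uncertainty converted to a 95% distance radius \code{r95_km}.
#'
#' @param object an \linkS4class{Assigner}.
#' @param geno training \linkS4class{GenoMatrix}.
#' @param samples training sample table (sample_id, group_id, lat, lon).
#' @param newGeno \linkS4class{GenoMatrix} of test individuals (same markers).
#' @param seed integer seed controlling any stochastic component.
#' @param ... passed to methods.
#' @return data.frame with columns sample_id, method, pred_lat, pred_lon,
#'   sd_lat, sd_lon, r95_km and a list-column \code{extras} of per-sample
#'   diagnostics.
#' @export
setGeneric("assignOrigin",
  function(object, geno, samples, newGeno, seed = 1L, ...)
    standardGeneric("assignOrigin"))

#' Internal leave-one-out machinery of an assigner
#'
#' \code{precomputeState} prepares everything shareable across leave-one-out
#' folds (encodings, distance/kinship matrices, tuned hyperparameters);
#' \code{predictFold} produces the prediction for one held-out individual.
#' Exported so new assigners can plug into \code{\link{looCrossval}}.
#'
#' @param object an \linkS4class{Assigner}.
#' @param geno a \linkS4class{GenoMatrix} over all individuals.
#' @param samples sample table aligned with \code{geno}.
#' @param seed integer seed.
#' @param state list returned by \code{precomputeState}.
#' @param testIdx row index of the held-out individual.
#' @name loo-internals
#' @export
setGeneric("precomputeState",
  function(object, geno, samples, seed = 1L) standardGeneric("precomputeState"))

#' @rdname loo-internals
#' @export
setGeneric("predictFold",
  function(object, state, testIdx, seed = 1L) standardGeneric("predictFold"))
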