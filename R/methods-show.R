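#' @rdname accessors
#' @export
setMethod("genotypes", "GenoMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("genotypes", "EncodedGeno", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("markerPloidy", "GenoMatrix", function(object) {
  stats::setNames(object@ploidy, colnames(object@values))
})

#' @rdname accessors
#' @export
setMethod("markerPloidy", "EncodedGeno", function(object) {
  stats::setNames(object@ploidy, colnames(object@values))
})

#' @rdname accessors
#' @export
setMethod("nSamples", "GenoMatrix", function(object) nrow(object@values))

#' @rdname accessors
#' @export
setMethod("nSamples", "EncodedGeno", function(object) nrow(object@values))

#' @rdname accessors
#' @export
setMethod("nMarkers", "GenoMatrix", function(object) ncol(object@values))

#' @rdname accessors
#' @export
setMethod("nMarkers", "EncodedGeno", function(object) ncol(object@values))

#' @rdname accessors
#' @export
setMethod("encodingScheme", "EncodedGeno", function(object) object@scheme)

#' @rdname accessors
#' @export
setMethod("missingPolicy", "EncodedGeno", function(object) object@missingPolicy)

#' @rdname accessors
#' @export
setMethod("columnMeans", "EncodedGeno", function(object) object@columnMeans)

#' @rdname accessors
#' @export
setMethod("gridCells", "GeoGrid", function(object) object@cells)

#' @rdname accessors
#' @export
setMethod("cellMembership", "GeoGrid", function(object) object@membership)

setMethod("show", "GenoMatrix", function(object) {
  v <- object@values
  miss <- mean(is.na(v))
  cat("GenoMatrix:", nrow(v), "samples x", ncol(v), "markers\n")
  cat(sprintf("  plastid markers: %d; missing calls: %.2f%%\n",
              sum(object@ploidy == "plastid"), 100 * miss))
})

setMethod("show", "EncodedGeno", function(object) {
  cat("EncodedGeno:", nrow(object@values), "x", ncol(object@values),
      sprintf("(scheme=%s, missing=%s)\n", object@scheme, object@missingPolicy))
})

setMethod("show", "GeoGrid", function(object) {
  cat(sprintf("GeoGrid: %d x %d cells of %.1f km (%d occupied)\n",
              length(object@latEdges) - 1L, length(object@lonEdges) - 1L,
              object@cellKm, length(unique(object@membership))))
})

setMethod("show", "Assigner", function(object) {
  cat("<", class(object), "> method=", object@method, "\n", sep = "")
})
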