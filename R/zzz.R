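#' @useDynLib GeoAssign, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd median quantile cor rnorm runif rbinom qbinom plogis
#' @importFrom utils read.table write.table combn head packageVersion
#' @importFrom graphics hist
NULL
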