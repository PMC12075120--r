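#' @useDynLib colrhythm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(".", ".I", "row0", "pre", "post", "w", "rec", "idx",
                         "receptor", "plastic", "weight"))
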