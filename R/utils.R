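#' @keywords internal
"_PACKAGE"

## Internal memo environment for canonical SMILES (OpenBabel round-trips are
## ~5 ms each; screening and dataset construction hit the same strings often).
.pz_cache <- new.env(parent = emptyenv())

pz_msg <- function(...) message("[pairzyme] ", ...)

#' Derive a reproducible child seed from a base seed and a label
#'
#' Every stochastic step of the pipeline draws from its own child seed so that
#' components can be re-run in isolation without replaying the whole stream.
#' Kept below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param label character tag naming the consumer.
#' @return An integer seed.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

## Simple numeric checksum of a parameter list: enough to certify that a
## frozen parameter set was not touched by training.
param_checksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  sum(v * seq_along(v) %% 97) + sum(abs(v))
}
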