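#' @useDynLib sdamll, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois quantile sd runif predict
#' @importFrom utils write.table read.table head modifyList
NULL

sigmoid <- function(t) 1 / (1 + exp(-t))

#' Derive a named sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed, split into named
#' streams (e.g. `"init"`, `"corrupt"`, `"shuffle"`, `"folds"`, `"simulate"`)
#' so that individual stages are independently reproducible.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name.
#' @return An integer in `[1, 2^31 - 2]`, deterministic in both arguments.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer(((abs(as.numeric(seed)) %% 1000003) * 20011 + h * 7919) %%
               2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable numeric formatting used for all TSV output so reruns are
# byte-identical: 9 significant digits, no scientific notation surprises.
format_num <- function(x) formatC(x, digits = 9, format = "g")
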