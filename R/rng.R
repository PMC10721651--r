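#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded helpers do not perturb the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a named RNG stream seed from a master seed
#'
#' All randomness in the synthetic generator flows from one master seed,
#' split into independent named streams (waveforms, spikes, behavior, ...)
#' so each stage is reproducible in isolation.  Results are kept below
#' 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name.
#' @return An integer seed.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}
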