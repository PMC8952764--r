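#' Derive a stream-specific random seed
#'
#' Each stochastic operation draws from its own generator, seeded
#' deterministically from the user seed and a short stream label so stages are
#' independently reproducible. The derivation is a position-dependent
#' polynomial hash: starting from the user seed, `h <- (h * 69069 + code) mod
#' (2^31 - 1)` over the label's UTF-8 codes, so permuted labels hash apart.
#'
#' @param seed Integer user seed.
#' @param stream Character stream label (e.g. `"substitutions"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stream))
    h <- (h * 69069 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded for one stream.
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

# round half away from zero (Table-style percentage rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# round-half-even at 2 decimals, for comparisons with printed coefficients
round2 <- function(x) round(x, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
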