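# Internal helpers: classed error conditions and RNG hygiene.

ts_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "trapscreen_error")))
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a deterministic 31-bit substream seed from a base seed and an offset.
substream_seed <- function(seed, offset) {
  (as.double(seed) * 48271 + offset * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format p-like values for delimited output: scientific, >= 3 significant
# figures, with an explicit sentinel below the rendering floor so that
# underflow is never written as a silent "0".
format_pvalue <- function(p, digits = 3) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < 1e-300, "<1e-300",
                       formatC(p, format = "e", digits = digits - 1)))
  out
}
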