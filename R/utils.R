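# Internal utilities: reproducible seeding and small helpers.

#' Derive a child seed from a base seed and a stream label
#'
#' All randomness in the package flows from one integer seed. Independent
#' generator calls (one per plot, per band, per replicate) use child seeds
#' derived deterministically from the base seed and a character label, so
#' plots can be generated in any order (or in parallel) with identical
#' results.
#'
#' @param seed base integer seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  label <- paste(c(format(seed, scientific = FALSE), as.character(list(...))),
                 collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double-int range
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stop with a classed condition so callers/tests can match on class.
stop_pnc <- function(class, msg, ...) {
  stop(structure(class = c(class, "pncfusion_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
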