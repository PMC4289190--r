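`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers can distinguish failure modes programmatically.
zs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "zebrascreen_error", "error")))
}

#' Derive a reproducible stream seed from a base seed and an identifier
#'
#' Hashes a base seed together with an arbitrary identifier (e.g. an image
#' name) into a 31-bit integer seed, so that every image, tree or tuning run
#' gets its own reproducible random stream and per-image results do not
#' depend on processing order.
#'
#' @param seed integer base seed.
#' @param id identifier (coerced to character) naming the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, id) {
  s <- paste0(as.integer(seed), ":", paste(as.character(id), collapse = ","))
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
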