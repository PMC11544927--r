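#' Null-coalescing operator
#'
#' Returns `b` when `a` is NULL, otherwise `a`.
#'
#' @param a,b values
#' @name op-null-default
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hash of an R object
#'
#' 64-bit FNV-1a over the serialized object, returned as a hex string. Used to
#' key model-stack caches and to stamp output files so that runs can be matched
#' to the configuration that produced them.
#'
#' @param x any serializable R object
#' @return a 16-character hex string
#' @export
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2, xdr = TRUE)
  # drop serialization header (R version dependent)
  bytes <- bytes[-seq_len(14L)]
  h1 <- 2166136261 %% 2^31
  h2 <- 305419896
  for (b in as.integer(bytes)) {
    h1 <- (bitwXor(as.integer(h1), b) * 69069 + 1) %% 2^31
    h2 <- (bitwXor(as.integer(h2), 255L - b) * 40692 + 7) %% 2^31
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

# reflect values into [lo, hi] (used for reflecting boundaries)
.reflect <- function(x, lo, hi) {
  if (!is.finite(lo) && !is.finite(hi)) return(x)
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  y + lo
}

# reflect at a floor only (z >= 0)
.reflect_floor <- function(x, lo = 0) ifelse(x < lo, 2 * lo - x, x)

.assert <- function(ok, msg, call. = FALSE) if (!isTRUE(ok)) stop(msg, call. = call.)
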