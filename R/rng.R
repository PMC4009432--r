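#' Derive a labelled stream seed from a root seed
#'
#' Every stochastic operation in the package draws from a stream derived
#' from one root seed plus a sequence of purpose labels (for example
#' `"hard-locations"`, `"data"`, `"cues"`, `"ties"`).  Two streams with
#' different labels are decorrelated, and every experiment cell can be
#' reproduced in isolation without replaying the operations before it.
#'
#' The derivation is a 31-bit multiplicative hash (base-31 Horner scheme
#' over the UTF-8 bytes of the labels, modulo the Mersenne prime
#' 2^31 - 1), so the result is always a valid `set.seed()` argument.
#'
#' @param root integer root seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' stream_seed(1, "hard-locations")
#' stream_seed(1, "cues", 200, 3)
#' @export
stream_seed <- function(root, ...) {
  stopifnot(length(root) == 1, is.finite(root))
  m <- 2147483647
  h <- as.double(abs(as.integer(root))) %% m
  labels <- paste(vapply(list(...), function(x) paste(as.character(x),
    collapse = ","), character(1)), collapse = "/")
  for (b in utf8ToInt(labels)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed means "use the current global RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
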