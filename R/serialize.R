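#' Save a memory store to a binary container file
#'
#' Format (little-endian throughout): the 4-byte magic `SDM1`; six 32-bit
#' signed integers (format version, n, H, r, seed, write count); the
#' address matrix bit-packed row-major (padded to a whole byte); the
#' counter matrix row-major as 32-bit signed integers.  Saving refuses if
#' any counter magnitude would overflow 32 bits.
#'
#' @param store an [sdm()] store.
#' @param path file path.
#' @return `path`, invisibly.
#' @seealso [load_sdm()]
#' @export
save_sdm <- function(store, path) {
  stopifnot(inherits(store, "sdm"))
  if (max(abs(store$counters)) > .Machine$integer.max) {
    stop("counter overflow risk: magnitudes exceed 32-bit signed range")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SDM1"), con)
  writeBin(as.integer(c(1L, store$n, store$H, store$r, store$seed,
    store$n_writes)), con, size = 4L, endian = "little")
  bits <- as.logical(t(store$addresses))     # row-major bit order
  pad <- (-length(bits)) %% 8
  if (pad > 0) bits <- c(bits, rep(FALSE, pad))
  writeBin(packBits(bits, "raw"), con)
  writeBin(as.integer(t(store$counters)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Load a memory store from a binary container file
#'
#' Validates the magic number, format version and matrix dimensions
#' written by [save_sdm()].  The per-location write-load bookkeeping is
#' not part of the container and is reconstructed as unknown (zeros).
#'
#' @param path file path produced by [save_sdm()].
#' @return An [sdm()] store.
#' @export
load_sdm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "SDM1")) {
    stop("not an SDM container file (bad magic '", magic, "')")
  }
  hdr <- readBin(con, "integer", 6L, size = 4L, endian = "little")
  if (hdr[1] != 1L) stop("unsupported container version ", hdr[1])
  n <- hdr[2]; H <- hdr[3]; r <- hdr[4]
  if (n < 1 || H < 1 || r < 0 || r > n) stop("corrupt header dimensions")
  nbits <- as.double(H) * n
  nbytes <- ceiling(nbits / 8)
  raw <- readBin(con, "raw", nbytes)
  if (length(raw) < nbytes) stop("truncated address matrix")
  bits <- as.integer(rawToBits(raw))[seq_len(nbits)]
  counters <- readBin(con, "integer", H * n, size = 4L, endian = "little")
  if (length(counters) < H * n) stop("truncated counter matrix")
  store <- new.env(parent = emptyenv())
  store$n <- n; store$H <- H; store$r <- r
  store$seed <- hdr[5]
  store$addresses <- matrix(as.double(bits), nrow = H, ncol = n,
    byrow = TRUE)
  store$addr_ones <- rowSums(store$addresses)
  store$counters <- matrix(as.double(counters), nrow = H, ncol = n,
    byrow = TRUE)
  store$write_load <- numeric(H)
  store$n_writes <- hdr[6]
  store$tie_counter <- 0L
  class(store) <- "sdm"
  store
}
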