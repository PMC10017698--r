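## Internal helpers: hashing, seeds, small numerics.

# FNV-1a 32-bit over the UTF-8 bytes of a string. Used to fingerprint the
# ordered feature-name list embedded in trained models; implemented with
# split 16-bit multiplication so all intermediates stay below 2^53.
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- .bitxor32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.bitxor32 <- function(a, b) {
  # a < 2^32 (double), b < 256
  lo <- bitwXor(a %% 2147483648, b)
  a %/% 2147483648 * 2147483648 + lo
}

#' Fingerprint of an ordered feature-name list
#'
#' A short stable hash of the concatenated feature names, embedded in trained
#' models so that prediction can detect a schema mismatch.
#'
#' @param featureNames character vector of feature names, in order.
#' @return character(1) 8-hex-digit fingerprint.
#' @export
schemaFingerprint <- function(featureNames) {
  .fnv1a(paste(featureNames, collapse = "\x1f"))
}

# epsilon floor for denominators (per-recording mean/median, delta power)
.EPS_DENOM <- 1e-12

.guardDenominator <- function(x) pmax(x, .EPS_DENOM)

# next length with only factors 2, 3, 5 (fast FFT sizes)
.nextFast <- function(n) stats::nextn(n, c(2L, 3L, 5L))

.stopifnot1 <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
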