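#' @keywords internal
"_PACKAGE"

## Small shared helpers: argument checks, clamping, hashing.

stop_input <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_input(what, " contains non-finite values")
  invisible(x)
}

#' Clamp values into a closed interval
#'
#' Element-wise range cropping: values below `lo` become `lo`, values above
#' `hi` become `hi`. This is the range-crop primitive used both for the
#' singular-value re-projection of the 1x1 convolution weights and for the
#' chessboard-distance latent interpolation.
#'
#' @param x numeric vector/matrix/array.
#' @param lo,hi interval bounds (`lo <= hi`), scalars or objects
#'   broadcastable against `x`.
#' @return `x` with every element cropped into `[lo, hi]`.
#' @export
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Order-independent content hash of an R object (FNV-style over serialized
## bytes, vectorized). Used to tie a normal-hyperplane basis to the flow
## model that produced its latents.
object_hash <- function(x) {
  r <- serialize(x, connection = NULL, version = 3L)
  ## skip serialization header (R version stamp) so the hash depends on
  ## content only
  r <- r[-seq_len(14L)]
  v <- as.double(r)
  k <- length(v)
  ## two independent weighted checksums mod 2^26 (exact in doubles)
  w1 <- (seq_len(k) * 2654435761) %% 67108864
  w2 <- (seq_len(k) * 40503 + 12345) %% 67108864
  h1 <- sum((v + 1) * w1) %% 67108859
  h2 <- sum((v + 7) * w2) %% 67108837
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

## deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629)
}
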