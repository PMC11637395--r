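## The "normal hyperplane": the linear subspace of latent space spanned by
## the latent codes of the normal training images (together with the
## origin). Enhancement measures abnormality as distance from this subspace.

#' Build the normal-hyperplane basis from training latents
#'
#' Computes an orthonormal basis `Q` of the span of the training latent
#' codes via pivoted (thin) QR factorization. The numerical rank `r` is the
#' number of R-diagonal magnitudes above `rank_tol` times the largest, so
#' rank-deficient inputs (e.g. duplicated images) are reduced cleanly. The
#' subspace contains the origin by construction, as the span of points
#' rather than their affine hull.
#'
#' @param Z_training `d x n` matrix whose columns are training latent codes
#'   (`n < d`; with `n >= d` the projection would be the identity and
#'   enhancement would degenerate).
#' @param rank_tol relative threshold fixing the numerical rank
#'   (default 1e-10).
#' @param model optional [flow_model()] that produced the latents; its
#'   parameter hash is stored so enhancement can detect a model/basis
#'   mismatch.
#' @return an object of class `normal_basis`: orthonormal `Q` (`d x r`),
#'   rank `r`, `n_train`, `rank_tol`, and `model_hash` (or `NA`).
#' @export
build_hyperplane <- function(Z_training, rank_tol = 1e-10, model = NULL) {
  Z <- as.matrix(Z_training)
  check_finite(Z, "Z_training")
  d <- nrow(Z); n <- ncol(Z)
  if (n < 1L) stop_input("need at least one training latent")
  if (n >= d)
    stop_input(sprintf(
      "n_train (%d) must be smaller than the latent dimension (%d): ",
      n, d), "otherwise the hyperplane fills the whole space")
  qrz <- qr(Z, LAPACK = TRUE)
  rd <- abs(diag(qr.R(qrz)))
  r <- sum(rd > rank_tol * max(rd, .Machine$double.xmin))
  r <- max(r, 1L)
  Q <- qr.Q(qrz)[, seq_len(r), drop = FALSE]
  structure(list(
    Q = Q, r = r, n_train = n, rank_tol = rank_tol,
    model_hash = if (is.null(model)) NA_character_ else model_hash(model)
  ), class = "normal_basis")
}

#' Project a latent code onto the normal hyperplane
#'
#' Returns the perpendicular foot `z0 = Q (Q' z)`, the unique Euclidean-
#' nearest point of the hyperplane: the "virtually normalized" latent whose
#' image is the normal-appearance version of the input. The residual
#' `z - z0` is orthogonal to every basis vector.
#'
#' @param z_input latent vector of length `d`, or a `d x B` matrix.
#' @param basis a [build_hyperplane()] result.
#' @return the projection, with the shape of `z_input`.
#' @export
project_to_hyperplane <- function(z_input, basis) {
  stopifnot(inherits(basis, "normal_basis"))
  vec <- is.null(dim(z_input))
  z <- if (vec) matrix(z_input, ncol = 1L) else as.matrix(z_input)
  if (nrow(z) != nrow(basis$Q))
    stop_input(sprintf("latent length %d does not match the basis (%d)",
                       nrow(z), nrow(basis$Q)))
  z0 <- basis$Q %*% crossprod(basis$Q, z)
  if (vec) as.vector(z0) else z0
}

## hash of the flow parameters only (ignores loss history etc.)
model_hash <- function(model) object_hash(flow_params(model))

#' @export
print.normal_basis <- function(x, ...) {
  cat(sprintf(
    "Normal hyperplane: rank %d from %d training latents (dim %d), rank_tol %g\n",
    x$r, x$n_train, nrow(x$Q), x$rank_tol))
  if (!is.na(x$model_hash)) cat("  tied to model", x$model_hash, "\n")
  invisible(x)
}
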