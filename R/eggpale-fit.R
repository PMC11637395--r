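## The user-facing model: one fitting function returning a classed object
## with the usual methods. Fitting = train the coupling flow on normal
## images, then build the normal-hyperplane basis from their latent codes.

#' Fit the abnormal-lesion emphasizer
#'
#' Trains the invertible coupling-flow generative model on a set of
#' *normal* images ([train_flow()]) and builds the normal-hyperplane basis
#' from their latent codes ([build_hyperplane()]). The returned object is
#' everything enhancement needs; training images are not retained beyond
#' their latent codes.
#'
#' @param images normal training images in `[0, 255]` at model resolution:
#'   a list of square matrices, an `H x W x n` array, or a list of
#'   `phantom_record`s.
#' @param config a [flow_config()]; default the desk-scale preset.
#' @param rank_tol relative rank threshold for the hyperplane basis.
#' @param verbose print per-epoch training loss.
#' @return an object of class `eggpale` with components `flow`
#'   (the trained [flow_model()]), `basis` (the [build_hyperplane()]
#'   result), `config`, `n_train`, and `latents` (the training latent
#'   codes, `d x n`).
#' @examples
#' \donttest{
#' normals <- generate_normal(phantom_spec(seed = 7), 200)
#' fit <- eggpale_fit(normals)
#' case <- inject_nodules(generate_normal(phantom_spec(seed = 99), 1)[[1]],
#'                        nodule_spec(c(16, 9), diameter = 5, contrast = 30))
#' enhanced <- predict(fit, case$image)
#' }
#' @export
eggpale_fit <- function(images, config = flow_config_preset("desk"),
                        rank_tol = 1e-10, verbose = FALSE) {
  if (is.list(images) && length(images) && inherits(images[[1]],
                                                    "phantom_record"))
    images <- lapply(images, `[[`, "image")
  if (is.list(images) && !is.array(images))
    images <- simplify2array(images)
  model <- train_flow(flow_model(config), images, config, verbose = verbose)
  n <- dim(images)[3]
  d <- latent_layout(model)$d
  if (n >= d)
    stop_input(sprintf(
      "need fewer training images (%d) than latent dimensions (%d) for the ",
      n, d), "normal hyperplane to be a proper subspace")
  ## deterministic latents (bin-center dequantization, no noise)
  Z <- matrix(0, d, n)
  bs <- 64L
  for (b0 in seq(1L, n, by = bs)) {
    idx <- b0:min(b0 + bs - 1L, n)
    xb <- array(dequantize(images[, , idx, drop = FALSE], noise = FALSE),
                c(dim(images)[1], dim(images)[2], 1L, length(idx)))
    Z[, idx] <- flow_forward_core(model, xb)$z
  }
  basis <- build_hyperplane(Z, rank_tol = rank_tol, model = model)
  structure(list(flow = model, basis = basis, config = model$config,
                 n_train = n, latents = Z),
            class = "eggpale")
}

#' Enhance (or normalize) images with a fitted emphasizer
#'
#' @param object an [eggpale_fit()] object.
#' @param newdata image(s) in `[0, 255]` at model resolution: a matrix, an
#'   `H x W x B` array, a list of matrices, or `phantom_record`(s).
#' @param gamma,beta,mode enhancement parameters (see [enhance_params()]).
#' @param type `"enhanced"` for the lesion-emphasized image,
#'   `"normalized"` for the virtually normalized image (latent projected
#'   onto the hyperplane, mapped back), `"latent"` for the raw latent
#'   code(s).
#' @param ... unused.
#' @return a matrix for one image, else a list of matrices (or a `d x B`
#'   matrix for `type = "latent"`). Enhanced/normalized outputs are in
#'   `[0, 255]`; enhanced matrices carry a `"diff"` attribute with the
#'   signed change.
#' @export
predict.eggpale <- function(object, newdata, gamma = 0.2, beta = 1.2,
                            mode = c("linf", "euclidean"),
                            type = c("enhanced", "normalized", "latent"),
                            ...) {
  type <- match.arg(type)
  params <- enhance_params(gamma = gamma, beta = beta, mode = match.arg(mode))
  imgs <- coerce_image_list(newdata)
  if (type == "latent") {
    zs <- vapply(imgs, function(im)
      as.vector(forward_map(object$flow, to_model_space(im))$z),
      numeric(nrow(object$basis$Q)))
    return(if (length(imgs) == 1L) matrix(zs, ncol = 1L) else zs)
  }
  out <- lapply(imgs, function(im) {
    if (type == "enhanced") {
      enhance_image(object$flow, object$basis, im, params)
    } else {
      z <- as.vector(forward_map(object$flow, to_model_space(im))$z)
      from_model_space(inverse_map(object$flow,
                                   project_to_hyperplane(z, object$basis)))
    }
  })
  if (length(out) == 1L) out[[1]] else out
}

coerce_image_list <- function(newdata) {
  if (inherits(newdata, "phantom_record")) newdata <- list(newdata)
  if (is.matrix(newdata)) return(list(newdata))
  if (is.array(newdata) && length(dim(newdata)) == 3L)
    return(lapply(seq_len(dim(newdata)[3]), function(i) newdata[, , i]))
  if (is.list(newdata))
    return(lapply(newdata, function(x)
      if (inherits(x, "phantom_record")) x$image else as.matrix(x)))
  stop_input("cannot interpret newdata as images")
}

#' Sample synthetic images from a fitted emphasizer
#'
#' @param object an [eggpale_fit()] object.
#' @param nsim number of images.
#' @param seed integer seed (deterministic given it).
#' @param temperature latent standard-deviation multiplier.
#' @param ... unused.
#' @return an `H x W x nsim` array in `[0, 255]`.
#' @export
simulate.eggpale <- function(object, nsim = 1L, seed = 1L,
                             temperature = 0.7, ...) {
  x <- sample_flow(object$flow, n = nsim, temperature = temperature,
                   seed = seed)
  from_model_space(x)
}

#' Log-likelihood of images under the fitted flow
#'
#' @param object an [eggpale_fit()] object.
#' @param newdata images in `[0, 255]`; if missing, the log-likelihood is
#'   evaluated via the stored training latents.
#' @param ... unused.
#' @return an object of class `logLik` (sum over images; `df` = number of
#'   flow parameters).
#' @export
logLik.eggpale <- function(object, newdata, ...) {
  d <- nrow(object$latents)
  ll <- if (missing(newdata)) {
    ## prior term from stored latents; log-det recomputed per image is not
    ## stored, so evaluate on reconstructed images
    xs <- inverse_map(object$flow, object$latents)
    log_likelihood(object$flow, xs)
  } else {
    imgs <- coerce_image_list(newdata)
    vapply(imgs, function(im)
      log_likelihood(object$flow, to_model_space(im)), numeric(1))
  }
  structure(sum(ll), df = length(unlist(flow_params(object$flow))),
            nobs = length(ll), class = "logLik")
}

#' Off-hyperplane residuals
#'
#' The residual of a latent code is its component orthogonal to the normal
#' hyperplane, `z - Q Q' z`; its norm is a per-image abnormality score
#' (zero, up to rank tolerance, for the training images themselves).
#'
#' @param object an [eggpale_fit()] object.
#' @param newdata optional images in `[0, 255]`; default: the stored
#'   training latents.
#' @param ... unused.
#' @return numeric vector of residual L2 norms.
#' @export
residuals.eggpale <- function(object, newdata, ...) {
  Z <- if (missing(newdata)) object$latents
       else predict(object, newdata, type = "latent")
  R <- Z - project_to_hyperplane(Z, object$basis)
  sqrt(colSums(R^2))
}

#' @export
coef.eggpale <- function(object, ...) unlist(flow_params(object$flow))

#' @export
print.eggpale <- function(x, ...) {
  cat("Abnormal-lesion emphasizer (coupling flow + normal hyperplane)\n")
  print(x$flow)
  print(x$basis)
  invisible(x)
}

#' @export
summary.eggpale <- function(object, ...) {
  res <- residuals(object)
  structure(list(
    config = object$config, n_train = object$n_train,
    rank = object$basis$r, latent_dim = nrow(object$latents),
    loss_history = object$flow$loss_history,
    train_residual_range = range(res)
  ), class = "summary.eggpale")
}

#' @export
print.summary.eggpale <- function(x, ...) {
  cat("Abnormal-lesion emphasizer fit\n")
  cat(sprintf("  training images: %d; latent dim: %d; hyperplane rank: %d\n",
              x$n_train, x$latent_dim, x$rank))
  cat(sprintf("  training loss (nats/image): %s\n",
              paste(sprintf("%.1f", x$loss_history), collapse = " -> ")))
  cat(sprintf("  training-latent residual norms: [%.2e, %.2e]\n",
              x$train_residual_range[1], x$train_residual_range[2]))
  invisible(x)
}

#' @export
plot.eggpale <- function(x, ...) {
  lh <- x$flow$loss_history
  graphics::plot(seq_along(lh), lh, type = "b", xlab = "epoch",
                 ylab = "mean NLL (nats/image)",
                 main = "Flow training loss", ...)
  invisible(x)
}

## ---- persistence ---------------------------------------------------------

#' Save / load a fitted emphasizer
#'
#' Single-file checkpoint (serialized with a schema version and the flow
#' parameter hash). `read_eggpale()` refuses checkpoints whose stored hash
#' does not match their own parameters (corruption guard).
#'
#' @param object an `eggpale`, `flow_model` or `normal_basis` object.
#' @param path file path.
#' @return `read_eggpale()` returns the stored object; `write_eggpale()`
#'   returns `path` invisibly.
#' @export
write_eggpale <- function(object, path) {
  payload <- list(schema = "eggpale-checkpoint-1",
                  class = class(object)[1], object = object,
                  hash = checkpoint_hash(object))
  saveRDS(payload, path)
  invisible(path)
}

checkpoint_hash <- function(object) {
  if (inherits(object, "eggpale")) model_hash(object$flow)
  else if (inherits(object, "flow_model")) model_hash(object)
  else object_hash(unclass(object))
}

#' @rdname write_eggpale
#' @export
read_eggpale <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema, "eggpale-checkpoint-1"))
    stop_input("not an emphasizer checkpoint (schema mismatch)")
  if (!identical(payload$hash, checkpoint_hash(payload$object)))
    stop_input("checkpoint hash mismatch: file corrupted or tampered")
  payload$object
}
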