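## Multi-scale coupling flow: model container and the invertible maps.

## Channel count entering the step stack of level l (after that level's
## squeeze): channels * 2^(l+1).
level_channels <- function(cfg, l) cfg$channels * 2L^(l + 1L)

#' Build an untrained coupling-flow model
#'
#' Allocates the full parameter set: per step an activation-normalization
#' layer (identity until its data-dependent initialization), an invertible
#' 1x1 convolution initialized to a random rotation, and an affine coupling
#' whose last convolution is zero-initialized so every coupling starts as
#' the identity map.
#'
#' @param config a [flow_config()].
#' @param init `"default"` for the trainable initialization above,
#'   `"identity"` for an exactly-identity flow (unit scales, identity 1x1
#'   weights, zero coupling nets) used mainly for testing and didactics.
#' @return an object of class `flow_model`.
#' @export
flow_model <- function(config, init = c("default", "identity")) {
  init <- match.arg(init)
  validate_flow_config(config)
  set.seed(derive_seed(config$seed, 1L))
  k <- config$kernel_size
  levels <- vector("list", config$n_levels)
  for (l in seq_len(config$n_levels)) {
    C <- level_channels(config, l)
    H <- config$image_size %/% 2L^l
    steps <- vector("list", config$n_steps)
    for (s in seq_len(config$n_steps)) {
      Wc <- if (init == "identity") diag(C) else rand_rotation(C)
      ch <- C %/% 2L
      widths <- c(ch, rep(config$hidden_width, config$n_coupling_convs - 1L), C)
      convs <- vector("list", config$n_coupling_convs)
      for (i in seq_len(config$n_coupling_convs)) {
        cin <- widths[i]; cout <- widths[i + 1L]
        fan_in <- cin * k^2
        Wm <- if (i == config$n_coupling_convs || init == "identity") {
          matrix(0, cout, fan_in)
        } else {
          matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                 cout, fan_in)
        }
        convs[[i]] <- list(W = Wm, b = numeric(cout))
      }
      steps[[s]] <- list(
        actnorm = list(logs = numeric(C), b = numeric(C)),
        invconv = list(W = Wc),
        coupling = list(convs = convs)
      )
    }
    levels[[l]] <- list(C = C, H = H, steps = steps,
                        ci = conv_index(H, H, k))
  }
  model <- list(config = config, levels = levels,
                actnorm_initialized = (init == "identity"),
                loss_history = numeric(0))
  class(model) <- "flow_model"
  model
}

rand_rotation <- function(n) {
  if (n == 1L) return(matrix(1, 1, 1))
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  ## fix sign so det = +1
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Latent layout of a flow model
#'
#' The latent code is a flat vector assembled level by level: at every level
#' but the last, half the channels are factored out after that level's
#' steps; the last level contributes all remaining channels. Each factored
#' block is flattened in column-major (row, column, channel) order, level 1
#' first. The layout makes `flatten` / `unflatten` an exact bijection.
#'
#' @param model a [flow_model()].
#' @return a list with per-level block dimensions `dims` and the total
#'   latent dimension `d`.
#' @export
latent_layout <- function(model) {
  cfg <- model$config
  L <- cfg$n_levels
  dims <- vector("list", L)
  for (l in seq_len(L)) {
    C <- level_channels(cfg, l)
    H <- cfg$image_size %/% 2L^l
    Cz <- if (l < L) C %/% 2L else C
    dims[[l]] <- c(H, H, Cz)
  }
  list(dims = dims, d = as.integer(sum(vapply(dims, prod, numeric(1)))))
}

## coerce user input to an (H, W, C, B) activation array in model space
as_batch_array <- function(x, cfg) {
  if (is.list(x)) {
    x <- vapply(x, function(m) as.matrix(m),
                matrix(0, cfg$image_size, cfg$image_size))
  }
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) {
    ## (H, W, B) stack of single-channel images
    d <- dim(x)
    dim(x) <- c(d[1], d[2], 1L, d[3])
  }
  d <- dim(x)
  if (d[1] != cfg$image_size || d[2] != cfg$image_size || d[3] != cfg$channels)
    stop_input(sprintf(
      "input shape %dx%dx%d does not match the model (%dx%dx%d)",
      d[1], d[2], d[3], cfg$image_size, cfg$image_size, cfg$channels))
  storage.mode(x) <- "double"
  x
}

## core forward pass; returns z (d x B), per-sample logdet, optional caches
flow_forward_core <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  B <- dim(x)[4]
  L <- cfg$n_levels
  logdet <- numeric(B)
  zblocks <- vector("list", L)
  caches <- if (keep_cache) vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    h <- squeeze2(h)
    lev <- model$levels[[l]]
    ci <- lev$ci
    scache <- if (keep_cache) vector("list", length(lev$steps))
    for (s in seq_along(lev$steps)) {
      st <- lev$steps[[s]]
      an <- actnorm_forward(h, st$actnorm$logs, st$actnorm$b)
      check_numeric_ok(an$y, l, s, "actnorm")
      ic <- invconv_forward(an$y, st$invconv$W)
      cp <- coupling_forward(ic$y, st$coupling$convs, ci, keep_cache)
      check_numeric_ok(cp$y, l, s, "coupling")
      logdet <- logdet + an$logdet + ic$logdet + cp$logdet
      if (keep_cache)
        scache[[s]] <- list(x_an = h, y_an = an$y, y_ic = ic$y, cpl = cp$cache)
      h <- cp$y
    }
    if (l < L) {
      C <- lev$C
      zblocks[[l]] <- h[, , seq_len(C %/% 2L), , drop = FALSE]
      h <- h[, , C %/% 2L + seq_len(C %/% 2L), , drop = FALSE]
    } else {
      zblocks[[l]] <- h
    }
    if (keep_cache) caches[[l]] <- scache
  }
  z <- do.call(rbind, lapply(zblocks, function(b) {
    matrix(b, prod(dim(b)[1:3]), B)
  }))
  list(z = z, logdet = logdet, caches = caches)
}

check_numeric_ok <- function(h, l, s, layer) {
  if (!all(is.finite(h)))
    stop(sprintf(
      "non-finite activations in level %d, step %d (%s layer)", l, s, layer),
      call. = FALSE)
  invisible(NULL)
}

flow_inverse_core <- function(model, z) {
  cfg <- model$config
  lay <- latent_layout(model)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  if (nrow(z) != lay$d)
    stop_input(sprintf("latent length %d does not match the model (%d)",
                       nrow(z), lay$d))
  B <- ncol(z)
  L <- cfg$n_levels
  ## slice z back into per-level blocks
  offs <- c(0, cumsum(vapply(lay$dims, prod, numeric(1))))
  zblocks <- lapply(seq_len(L), function(l) {
    block <- z[(offs[l] + 1L):offs[l + 1L], , drop = FALSE]
    array(block, c(lay$dims[[l]], B))
  })
  h <- NULL
  for (l in rev(seq_len(L))) {
    lev <- model$levels[[l]]
    ci <- lev$ci
    h <- if (l == L) zblocks[[L]] else {
      d <- dim(h)
      full <- array(0, c(d[1], d[2], lev$C, B))
      full[, , seq_len(lev$C %/% 2L), ] <- zblocks[[l]]
      full[, , lev$C %/% 2L + seq_len(lev$C %/% 2L), ] <- h
      full
    }
    for (s in rev(seq_along(lev$steps))) {
      st <- lev$steps[[s]]
      h <- coupling_inverse(h, st$coupling$convs, ci)
      h <- invconv_inverse(h, st$invconv$W)
      ## invert actnorm: x = y / s - b
      HW <- dim(h)[1] * dim(h)[2]
      h <- h / rep(exp(st$actnorm$logs), each = HW) -
        rep(st$actnorm$b, each = HW)
    }
    h <- unsqueeze2(h)
  }
  h
}

#' Map images to latent codes (forward flow)
#'
#' Applies the invertible flow to one or more images, returning the flat
#' latent code(s) and the accumulated log-determinant of the Jacobian,
#' summed over every layer of the composition.
#'
#' The flow operates on *model-space* intensities (roughly centered, unit
#' scale); use [to_model_space()] to convert preprocessed `[0, 255]` images.
#'
#' @param model a trained (or at least actnorm-initialized) [flow_model()].
#' @param x a single image matrix, an `H x W x B` stack, or a list of
#'   matrices, already in model space.
#' @return a list with `z` (latent matrix, `d x B`; a single input also
#'   keeps `z` as a matrix with one column), `logdet` (length-`B` vector)
#'   and `layout` (see [latent_layout()]).
#' @export
forward_map <- function(model, x) {
  stopifnot(inherits(model, "flow_model"))
  if (!model$actnorm_initialized)
    stop_input("actnorm layers are uninitialized; train the model or ",
               "supply an initialization batch via train_flow()")
  xb <- as_batch_array(x, model$config)
  fw <- flow_forward_core(model, xb)
  list(z = fw$z, logdet = fw$logdet, layout = latent_layout(model))
}

#' Map latent codes back to images (inverse flow)
#'
#' Exact layer-by-layer algebraic inverse of [forward_map()], applied in
#' reverse order.
#'
#' @param model a [flow_model()].
#' @param z a latent vector of length `d`, or a `d x B` matrix of codes.
#' @return a single image matrix (one code) or an `H x W x B` array.
#' @export
inverse_map <- function(model, z) {
  stopifnot(inherits(model, "flow_model"))
  single <- is.null(dim(z))
  x <- flow_inverse_core(model, z)
  d <- dim(x)
  if (model$config$channels == 1L) {
    dim(x) <- c(d[1], d[2], d[4])
    if (single || d[4] == 1L) x <- x[, , 1L]
  }
  x
}

#' Exact log-likelihood under the flow
#'
#' Computes `log p(z) + log|det J|` with the prior fixed to the standard
#' Gaussian: `log p(z) = -d/2 log(2 pi) - ||z||^2 / 2` for latent dimension
#' `d`. The fixed isotropic prior is what gives Euclidean and chessboard
#' distances in latent space their meaning.
#'
#' @inheritParams forward_map
#' @return numeric vector of per-image log-likelihoods (nats).
#' @export
log_likelihood <- function(model, x) {
  fw <- forward_map(model, x)
  d <- nrow(fw$z)
  -0.5 * d * log(2 * pi) - 0.5 * colSums(fw$z^2) + fw$logdet
}

#' Re-project a weight matrix onto bounded singular values
#'
#' Replaces `W = U S V'` by `U crop(S) V'` where every singular value is
#' cropped into `[sv_min, sv_max]`. Applied to every invertible 1x1
#' convolution weight at the end of each training epoch, this guarantees an
#' inverse exists with condition number at most `sv_max / sv_min`. Matrices
#' whose singular values are already in range are returned unchanged up to
#' floating-point round-off, and the operation is idempotent.
#'
#' @param W square numeric matrix with finite entries.
#' @param sv_min,sv_max positive crop bounds, `sv_min < sv_max`
#'   (defaults 1e-3 and 1e3).
#' @return the re-projected square matrix.
#' @export
svd_reproject_weights <- function(W, sv_min = 1e-3, sv_max = 1e3) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop_input("W must be a square matrix")
  check_finite(W, "W")
  if (sv_min <= 0 || sv_min >= sv_max)
    stop_input("need 0 < sv_min < sv_max")
  sv <- svd(W)
  d_new <- clamp(sv$d, sv_min, sv_max)
  if (identical(d_new, sv$d)) return(W)
  sv$u %*% (d_new * t(sv$v))
}

## apply the re-projection to every 1x1 weight of a model
reproject_model_weights <- function(model) {
  cfg <- model$config
  for (l in seq_along(model$levels))
    for (s in seq_along(model$levels[[l]]$steps)) {
      W <- model$levels[[l]]$steps[[s]]$invconv$W
      model$levels[[l]]$steps[[s]]$invconv$W <-
        svd_reproject_weights(W, cfg$sv_min, cfg$sv_max)
    }
  model
}

#' Draw images from the flow
#'
#' Samples latent codes from `N(0, temperature^2 I)` and maps them through
#' the inverse flow. Mainly a diagnostic: at `temperature = 0` it returns
#' `n` copies of the model's modal image.
#'
#' @param model a trained [flow_model()].
#' @param n number of images.
#' @param temperature standard-deviation multiplier of the latent draw.
#' @param seed integer seed; the draw is deterministic given it.
#' @return an `H x W x n` array in model space.
#' @export
sample_flow <- function(model, n = 1L, temperature = 0.7, seed = 1L) {
  stopifnot(inherits(model, "flow_model"))
  d <- latent_layout(model)$d
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(d * n, sd = 1), d, n) * temperature
  x <- flow_inverse_core(model, z)
  dm <- dim(x)
  dim(x) <- c(dm[1], dm[2], dm[4])
  x
}

## ---- model-space conversion --------------------------------------------

#' Convert between display and model intensity scales
#'
#' The flow operates on intensities mapped from `[0, 255]` to
#' `[-0.5, 0.5]` via `(x + 0.5)/256 - 0.5` (the deterministic center of the
#' training-time dequantization bin). `from_model_space()` applies the exact
#' inverse and, by default, clips back into `[0, 255]`.
#'
#' @param x image matrix/array in `[0, 255]` (resp. model space).
#' @param clip clip the display-space result into `[0, 255]`.
#' @return converted matrix/array.
#' @export
to_model_space <- function(x) (x + 0.5) / 256 - 0.5

#' @rdname to_model_space
#' @export
from_model_space <- function(x, clip = TRUE) {
  y <- (x + 0.5) * 256 - 0.5
  if (clip) y <- clamp(y, 0, 255)
  y
}

#' @export
print.flow_model <- function(x, ...) {
  cfg <- x$config
  np <- length(unlist(flow_params(x)))
  cat(sprintf(
    "Coupling flow: %dx%d -> latent %d; %d level(s) x %d step(s); %s parameters\n",
    cfg$image_size, cfg$image_size, latent_layout(x)$d, cfg$n_levels,
    cfg$n_steps, format(np, big.mark = ",")))
  cat(sprintf("  actnorm initialized: %s; epochs trained: %d\n",
              x$actnorm_initialized, length(x$loss_history)))
  invisible(x)
}
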