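## Maximum-likelihood training of the coupling flow.
##
## The loss is the mean negative log-likelihood (nats/image). Gradients are
## hand-derived per layer (validated against finite differences in the test
## suite) and optimized with Adam.

## nested parameter list mirroring the model; unlist() gives the flat vector
flow_params <- function(model) {
  lapply(model$levels, function(lev) {
    lapply(lev$steps, function(st) {
      list(an_logs = st$actnorm$logs, an_b = st$actnorm$b,
           ic_W = st$invconv$W,
           cpl = lapply(st$coupling$convs, function(cv)
             list(W = cv$W, b = cv$b)))
    })
  })
}

set_flow_params <- function(model, params) {
  for (l in seq_along(model$levels))
    for (s in seq_along(model$levels[[l]]$steps)) {
      p <- params[[l]][[s]]
      model$levels[[l]]$steps[[s]]$actnorm$logs <- p$an_logs
      model$levels[[l]]$steps[[s]]$actnorm$b <- p$an_b
      model$levels[[l]]$steps[[s]]$invconv$W <- p$ic_W
      for (i in seq_along(p$cpl)) {
        model$levels[[l]]$steps[[s]]$coupling$convs[[i]]$W <- p$cpl[[i]]$W
        model$levels[[l]]$steps[[s]]$coupling$convs[[i]]$b <- p$cpl[[i]]$b
      }
    }
  model
}

## loss and parameter gradient for one model-space minibatch
flow_loss_grad <- function(model, xb) {
  cfg <- model$config
  B <- dim(xb)[4]
  fw <- flow_forward_core(model, xb, keep_cache = TRUE)
  d <- nrow(fw$z)
  loss <- mean(0.5 * colSums(fw$z^2)) + 0.5 * d * log(2 * pi) -
    mean(fw$logdet)
  gz <- fw$z / B
  L <- cfg$n_levels
  lay <- latent_layout(model)
  offs <- c(0, cumsum(vapply(lay$dims, prod, numeric(1))))
  gblocks <- lapply(seq_len(L), function(l) {
    array(gz[(offs[l] + 1L):offs[l + 1L], , drop = FALSE],
          c(lay$dims[[l]], B))
  })
  grads <- vector("list", L)
  gh <- NULL
  for (l in rev(seq_len(L))) {
    lev <- model$levels[[l]]
    ci <- lev$ci
    g <- if (l == L) gblocks[[L]] else {
      dm <- dim(gh)
      full <- array(0, c(dm[1], dm[2], lev$C, B))
      full[, , seq_len(lev$C %/% 2L), ] <- gblocks[[l]]
      full[, , lev$C %/% 2L + seq_len(lev$C %/% 2L), ] <- gh
      full
    }
    gsteps <- vector("list", length(lev$steps))
    for (s in rev(seq_along(lev$steps))) {
      st <- lev$steps[[s]]
      cch <- fw$caches[[l]][[s]]
      cb <- coupling_backward(g, st$coupling$convs, cch$cpl, ci, B)
      ib <- invconv_backward(cb$gx, cch$y_an, st$invconv$W, B)
      ab <- actnorm_backward(ib$gx, cch$y_an, st$actnorm$logs, B)
      gsteps[[s]] <- list(
        an_logs = ab$glogs, an_b = ab$gb, ic_W = ib$gW,
        cpl = cb$gconvs)
      g <- ab$gx
    }
    grads[[l]] <- gsteps
    gh <- unsqueeze2(g)
  }
  list(loss = loss, grads = grads, z = fw$z, logdet = fw$logdet)
}

## data-dependent initialization of every actnorm layer on one batch:
## each layer is set so its output has per-channel mean 0, variance 1,
## then the forward pass continues through the freshly initialized layer
actnorm_initialize <- function(model, xb) {
  L <- model$config$n_levels
  h <- xb
  for (l in seq_len(L)) {
    h <- squeeze2(h)
    lev <- model$levels[[l]]
    for (s in seq_along(lev$steps)) {
      ini <- actnorm_init(h)
      model$levels[[l]]$steps[[s]]$actnorm$logs <- ini$logs
      model$levels[[l]]$steps[[s]]$actnorm$b <- ini$b
      h <- actnorm_forward(h, ini$logs, ini$b)$y
      st <- model$levels[[l]]$steps[[s]]
      h <- invconv_forward(h, st$invconv$W)$y
      h <- coupling_forward(h, st$coupling$convs, lev$ci)$y
    }
    if (l < L) h <- h[, , lev$C %/% 2L + seq_len(lev$C %/% 2L), ,
                      drop = FALSE]
  }
  model$actnorm_initialized <- TRUE
  model
}

## dequantize [0,255] integers-or-reals into model space; u ~ U(0,1) noise
## during training, the bin center 0.5 at evaluation time
dequantize <- function(raw, noise = TRUE) {
  u <- if (noise) stats::runif(length(raw)) else 0.5
  (raw + u) / 256 - 0.5
}

#' Train the coupling flow on normal images
#'
#' Minimizes the mean negative log-likelihood by Adam. On the first batch
#' (fixed by the seed) every activation-normalization layer is initialized
#' from the data so its output has per-channel zero mean and unit variance.
#' At the end of every epoch each invertible 1x1 convolution weight is
#' re-projected onto bounded singular values ([svd_reproject_weights()]),
#' which keeps the whole flow invertible throughout training. Inputs are
#' dequantized with uniform noise of one intensity quantum (1/256 after
#' rescaling); the trained model itself is fully deterministic.
#'
#' @param model an untrained [flow_model()], or `NULL` to build one from
#'   `config`.
#' @param images training images in `[0, 255]`: a list of square matrices
#'   or an `H x W x n` array, already at model resolution.
#' @param config a [flow_config()]; defaults to the model's own.
#' @param verbose print per-epoch loss.
#' @return the trained `flow_model`, with `loss_history` holding the mean
#'   per-epoch training loss (nats/image).
#' @export
train_flow <- function(model = NULL, images, config = NULL, verbose = FALSE) {
  if (is.null(model)) {
    if (is.null(config)) stop_input("supply a model or a config")
    model <- flow_model(config)
  }
  if (is.null(config)) config <- model$config
  cfg <- config
  if (is.list(images) && !is.array(images))
    images <- simplify2array(images)
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[3]
  if (n < cfg$batch_size)
    stop_input(sprintf("need at least batch_size = %d images, got %d",
                       cfg$batch_size, n))
  if (dim(images)[1] != cfg$image_size || dim(images)[2] != cfg$image_size)
    stop_input("images must already be at model resolution; ",
               "see standardize_geometry()")
  set.seed(derive_seed(cfg$seed, 2L))
  d <- latent_layout(model)$d

  params <- flow_params(model)
  skel <- params
  theta <- unlist(params, use.names = FALSE)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0L

  first_batch_done <- FALSE
  for (epoch in seq_len(cfg$n_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    batch_losses <- numeric(0)
    for (b0 in starts) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      if (length(idx) < 2L) next          # skip degenerate tail batch
      raw <- images[, , idx, drop = FALSE]
      xb <- array(dequantize(raw), c(cfg$image_size, cfg$image_size, 1L,
                                     length(idx)))
      if (!first_batch_done && !model$actnorm_initialized) {
        model <- actnorm_initialize(model, xb)
        first_batch_done <- TRUE
      }
      lg <- flow_loss_grad(model, xb)
      if (!is.finite(lg$loss))
        stop(sprintf(
          "training diverged (non-finite loss) at epoch %d, batch %d",
          epoch, match(b0, starts)), call. = FALSE)
      g <- unlist(lg$grads, use.names = FALSE)
      t_step <- t_step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^t_step)
      vhat <- v / (1 - b2^t_step)
      theta <- unlist(flow_params(model), use.names = FALSE)
      theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      model <- set_flow_params(model, utils::relist(theta, skel))
      batch_losses <- c(batch_losses, lg$loss)
    }
    model <- reproject_model_weights(model)
    model$loss_history <- c(model$loss_history, mean(batch_losses))
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.3f nats (%.4f bits/dim)",
                      epoch, cfg$n_epochs, mean(batch_losses),
                      mean(batch_losses) / (d * log(2))))
  }
  model$config <- cfg
  model
}
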