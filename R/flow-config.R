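#' Configuration of the coupling-flow generative model
#'
#' Collects every architectural and training hyperparameter of the
#' multi-scale coupling flow. The model operates on square grayscale images;
#' at each of `n_levels` resolution levels a squeeze doubles the channel
#' count four-fold while halving each spatial side, followed by `n_steps`
#' flow steps (activation normalization, invertible 1x1 convolution, affine
#' coupling). Between levels half the channels are factored out into the
#' latent code.
#'
#' @param image_size side length in pixels of the (square) model input.
#'   Must be divisible by `2^n_levels`.
#' @param channels input channel count; 1 for grayscale radiographs.
#' @param n_levels number of multi-scale levels (>= 1).
#' @param n_steps flow steps per level (>= 1).
#' @param n_coupling_convs convolution layers inside each coupling network.
#' @param kernel_size spatial kernel extent (odd).
#' @param hidden_width channel count of the coupling-network hidden layers.
#' @param sv_min,sv_max crop bounds for the singular values of every 1x1
#'   convolution weight; applied at the end of each training epoch so the
#'   weights stay comfortably invertible (condition number at most
#'   `sv_max / sv_min`). Defaults 1e-3 and 1e3.
#' @param batch_size minibatch size for training.
#' @param n_epochs number of training epochs.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization, minibatch order and
#'   dequantization noise.
#' @return an object of class `flow_config` (a validated named list).
#' @seealso [flow_config_preset()] for the shipped presets.
#' @export
flow_config <- function(image_size = 32L, channels = 1L, n_levels = 2L,
                        n_steps = 4L, n_coupling_convs = 3L, kernel_size = 3L,
                        hidden_width = 64L, sv_min = 1e-3, sv_max = 1e3,
                        batch_size = 8L, n_epochs = 4L, learning_rate = 1e-4,
                        seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size), channels = as.integer(channels),
    n_levels = as.integer(n_levels), n_steps = as.integer(n_steps),
    n_coupling_convs = as.integer(n_coupling_convs),
    kernel_size = as.integer(kernel_size),
    hidden_width = as.integer(hidden_width),
    sv_min = as.numeric(sv_min), sv_max = as.numeric(sv_max),
    batch_size = as.integer(batch_size), n_epochs = as.integer(n_epochs),
    learning_rate = as.numeric(learning_rate), seed = as.integer(seed)
  )
  validate_flow_config(cfg)
  class(cfg) <- "flow_config"
  cfg
}

validate_flow_config <- function(cfg) {
  if (cfg$n_levels < 1L) stop_input("n_levels must be >= 1")
  if (cfg$n_steps < 1L) stop_input("n_steps must be >= 1")
  if (cfg$image_size %% (2L^cfg$n_levels) != 0L)
    stop_input("image_size must be divisible by 2^n_levels")
  if (cfg$sv_min <= 0) stop_input("sv_min must be > 0")
  if (cfg$sv_min >= cfg$sv_max) stop_input("sv_min must be < sv_max")
  if (cfg$kernel_size %% 2L != 1L) stop_input("kernel_size must be odd")
  if (cfg$channels < 1L) stop_input("channels must be >= 1")
  if (cfg$batch_size < 1L) stop_input("batch_size must be >= 1")
  invisible(cfg)
}

#' Shipped flow configurations
#'
#' `"desk"` is the small configuration every test and example runs on a
#' single CPU: 32x32 single-channel images, 2 levels, 4 steps per level,
#' hidden width 64. `"paper512"` is the full-scale radiograph configuration
#' (512x512, 7 levels, 32 steps per level, hidden width 512, 22 epochs,
#' minibatch 4); it is shipped as metadata for completeness and is far too
#' large to train casually.
#'
#' @param name `"desk"` or `"paper512"`.
#' @return a [flow_config()] object.
#' @export
flow_config_preset <- function(name = c("desk", "paper512")) {
  name <- match.arg(name)
  switch(name,
    desk = flow_config(),
    paper512 = flow_config(
      image_size = 512L, channels = 1L, n_levels = 7L, n_steps = 32L,
      n_coupling_convs = 3L, kernel_size = 3L, hidden_width = 512L,
      batch_size = 4L, n_epochs = 22L
    )
  )
}

#' Read / write a flow configuration as YAML
#'
#' @param path file path.
#' @param cfg a [flow_config()] object.
#' @return `read_flow_config()` returns a `flow_config`;
#'   `write_flow_config()` returns `path` invisibly.
#' @export
read_flow_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(flow_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop_input("unknown config fields: ",
                                paste(extra, collapse = ", "))
  do.call(flow_config, raw)
}

#' @rdname read_flow_config
#' @export
write_flow_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "flow_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.flow_config <- function(x, ...) {
  cat("Coupling-flow configuration\n")
  cat(sprintf("  image: %dx%d, %d channel(s); latent dim %d\n",
              x$image_size, x$image_size, x$channels,
              x$image_size^2 * x$channels))
  cat(sprintf("  levels: %d, steps/level: %d, coupling convs: %d (%dx%d, width %d)\n",
              x$n_levels, x$n_steps, x$n_coupling_convs,
              x$kernel_size, x$kernel_size, x$hidden_width))
  cat(sprintf("  singular-value crop: [%g, %g]\n", x$sv_min, x$sv_max))
  cat(sprintf("  training: %d epochs, batch %d, lr %g, seed %d\n",
              x$n_epochs, x$batch_size, x$learning_rate, x$seed))
  invisible(x)
}
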