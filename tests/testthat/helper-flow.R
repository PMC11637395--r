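## Shared fixtures. The trained desk-scale fit is expensive (~1.5 min), so
## it is built once per test run and reused by every test that needs a
## trained model.

.fixtures <- new.env(parent = emptyenv())

## 200 normal phantoms -> trained desk-scale flow + normal-hyperplane basis
trained_fit <- function() {
  if (is.null(.fixtures$fit)) {
    normals <- generate_normal(phantom_spec(seed = 101L), 200)
    .fixtures$fit <- eggpale_fit(normals)
  }
  .fixtures$fit
}

tiny_config <- function(image_size = 8L, n_levels = 2L, n_steps = 2L,
                        hidden_width = 6L, seed = 5L, ...) {
  flow_config(image_size = image_size, n_levels = n_levels,
              n_steps = n_steps, hidden_width = hidden_width,
              batch_size = 4L, seed = seed, ...)
}

## a small non-trivial flow: random actnorm scales/offsets, random
## rotations (from the constructor) and non-zero final coupling weights,
## marked actnorm-initialized so the maps can be used directly
randomized_model <- function(cfg = tiny_config(), seed = 7L,
                             coupling_sd = 0.05) {
  m <- flow_model(cfg)
  set.seed(seed)
  for (l in seq_along(m$levels)) {
    C <- m$levels[[l]]$C
    for (s in seq_along(m$levels[[l]]$steps)) {
      m$levels[[l]]$steps[[s]]$actnorm$logs <- stats::rnorm(C, sd = 0.1)
      m$levels[[l]]$steps[[s]]$actnorm$b <- stats::rnorm(C, sd = 0.1)
      nc <- length(m$levels[[l]]$steps[[s]]$coupling$convs)
      W <- m$levels[[l]]$steps[[s]]$coupling$convs[[nc]]$W
      m$levels[[l]]$steps[[s]]$coupling$convs[[nc]]$W <-
        matrix(stats::rnorm(length(W), sd = coupling_sd), nrow(W))
    }
  }
  m$actnorm_initialized <- TRUE
  m
}

## finite-difference Jacobian log-determinant of the forward map
fd_logdet <- function(model, x, h = 1e-5) {
  n <- model$config$image_size
  f <- function(v) as.vector(forward_map(model, matrix(v, n, n))$z)
  d <- n * n
  J <- matrix(0, d, d)
  v0 <- as.vector(x)
  for (i in seq_len(d)) {
    e <- numeric(d); e[i] <- h
    J[, i] <- (f(v0 + e) - f(v0 - e)) / (2 * h)
  }
  as.numeric(determinant(J, logarithm = TRUE)$modulus)
}
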