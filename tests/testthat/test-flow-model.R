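test_that("identity flow maps an image to a permutation of its pixels with zero log-det", {
  cfg <- tiny_config(n_steps = 1L)
  m <- flow_model(cfg, init = "identity")
  set.seed(1)
  x <- matrix(rnorm(64), 8, 8)
  fw <- forward_map(m, x)
  expect_equal(fw$logdet, 0)
  expect_equal(sort(as.vector(fw$z)), sort(as.vector(x)))
  expect_equal(inverse_map(m, fw$z), x)
  ## zero latent -> all-zero image
  expect_equal(inverse_map(m, numeric(64)), matrix(0, 8, 8))
})

test_that("a single scaling layer has log-det n*log|s|, matching the numerical Jacobian", {
  ## one level, one step, identity everywhere except a uniform actnorm
  ## scale s: on a 4x4 single-channel image the Jacobian determinant is
  ## s^16, so log-det = 16 log s
  cfg <- flow_config(image_size = 4L, n_levels = 1L, n_steps = 1L,
                     hidden_width = 4L, batch_size = 2L)
  m <- flow_model(cfg, init = "identity")
  s <- 1.7
  m$levels[[1]]$steps[[1]]$actnorm$logs <- rep(log(s), m$levels[[1]]$C)
  set.seed(2)
  x <- matrix(rnorm(16), 4, 4)
  fw <- forward_map(m, x)
  expect_equal(fw$logdet, 16 * log(s))
  expect_equal(fw$logdet, fd_logdet(m, x), tolerance = 1e-6)
})

test_that("forward log-det matches the finite-difference Jacobian on 8x8 inputs", {
  m <- randomized_model(tiny_config())
  set.seed(3)
  for (rep in 1:2) {
    x <- matrix(rnorm(64), 8, 8)
    fw <- forward_map(m, x)
    expect_equal(fw$logdet, fd_logdet(m, x), tolerance = 1e-3)
  }
})

test_that("forward followed by inverse reproduces random images exactly", {
  m <- randomized_model(tiny_config(n_levels = 3L, image_size = 16L))
  set.seed(4)
  xs <- array(rnorm(16 * 16 * 20), c(16, 16, 20))
  fw <- forward_map(m, xs)
  xr <- inverse_map(m, fw$z)
  expect_lt(max(abs(xr - xs)), 1e-8)
})

test_that("latent dimension equals pixel count for any configuration", {
  for (cfg in list(tiny_config(), tiny_config(image_size = 16L, n_levels = 4L),
                   flow_config_preset("desk"))) {
    m <- flow_model(cfg, init = "identity")
    lay <- latent_layout(m)
    expect_equal(lay$d, cfg$image_size^2 * cfg$channels)
    fw <- forward_map(m, matrix(0.3, cfg$image_size, cfg$image_size))
    expect_equal(nrow(fw$z), lay$d)
  }
})

test_that("log-likelihood reduces to the standard-Gaussian prior for the identity flow", {
  cfg <- flow_config(image_size = 2L, n_levels = 1L, n_steps = 1L,
                     hidden_width = 4L, batch_size = 2L)
  m <- flow_model(cfg, init = "identity")
  ## z = 0, d = 4: log p = -d/2 log(2 pi)
  expect_equal(log_likelihood(m, matrix(0, 2, 2)), -2 * log(2 * pi))
  set.seed(5)
  x <- matrix(rnorm(4), 2, 2)
  expect_equal(log_likelihood(m, x),
               -2 * log(2 * pi) - 0.5 * sum(x^2))
})

test_that("log-likelihood equals prior plus numerical Jacobian log-det on a tiny model", {
  m <- randomized_model(tiny_config())
  set.seed(6)
  x <- matrix(rnorm(64), 8, 8)
  fw <- forward_map(m, x)
  ll_expected <- -32 * log(2 * pi) - 0.5 * sum(fw$z^2) + fd_logdet(m, x)
  expect_equal(log_likelihood(m, x), ll_expected, tolerance = 1e-3)
})

test_that("forward_map validates input shape and actnorm state", {
  m <- randomized_model(tiny_config())
  expect_error(forward_map(m, matrix(0, 4, 4)), "does not match")
  m2 <- flow_model(tiny_config())
  expect_error(forward_map(m2, matrix(0, 8, 8)), "uninitialized")
})

test_that("non-finite activations are reported with the layer position", {
  m <- randomized_model(tiny_config())
  m$levels[[1]]$steps[[1]]$actnorm$logs[] <- 1e4   # overflows exp()
  expect_error(forward_map(m, matrix(1, 8, 8)), "level 1, step 1")
})

test_that("singular-value re-projection crops, preserves in-range matrices, and is idempotent", {
  ## orthogonal matrix: all singular values 1, unchanged
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(svd_reproject_weights(Q), Q)
  ## hand-computable diagonal case
  W <- diag(c(2, 1e-5))
  Wn <- svd_reproject_weights(W, 1e-3, 1e3)
  expect_equal(sort(svd(Wn)$d), c(1e-3, 2))
  ## idempotence and condition-number bound on random ill-conditioned input
  set.seed(7)
  B <- matrix(rnorm(36), 6, 6) %*% diag(10^seq(-6, 5, length.out = 6)) %*%
    qr.Q(qr(matrix(rnorm(36), 6, 6)))
  B1 <- svd_reproject_weights(B, 1e-3, 1e3)
  sv <- svd(B1)$d
  expect_true(all(sv >= 1e-3 - 1e-9 & sv <= 1e3 + 1e-6))
  expect_lte(max(sv) / min(sv), 1e6 * (1 + 1e-9))
  expect_equal(svd_reproject_weights(B1, 1e-3, 1e3), B1, tolerance = 1e-10)
  expect_error(svd_reproject_weights(matrix(0, 2, 3)), "square")
  expect_error(svd_reproject_weights(matrix(c(1, NA, 0, 1), 2, 2)),
               "non-finite")
})

test_that("sampling is deterministic and degenerates to the modal image at temperature 0", {
  m <- randomized_model(tiny_config())
  s0 <- sample_flow(m, n = 3, temperature = 0, seed = 9)
  modal <- inverse_map(m, numeric(64))
  for (i in 1:3) expect_equal(s0[, , i], modal)
  s1 <- sample_flow(m, n = 2, temperature = 0.7, seed = 11)
  s2 <- sample_flow(m, n = 2, temperature = 0.7, seed = 11)
  expect_identical(s1, s2)
  expect_true(all(is.finite(s1)))
})

test_that("model-space conversion is an exact round trip", {
  x <- matrix(seq(0, 255, length.out = 64), 8, 8)
  expect_equal(from_model_space(to_model_space(x)), x)
})
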