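## constrained-minimization oracle: minimize ||z - z_input||_2 over the
## ball ||z - z0||_2 <= R by Nelder-Mead on the ball-projected objective
ball_min_oracle <- function(z_input, z0, R) {
  proj <- function(v) {
    d <- v - z0
    nd <- sqrt(sum(d^2))
    if (nd <= R) v else z0 + d * R / max(nd, 1e-300)
  }
  obj <- function(v) sum((proj(v) - z_input)^2)
  best <- NULL
  set.seed(41)
  for (start in list(z0, z_input, (z0 + z_input) / 2,
                     z0 + rnorm(length(z0)))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  proj(best$par)
}

## separable L1 oracle: the box-constrained L1 minimizer coordinate-wise by
## fine grid search
box_l1_oracle <- function(z_input, z0, Gamma) {
  vapply(seq_along(z_input), function(j) {
    grid <- seq(z0[j] - Gamma, z0[j] + Gamma, length.out = 4001)
    grid[which.min(abs(grid - z_input[j]))]
  }, numeric(1))
}

test_that("Euclidean extrapolation identities and hand example", {
  z0 <- c(0, 0); zi <- c(2, 0)
  expect_equal(extrapolate_euclidean(zi, z0, 1), zi)
  expect_equal(extrapolate_euclidean(zi, z0, 0), z0)
  expect_equal(extrapolate_euclidean(zi, z0, 1.5), c(3, 0))
  expect_error(extrapolate_euclidean(c(1, 2), c(1, 2, 3), 1), "differ")
})

test_that("for gamma in [0,1] Euclidean extrapolation solves the hypersphere problem", {
  set.seed(42)
  for (rep in 1:6) {
    z0 <- rnorm(5); zi <- rnorm(5)
    gamma <- runif(1)
    R <- gamma * sqrt(sum((zi - z0)^2))
    got <- extrapolate_euclidean(zi, z0, gamma)
    want <- ball_min_oracle(zi, z0, R)
    expect_equal(got, want, tolerance = 1e-4)
    ## and it attains the predicted optimal distance
    expect_equal(sqrt(sum((got - zi)^2)),
                 (1 - gamma) * sqrt(sum((zi - z0)^2)), tolerance = 1e-10)
  }
})

test_that("chessboard interpolation identities, hand example, and L1 oracle", {
  z0 <- c(0, 0); zi <- c(3, 1)
  expect_equal(interpolate_linf(zi, z0, 0), z0)
  expect_equal(interpolate_linf(zi, z0, 1), zi)
  expect_equal(interpolate_linf(zi, z0, 0.5), c(1.5, 1))
  expect_error(interpolate_linf(zi, z0, 1.2), "0, 1")
  set.seed(43)
  for (rep in 1:6) {
    a <- rnorm(5); b <- rnorm(5); g <- runif(1)
    Gamma <- g * max(abs(a - b))
    got <- interpolate_linf(a, b, g)
    ## oracle accuracy is limited by its grid resolution
    expect_lt(max(abs(got - box_l1_oracle(a, b, Gamma))),
              max(Gamma / 1000, 1e-9))
    ## feasibility: inside the hypercube
    expect_true(all(abs(got - b) <= Gamma + 1e-12))
  }
})

test_that("interpolation is element-wise between the endpoints and monotone in gamma", {
  set.seed(44)
  a <- rnorm(20); b <- rnorm(20)
  gammas <- seq(0, 1, by = 0.1)
  prev <- NULL
  prev_altered <- Inf
  for (g in gammas) {
    v <- interpolate_linf(a, b, g)
    expect_true(all(v >= pmin(a, b) - 1e-12 & v <= pmax(a, b) + 1e-12))
    if (!is.null(prev)) {
      ## each element moves monotonically from z0 toward z_input
      expect_true(all((v - prev) * sign(a - b) >= -1e-12))
    }
    altered <- sum(v != a)
    expect_lte(altered, prev_altered)
    prev_altered <- altered
    prev <- v
  }
  expect_equal(sum(interpolate_linf(a, b, 1) != a), 0)
})

test_that("final extrapolation amplifies only cropped elements", {
  zi <- c(3, 1); zint <- c(1.5, 1)
  expect_equal(extrapolate_final(zi, zint, 1.2), c(3.3, 1))
  expect_equal(extrapolate_final(zi, zint, 1), zi)
  ## elements untouched by the interpolation remain bit-identical
  set.seed(45)
  a <- rnorm(50); b <- rnorm(50)
  v <- interpolate_linf(a, b, 0.3)
  out <- extrapolate_final(a, v, 1.2)
  same <- v == a
  expect_true(any(same))
  expect_identical(out[same], a[same])
  ## altered fraction equals the fraction beyond the crop width
  Gamma <- 0.3 * max(abs(a - b))
  expect_equal(mean(out != a), mean(abs(a - b) > Gamma))
  expect_error(extrapolate_final(a, v, 0.5), ">= 1")
})

test_that("enhancement parameter validation matches the scheme's constraints", {
  expect_error(enhance_params(gamma = -0.1), ">= 0")
  expect_error(enhance_params(gamma = 1.5, mode = "linf"), "0, 1")
  expect_error(enhance_params(beta = 0.5, mode = "linf"), ">= 1")
  expect_warning(enhance_params(beta = 2.5), "deformation")
  p <- enhance_params()
  expect_equal(p$gamma, 0.2)
  expect_equal(p$beta, 1.2)
  expect_equal(p$mode, "linf")
})

test_that("the full pipeline with beta = 1 is the identity up to round-trip tolerance", {
  fit <- trained_fit()
  rec <- generate_eval_set(phantom_spec(seed = 404L), 1, seed = 405L)[[1]]
  y <- enhance_image(fit$flow, fit$basis, rec$image,
                     enhance_params(beta = 1))
  expect_lt(max(abs(y - rec$image)), 1e-6)
})

test_that("enhancement changes the nodule region more than the rest of the lung", {
  fit <- trained_fit()
  rec <- generate_eval_set(phantom_spec(seed = 406L), 1, seed = 407L)[[1]]
  y <- enhance_image(fit$flow, fit$basis, rec$image)
  dif <- abs(y - rec$image)
  roi <- Reduce(`|`, rec$nodule_masks)
  expect_gt(mean(dif[roi & rec$lung_mask]),
            mean(dif[rec$lung_mask & !roi]))
})

test_that("a basis from a different model is refused", {
  fit <- trained_fit()
  other <- randomized_model(tiny_config(image_size = 32L, n_levels = 2L,
                                        n_steps = 1L))
  set.seed(46)
  Z <- matrix(rnorm(1024 * 5), 1024, 5)
  wrong <- build_hyperplane(Z, model = other)
  rec <- generate_normal(phantom_spec(seed = 408L), 1)[[1]]
  expect_error(enhance_image(fit$flow, wrong, rec$image), "hash mismatch")
})
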