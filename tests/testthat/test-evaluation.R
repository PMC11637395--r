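## brute-force pixel-loop CNR reference
cnr_pixel_loop <- function(img, nodule_mask, lung_mask) {
  nod <- c(); lung <- c()
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img))) {
      if (nodule_mask[i, j]) nod <- c(nod, img[i, j])
      else if (lung_mask[i, j]) lung <- c(lung, img[i, j])
    }
  (mean(nod) - mean(lung)) / sd(lung)
}

make_masks <- function(n = 12) {
  nodule <- matrix(FALSE, n, n); nodule[5:7, 5:7] <- TRUE
  lung <- matrix(FALSE, n, n); lung[2:(n - 1), 2:(n - 1)] <- TRUE
  list(nodule = nodule, lung = lung)
}

test_that("CNR arithmetic: direct cases", {
  m <- make_masks()
  ## nodule mean equals lung mean -> CNR 0
  img <- matrix(rep(c(100, 101), length.out = 144), 12, 12)
  img[m$nodule] <- mean(img[m$lung & !m$nodule])
  expect_equal(compute_cnr(img, m$nodule, m$lung), 0, tolerance = 1e-12)
  ## mu_nodule 150, mu_lung 100, sd_lung 25 -> 2.0
  set.seed(71)
  lungvals <- rnorm(sum(m$lung & !m$nodule))
  lungvals <- (lungvals - mean(lungvals)) / sd(lungvals) * 25 + 100
  img2 <- matrix(0, 12, 12)
  img2[m$lung] <- 0
  img2[m$lung & !m$nodule] <- lungvals
  img2[m$nodule] <- 150
  expect_equal(compute_cnr(img2, m$nodule, m$lung), 2.0)
})

test_that("CNR matches the pixel-loop reference on random images", {
  m <- make_masks()
  set.seed(72)
  for (rep in 1:5) {
    img <- matrix(runif(144, 0, 255), 12, 12)
    expect_equal(compute_cnr(img, m$nodule, m$lung),
                 cnr_pixel_loop(img, m$nodule, m$lung), tolerance = 1e-10)
  }
})

test_that("CNR is invariant under positive affine intensity changes", {
  m <- make_masks()
  set.seed(73)
  img <- matrix(runif(144, 0, 255), 12, 12)
  base <- compute_cnr(img, m$nodule, m$lung)
  for (ab in list(c(2, 10), c(0.3, -40), c(17, 0))) {
    expect_equal(compute_cnr(ab[1] * img + ab[2], m$nodule, m$lung), base,
                 tolerance = 1e-10)
  }
})

test_that("CNR rejects degenerate inputs", {
  m <- make_masks()
  img <- matrix(1, 12, 12)
  expect_error(compute_cnr(img, matrix(FALSE, 12, 12), m$lung), "empty")
  expect_error(compute_cnr(img, m$nodule, matrix(FALSE, 12, 12)), "empty")
  expect_error(compute_cnr(img, m$nodule, m$lung), "variance")
  expect_error(compute_cnr(img[1:6, ], m$nodule, m$lung), "size")
})

test_that("delta CNR: identity, closed-form ROI perturbation, antisymmetry", {
  m <- make_masks()
  set.seed(74)
  img <- matrix(runif(144, 0, 255), 12, 12)
  r0 <- delta_cnr(img, img, m$nodule, m$lung)
  expect_equal(r0$delta, 0)
  expect_equal(r0$delta, r0$cnr_plus - r0$cnr_minus)
  ## +10 inside the ROI only: delta = 10 / sd over the lung field
  enh <- img; enh[m$nodule] <- enh[m$nodule] + 10
  sd_lung <- sd(img[m$lung & !m$nodule])
  r1 <- delta_cnr(img, enh, m$nodule, m$lung)
  expect_equal(r1$delta, 10 / sd_lung, tolerance = 1e-10)
  r2 <- delta_cnr(enh, img, m$nodule, m$lung)
  expect_equal(r2$delta, -r1$delta, tolerance = 1e-12)
  expect_error(delta_cnr(img, img[1:6, ], m$nodule, m$lung), "size")
})

test_that("summaries tally improvements and conserve histogram counts", {
  recs <- data.frame(delta = c(1, -1, 2))
  s <- summarize_evaluation(recs)
  expect_equal(s$fraction_improved, 2 / 3)
  expect_equal(s$n_improved, 2)
  expect_equal(s$mean_delta, 2 / 3)
  expect_equal(sum(s$counts), 3)
  ## bins are width 0.1 centered at zero
  expect_equal(s$bin_width, 0.1)
  expect_true(any(abs(s$breaks - (-0.05)) < 1e-12) ||
                any(abs(s$breaks - 0.05) < 1e-12))
  ## degenerate all-improved set
  expect_equal(summarize_evaluation(data.frame(delta = c(0.1, 0.2)))
               $fraction_improved, 1)
  expect_error(summarize_evaluation(data.frame()), "no records")
  set.seed(75)
  big <- data.frame(delta = rnorm(500))
  expect_equal(sum(summarize_evaluation(big)$counts), 500)
})
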