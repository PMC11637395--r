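## Radiograph preprocessing: window/level intensity normalization to
## [0, 255], geometry standardization to a square model input, and bicubic
## up-sampling of enhanced images for display.

#' Intensity window specification
#'
#' A linear display window: raw intensities in
#' `[center - width/2, center + width/2]` map onto `[0, 255]`; values
#' outside saturate. `window_full_range()` builds the fallback window
#' spanning the observed min/max of an image (used when no window is
#' recorded with the data).
#'
#' @param center,width window center and width in raw intensity units
#'   (`width > 0`).
#' @param source provenance tag: `"explicit"`, `"dicom_tags"` (values taken
#'   from the DICOM window center/width display tags) or `"full_range"`.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(center, width,
                        source = c("explicit", "dicom_tags", "full_range")) {
  if (width <= 0) stop_input("window width must be > 0")
  structure(list(center = as.numeric(center), width = as.numeric(width),
                 source = match.arg(source)),
            class = "window_spec")
}

#' @rdname window_spec
#' @param raw image matrix used to derive the full-range window.
#' @export
window_full_range <- function(raw) {
  rng <- range(raw, finite = TRUE)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1   # constant image: unit width
  window_spec(center = mean(rng), width = diff(rng), source = "full_range")
}

#' Apply an intensity window
#'
#' Linear map of the window interval onto `[0, 255]` with saturation
#' outside; monotone non-decreasing in the raw intensity.
#'
#' @param raw numeric image matrix with finite intensities.
#' @param w a [window_spec()]; if `NULL`, the full observed range is used
#'   (with a message, since that discards the calibrated display window).
#' @return image matrix in `[0, 255]`.
#' @export
window_to_unit_range <- function(raw, w = NULL) {
  check_finite(raw, "raw image")
  if (is.null(w)) {
    message("no window supplied; falling back to full-range scaling")
    w <- window_full_range(raw)
  }
  stopifnot(inherits(w, "window_spec"))
  lo <- w$center - w$width / 2
  clamp((raw - lo) / w$width, 0, 1) * 255
}

## ---- separable resampling kernels --------------------------------------

## area-average (anti-aliased box) weights, n -> m; exact interval overlap
resample_weights_area <- function(n, m) {
  Wm <- matrix(0, m, n)
  r <- n / m
  for (i in seq_len(m)) {
    a <- (i - 1) * r; b <- i * r
    j0 <- floor(a) + 1L; j1 <- ceiling(b)
    for (j in j0:min(j1, n)) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) Wm[i, j] <- ov / r
    }
  }
  Wm
}

resample_weights_bilinear <- function(n, m) {
  Wm <- matrix(0, m, n)
  for (i in seq_len(m)) {
    x <- (i - 0.5) * n / m + 0.5          # 1-based source position
    j0 <- floor(x)
    t <- x - j0
    jl <- clamp(j0, 1L, n); jr <- clamp(j0 + 1L, 1L, n)
    Wm[i, jl] <- Wm[i, jl] + (1 - t)
    Wm[i, jr] <- Wm[i, jr] + t
  }
  Wm
}

## Keys cubic-convolution kernel, a = -0.5 (reproduces linear ramps exactly)
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

resample_weights_bicubic <- function(n, m) {
  Wm <- matrix(0, m, n)
  for (i in seq_len(m)) {
    x <- (i - 0.5) * n / m + 0.5
    j0 <- floor(x)
    for (j in (j0 - 1L):(j0 + 2L)) {
      w <- cubic_kernel(x - j)
      jc <- clamp(j, 1L, n)               # replicate edges
      Wm[i, jc] <- Wm[i, jc] + w
    }
  }
  Wm
}

resample_matrix <- function(img, nr, nc, kernel = c("area", "bilinear",
                                                    "bicubic")) {
  kernel <- match.arg(kernel)
  wfun <- switch(kernel, area = resample_weights_area,
                 bilinear = resample_weights_bilinear,
                 bicubic = resample_weights_bicubic)
  out <- img
  if (nr != nrow(img)) out <- wfun(nrow(img), nr) %*% out
  if (nc != ncol(img)) out <- out %*% t(wfun(ncol(img), nc))
  out
}

## ---- geometry -----------------------------------------------------------

#' Standardize image geometry for the model
#'
#' Rescales so the width equals `target_canvas` pixels (aspect ratio
#' preserved; anti-aliased area averaging when shrinking, bilinear when
#' enlarging), then makes the height `target_canvas` by symmetric
#' truncation of taller images or symmetric zero-padding of shorter ones,
#' and finally down-samples the square canvas to `model_size x model_size`
#' by area averaging. Fully deterministic. The full-scale radiograph chain
#' uses canvas 1024 and model 512; the desk-scale chain uses 64 and 32.
#'
#' @param img numeric image matrix (rows x cols), any aspect ratio.
#' @param target_canvas intermediate square canvas side (pixels).
#' @param model_size final model input side (pixels).
#' @return a `model_size x model_size` matrix.
#' @export
standardize_geometry <- function(img, target_canvas = 64L, model_size = 32L) {
  img <- as.matrix(img)
  if (any(dim(img) == 0L)) stop_input("degenerate (zero-dimension) image")
  h0 <- nrow(img); w0 <- ncol(img)
  new_h <- max(1L, as.integer(round(h0 * target_canvas / w0)))
  kern_w <- if (target_canvas < w0) "area" else "bilinear"
  kern_h <- if (new_h < h0) "area" else "bilinear"
  x <- img
  if (w0 != target_canvas) x <- resample_matrix(x, nrow(x), target_canvas,
                                                kern_w)
  if (new_h != h0) x <- resample_matrix(x, new_h, ncol(x), kern_h)
  if (new_h > target_canvas) {
    top <- (new_h - target_canvas) %/% 2L
    x <- x[top + seq_len(target_canvas), , drop = FALSE]
  } else if (new_h < target_canvas) {
    pad <- matrix(0, target_canvas, target_canvas)
    top <- (target_canvas - new_h) %/% 2L
    pad[top + seq_len(new_h), ] <- x
    x <- pad
  }
  if (model_size != target_canvas)
    x <- resample_matrix(x, model_size, model_size, "area")
  x
}

#' Up-sample an enhanced image for display
#'
#' Bicubic interpolation of a square image to `display_size` per side
#' (the enhanced-image display chain; 512 -> 1024 at full scale).
#'
#' @param img square numeric matrix.
#' @param display_size output side length in pixels.
#' @return a `display_size x display_size` matrix.
#' @export
upsample_output <- function(img, display_size) {
  img <- as.matrix(img)
  if (nrow(img) != ncol(img)) stop_input("input must be square")
  resample_matrix(img, display_size, display_size, "bicubic")
}

## ---- image file IO -------------------------------------------------------

#' Read / write grayscale images
#'
#' PNG and TIFF are supported (8- or 16-bit; multi-channel images are
#' averaged to grayscale). Intensities are returned on the `[0, 255]`
#' scale regardless of bit depth. `write_image()` writes an 8-bit PNG.
#'
#' @param path file path; format chosen by extension.
#' @param img matrix in `[0, 255]`.
#' @return `read_image()`: a numeric matrix in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_input("unsupported image format: .", ext))
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])),
                                         drop = FALSE], c(1, 2), mean)
  a * 255
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp(as.matrix(img), 0, 255) / 255, path)
  invisible(path)
}
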