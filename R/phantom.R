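## Synthetic chest phantoms: a PA-radiograph-like appearance (bright thorax,
## darker lung fields, rib-like periodic bands, a bright mediastinal
## column) with per-image geometric jitter and Gaussian noise, plus
## injectable Gaussian nodules with ground-truth half-maximum ROI masks.
## These phantoms are the canonical fixtures: every stage of the pipeline
## is trainable and testable on them without any image download.

#' Phantom generation parameters
#'
#' @param size image side length in pixels (>= 16).
#' @param n_ribs number of rib-like bands across the lung height.
#' @param rib_contrast peak intensity added by a rib band (intensity units).
#' @param mediastinum_width_frac width of the bright central column as a
#'   fraction of the frame (in (0, 1)).
#' @param noise_sd Gaussian pixel-noise standard deviation (>= 0).
#' @param jitter per-image geometric perturbation scale (fraction of the
#'   frame; 0 disables jitter).
#' @param seed integer seed; generation is bit-reproducible given it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 32L, n_ribs = 5L, rib_contrast = 20,
                         mediastinum_width_frac = 0.22, noise_sd = 4,
                         jitter = 0.04, seed = 1L) {
  if (size < 16L) stop_input("size must be >= 16")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (mediastinum_width_frac <= 0 || mediastinum_width_frac >= 1)
    stop_input("mediastinum_width_frac must be in (0, 1)")
  if (jitter < 0) stop_input("jitter must be >= 0")
  structure(list(size = as.integer(size), n_ribs = as.integer(n_ribs),
                 rib_contrast = as.numeric(rib_contrast),
                 mediastinum_width_frac = as.numeric(mediastinum_width_frac),
                 noise_sd = as.numeric(noise_sd), jitter = as.numeric(jitter),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Nodule injection parameters
#'
#' A nodule is a radially symmetric Gaussian blob; `diameter` is its full
#' width at half maximum, and the ground-truth ROI mask is the half-maximum
#' disc (radius `diameter / 2`).
#'
#' @param center `(row, col)` pixel position of the peak (1-based).
#' @param diameter FWHM in pixels (>= 2).
#' @param contrast intensity added at the peak (units of `[0, 255]`).
#' @param profile blob profile; only `"gaussian"`.
#' @return an object of class `nodule_spec`.
#' @export
nodule_spec <- function(center, diameter, contrast, profile = "gaussian") {
  if (diameter < 2) stop_input("diameter must be >= 2")
  profile <- match.arg(profile, "gaussian")
  structure(list(center = as.numeric(center), diameter = as.numeric(diameter),
                 contrast = as.numeric(contrast), profile = profile),
            class = "nodule_spec")
}

## one jittered phantom; assumes the RNG state is already set by the caller
render_phantom <- function(spec) {
  s <- spec$size
  j <- spec$jitter
  jit <- function(x) x + stats::runif(1, -j, j)
  ## normalized coordinate grids (pixel centers)
  cy <- (row(matrix(0, s, s)) - 0.5) / s
  cx <- (col(matrix(0, s, s)) - 0.5) / s
  inside_ellipse <- function(x0, y0, rx, ry)
    ((cx - x0) / rx)^2 + ((cy - y0) / ry)^2 <= 1

  img <- matrix(40, s, s)                       # background (outside body)
  thorax <- inside_ellipse(jit(0.5), jit(0.52), 0.46, 0.46)
  img[thorax] <- 185                            # soft tissue / bone field
  lung_l <- inside_ellipse(jit(0.30), jit(0.50), 0.155 * (1 + jit(0)),
                           0.30 * (1 + jit(0)))
  lung_r <- inside_ellipse(jit(0.70), jit(0.50), 0.155 * (1 + jit(0)),
                           0.30 * (1 + jit(0)))
  lungs <- (lung_l | lung_r) & thorax
  img[lungs] <- 85                              # air: dark
  ## rib-like periodic bands inside the lungs (brighter overlying bone)
  phase <- stats::runif(1, -j, j)
  bands <- pmax(cos(2 * pi * (spec$n_ribs * (cy + phase) + 0.12 * cx)),
                0)^2
  img[lungs] <- img[lungs] + spec$rib_contrast * bands[lungs]
  ## bright mediastinal column
  med <- abs(cx - 0.5) <= spec$mediastinum_width_frac / 2 & thorax
  img[med] <- 225
  lung_mask <- lungs & !med
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(s * s, sd = spec$noise_sd), s, s)
  img <- clamp(img, 0, 255)
  structure(list(image = img, lung_mask = lung_mask,
                 nodule_masks = list(), nodule_specs = list(), spec = spec),
            class = "phantom_record")
}

#' Generate normal chest phantoms
#'
#' Produces `n` lesion-free phantoms with per-image jittered geometry and
#' Gaussian noise. Bit-reproducible: the same spec (including its seed)
#' always yields identical images.
#'
#' @param spec a [phantom_spec()].
#' @param n number of phantoms (>= 1).
#' @return list of `phantom_record` objects (`image` in `[0, 255]`,
#'   logical `lung_mask`, empty nodule list).
#' @export
generate_normal <- function(spec = phantom_spec(), n = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 1L) stop_input("n must be >= 1")
  set.seed(spec$seed)
  lapply(seq_len(n), function(i) render_phantom(spec))
}

nodule_blob <- function(s, nd) {
  sigma <- nd$diameter / (2 * sqrt(2 * log(2)))
  r2 <- (row(matrix(0, s, s)) - nd$center[1])^2 +
    (col(matrix(0, s, s)) - nd$center[2])^2
  nd$contrast * exp(-r2 / (2 * sigma^2))
}

#' Inject nodules into a phantom
#'
#' Adds each Gaussian blob to the image (clipping to `[0, 255]`) and
#' records the half-maximum disc as the nodule's ROI mask. The input record
#' is not modified. Nodules must lie fully inside the lung field.
#'
#' @param record a `phantom_record` from [generate_normal()].
#' @param nodules list of [nodule_spec()] objects.
#' @return a new `phantom_record` with updated image and appended
#'   `nodule_masks` / `nodule_specs`.
#' @export
inject_nodules <- function(record, nodules) {
  stopifnot(inherits(record, "phantom_record"))
  if (inherits(nodules, "nodule_spec")) nodules <- list(nodules)
  s <- nrow(record$image)
  out <- record
  for (nd in nodules) {
    stopifnot(inherits(nd, "nodule_spec"))
    ctr <- round(nd$center)
    if (any(ctr < 1) || any(ctr > s) ||
        !record$lung_mask[ctr[1], ctr[2]])
      stop_input(sprintf("nodule center (%.0f, %.0f) is outside the lung field",
                         nd$center[1], nd$center[2]))
    blob <- nodule_blob(s, nd)
    roi <- blob >= nd$contrast / 2            # half-maximum disc
    if (nd$contrast == 0)
      roi <- ((row(blob) - nd$center[1])^2 + (col(blob) - nd$center[2])^2) <=
        (nd$diameter / 2)^2
    if (any(roi & !record$lung_mask))
      stop_input("nodule ROI extends outside the lung field")
    out$image <- clamp(out$image + blob, 0, 255)
    out$nodule_masks <- c(out$nodule_masks, list(roi))
    out$nodule_specs <- c(out$nodule_specs, list(nd))
  }
  out
}

## sample a nodule placement whose ROI fits inside the lung mask
sample_nodule <- function(lung_mask, diameter_range, contrast_range,
                          max_tries = 500L) {
  s <- nrow(lung_mask)
  cand <- which(lung_mask, arr.ind = TRUE)
  for (i in seq_len(max_tries)) {
    d <- stats::runif(1, diameter_range[1], diameter_range[2])
    ct <- cand[sample.int(nrow(cand), 1L), ]
    rr <- (row(lung_mask) - ct[1])^2 + (col(lung_mask) - ct[2])^2
    roi <- rr <= (d / 2)^2
    if (!any(roi & !lung_mask))
      return(nodule_spec(center = as.numeric(ct), diameter = d,
                         contrast = stats::runif(1, contrast_range[1],
                                                 contrast_range[2])))
  }
  stop_input("could not place a nodule inside the lung field")
}

#' Generate a nodule evaluation set
#'
#' A reproducible set of phantoms with injected nodules for
#' contrast-to-noise-ratio evaluation. Per-case nodule counts are drawn
#' from `nodules_per_case` (probabilities over counts `1, 2, ...`; the
#' default gives 1.33 nodules per case on average, the density of the
#' clinical evaluation set this mirrors). Sizes and contrasts are drawn
#' uniformly from the given ranges.
#'
#' @param spec a [phantom_spec()] describing the normal anatomy.
#' @param n_cases number of cases (>= 1).
#' @param nodules_per_case probability weights over nodule counts 1..k.
#' @param diameter_range,contrast_range uniform sampling ranges for nodule
#'   FWHM (pixels) and peak contrast (intensity units).
#' @param seed integer seed for the whole set.
#' @return list of `phantom_record`s, each with at least one nodule; the
#'   attached `nodule_specs` serve as the manifest.
#' @export
generate_eval_set <- function(spec = phantom_spec(), n_cases = 50L,
                              nodules_per_case = c(0.70, 0.27, 0.03),
                              diameter_range = c(3, 7),
                              contrast_range = c(20, 40), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_cases < 1L) stop_input("n_cases must be >= 1")
  base_spec <- spec
  base_spec$seed <- derive_seed(seed, 11L)
  cases <- generate_normal(base_spec, n_cases)
  set.seed(derive_seed(seed, 12L))
  counts <- sample.int(length(nodules_per_case), n_cases, replace = TRUE,
                       prob = nodules_per_case)
  lapply(seq_len(n_cases), function(i) {
    nds <- lapply(seq_len(counts[i]), function(k)
      sample_nodule(cases[[i]]$lung_mask, diameter_range, contrast_range))
    rec <- inject_nodules(cases[[i]], nds)
    rec$case_id <- i
    rec
  })
}

#' @export
print.phantom_record <- function(x, ...) {
  cat(sprintf(
    "Chest phantom %dx%d: lung area %.0f%%, %d nodule(s)\n",
    nrow(x$image), ncol(x$image), 100 * mean(x$lung_mask),
    length(x$nodule_masks)))
  invisible(x)
}
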