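## Quantitative evaluation of enhancement: per-nodule contrast-to-noise
## ratio (CNR) before and after enhancement, and summaries of the CNR
## change across an evaluation set.

#' Contrast-to-noise ratio of a nodule
#'
#' `CNR = (mean over the nodule ROI - mean over the lung field) /
#' (standard deviation over the lung field)`. Lung-field statistics are
#' computed over `lung_mask` with the nodule ROI pixels excluded, so a
#' change confined to the ROI leaves the denominator untouched. The ratio
#' is invariant under any positive affine intensity change of the whole
#' image.
#'
#' @param img numeric image matrix.
#' @param nodule_mask,lung_mask logical masks of the same size as `img`;
#'   both non-empty, and the lung field (minus the ROI) must have positive
#'   intensity variance.
#' @return the CNR (unitless scalar).
#' @export
compute_cnr <- function(img, nodule_mask, lung_mask) {
  img <- as.matrix(img)
  if (!any(nodule_mask)) stop_input("empty nodule mask")
  if (!any(lung_mask)) stop_input("empty lung mask")
  if (!all(dim(img) == dim(nodule_mask)) ||
      !all(dim(img) == dim(lung_mask)))
    stop_input("mask size does not match the image")
  lung_eval <- lung_mask & !nodule_mask
  if (sum(lung_eval) < 2L) stop_input("lung field too small outside the ROI")
  sd_lung <- stats::sd(img[lung_eval])
  if (sd_lung == 0) stop_input("zero lung-field variance (degenerate input)")
  (mean(img[nodule_mask]) - mean(img[lung_eval])) / sd_lung
}

#' CNR change between an original and an enhanced image
#'
#' @param original,enhanced image matrices of identical size.
#' @inheritParams compute_cnr
#' @param case_id,nodule_id optional identifiers carried into the record.
#' @return a one-row data frame with `cnr_minus` (original), `cnr_plus`
#'   (enhanced) and `delta = cnr_plus - cnr_minus`.
#' @export
delta_cnr <- function(original, enhanced, nodule_mask, lung_mask,
                      case_id = NA_integer_, nodule_id = NA_integer_) {
  if (!all(dim(as.matrix(original)) == dim(as.matrix(enhanced))))
    stop_input("original and enhanced images differ in size")
  cm <- compute_cnr(original, nodule_mask, lung_mask)
  cp <- compute_cnr(enhanced, nodule_mask, lung_mask)
  data.frame(case_id = case_id, nodule_id = nodule_id,
             cnr_minus = cm, cnr_plus = cp, delta = cp - cm)
}

#' Evaluate enhancement over a set of nodule cases
#'
#' Enhances every case and computes one CNR record per nodule. For
#' multi-nodule cases, each nodule's lung-field statistics exclude *all*
#' nodule ROIs of that case.
#'
#' @param model a trained [flow_model()].
#' @param basis the matching [build_hyperplane()] basis.
#' @param cases list of `phantom_record`s with nodules (or any list with
#'   `image`, `lung_mask`, `nodule_masks`).
#' @param params an [enhance_params()] object.
#' @return a data frame of per-nodule records (class
#'   `eggpale_cnr_records`), plus attribute `"mean_abs_change"` holding the
#'   across-set mean absolute pixel change inside nodule ROIs
#'   (`roi`) and over the lung field outside them (`lung`).
#' @export
evaluate_cases <- function(model, basis, cases, params = enhance_params()) {
  rows <- list()
  chg_roi <- c(); chg_lung <- c()
  for (i in seq_along(cases)) {
    rec <- cases[[i]]
    if (!length(rec$nodule_masks)) next
    enh <- enhance_image(model, basis, rec$image, params)
    all_roi <- Reduce(`|`, rec$nodule_masks)
    lung_free <- rec$lung_mask & !all_roi
    dif <- abs(enh - rec$image)
    chg_roi <- c(chg_roi, dif[all_roi & rec$lung_mask])
    chg_lung <- c(chg_lung, dif[lung_free])
    for (k in seq_along(rec$nodule_masks)) {
      rows[[length(rows) + 1L]] <- delta_cnr(
        rec$image, enh, rec$nodule_masks[[k]],
        rec$lung_mask & !(all_roi & !rec$nodule_masks[[k]]),
        case_id = if (!is.null(rec$case_id)) rec$case_id else i,
        nodule_id = k)
    }
  }
  if (!length(rows)) stop_input("no nodules found in the supplied cases")
  out <- do.call(rbind, rows)
  attr(out, "mean_abs_change") <- c(roi = mean(chg_roi),
                                    lung = mean(chg_lung))
  class(out) <- c("eggpale_cnr_records", class(out))
  out
}

#' Summarize CNR changes over an evaluation set
#'
#' Reports how many nodules improved (`delta > 0`), the mean and median
#' change, and histogram counts on bins of width `bin_width` centered at
#' zero (edges at odd multiples of `bin_width / 2`).
#'
#' @param records data frame with a `delta` column (e.g. from
#'   [evaluate_cases()], or hand-built).
#' @param bin_width histogram bin width (default 0.1).
#' @return an object of class `eggpale_eval_summary` with fields `n`,
#'   `n_improved`, `fraction_improved`, `mean_delta`, `median_delta`,
#'   `breaks`, `counts`.
#' @export
summarize_evaluation <- function(records, bin_width = 0.1) {
  if (!NROW(records)) stop_input("no records to summarize")
  delta <- records$delta
  if (is.null(delta)) stop_input("records must have a 'delta' column")
  half <- bin_width / 2
  lo <- floor((min(delta) + half) / bin_width) * bin_width - half
  hi <- ceiling((max(delta) - half) / bin_width) * bin_width + half
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.vector(table(cut(delta, breaks, include.lowest = TRUE)))
  structure(list(
    n = length(delta), n_improved = sum(delta > 0),
    fraction_improved = mean(delta > 0),
    mean_delta = mean(delta), median_delta = stats::median(delta),
    breaks = breaks, counts = counts, bin_width = bin_width
  ), class = "eggpale_eval_summary")
}

#' @export
print.eggpale_eval_summary <- function(x, ...) {
  cat(sprintf(
    "CNR evaluation over %d nodules: %d improved (%.1f%%)\n",
    x$n, x$n_improved, 100 * x$fraction_improved))
  cat(sprintf("  delta CNR: mean %.3f, median %.3f\n",
              x$mean_delta, x$median_delta))
  invisible(x)
}

#' @export
plot.eggpale_eval_summary <- function(x, ...) {
  graphics::barplot(x$counts,
                    names.arg = sprintf("%.2f",
                                        utils::head(x$breaks, -1) +
                                          x$bin_width / 2),
                    xlab = expression(Delta[CNR]), ylab = "nodules",
                    main = "CNR change after enhancement", ...)
  invisible(x)
}
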