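#' Infarct segmentation result
#'
#' All quantification methods return an `infarct_seg`: a per-voxel weight map
#' in `[0, 1]` on the myocardial mask, its binary support (`weight > 0`), the
#' thresholds the method used, and the derived infarct volume (mL), mass (g)
#' and fraction of LV mass (%).
#'
#' @name infarct_seg
NULL

new_infarct_seg <- function(weights, mask, stack, method, thresholds = list(),
                            details = list()) {
  weights[!mask$mask] <- 0
  weights <- pmin(1, pmax(0, weights))
  dim(weights) <- dim(mask$mask)  # pmin/pmax drop the array dim
  sz <- infarct_size(weights, mask, stack)
  structure(
    list(weights = weights, support = weights > 0, method = method,
         thresholds = thresholds, details = details,
         volume_ml = sz$volume_ml, mass_g = sz$mass_g,
         fraction_pct = sz$fraction_pct,
         lv_mass_g = mask$lv_mass_g, density = mask$density,
         convention = stack$convention),
    class = "infarct_seg"
  )
}

zero_seg <- function(mask, stack, method, thresholds = list(), details = list()) {
  new_infarct_seg(array(0, dim(mask$mask)), mask, stack, method,
                  thresholds, details)
}

#' @export
print.infarct_seg <- function(x, ...) {
  cat(sprintf("<infarct_seg> method '%s' (%s)\n", x$method, x$convention))
  cat(sprintf("  infarct: %.2f mL, %.2f g, %.2f%% of LV mass (LV %.1f g)\n",
              x$volume_ml, x$mass_g, x$fraction_pct, x$lv_mass_g))
  if (length(x$thresholds)) {
    th <- vapply(x$thresholds, function(t) sprintf("%.4g", t), "")
    cat("  thresholds:", paste(names(th), th, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.infarct_seg <- function(object, ...) {
  d <- dim(object$weights)
  per_slice <- vapply(seq_len(d[3L]), function(s) sum(object$weights[, , s]), 0)
  out <- list(method = object$method, fraction_pct = object$fraction_pct,
              volume_ml = object$volume_ml, mass_g = object$mass_g,
              support_voxels = sum(object$support),
              slice_weight_sums = per_slice, thresholds = object$thresholds)
  class(out) <- "summary.infarct_seg"
  out
}

#' @export
print.summary.infarct_seg <- function(x, ...) {
  cat(sprintf("Infarct segmentation, method '%s'\n", x$method))
  cat(sprintf("  %.2f%% of LV mass | %.2f mL | %.2f g | %d support voxels\n",
              x$fraction_pct, x$volume_ml, x$mass_g, x$support_voxels))
  cat("  per-slice weight sums:", paste(sprintf("%.1f", x$slice_weight_sums),
                                        collapse = " "), "\n")
  invisible(x)
}

#' Overlay plot of a segmentation on a slice
#'
#' @param x an `infarct_seg`.
#' @param stack the stack it was computed on.
#' @param slice slice index.
#' @param ... passed to [graphics::image()].
#' @export
plot.infarct_seg <- function(x, stack, slice = 1L, ...) {
  v <- stack$voxels[, , slice]
  graphics::image(t(v)[, nrow(v):1], col = grDevices::gray.colors(128),
                  axes = FALSE, asp = 1,
                  main = sprintf("%s: %.1f%% LV", x$method, x$fraction_pct), ...)
  w <- x$weights[, , slice]
  if (any(w > 0)) {
    ol <- t(w)[, nrow(w):1]
    ol[ol == 0] <- NA
    graphics::image(ol, col = grDevices::hcl.colors(32, "Reds", rev = TRUE,
                                                    alpha = 0.5),
                    add = TRUE)
  }
  invisible(x)
}

#' Quantify infarct size with a named method
#'
#' One front door over the individual `segment_*` engines. Methods `"2sd"`,
#' `"3sd"`, `"5sd"`, `"6sd"` are presets of [segment_nsd()]; `"nsd"` takes an
#' explicit `n`. `"fwhm"` is the ROI-maximum full-width-at-half-maximum
#' variant; `"fact"`, `"heiberg08"`, `"ewa"`, `"otsu"` and `"manual"` map to
#' their engines.
#'
#' @param stack an [lge_stack].
#' @param contours an [lge_contours] (LV wall delineation).
#' @param rois an [lge_rois] with infarct/remote ROIs where the method needs
#'   them (`NULL` otherwise).
#' @param method method name (see Details).
#' @param ... passed to the engine (e.g. `n`, `threshold`, `anchor`, cutoffs).
#' @param density myocardial density g/mL.
#' @param mask optional precomputed [lge_mask] (avoids re-rasterizing).
#' @return an [infarct_seg].
#' @export
quantify_infarct <- function(stack, contours, rois = NULL,
                             method = c("ewa", "fact", "heiberg08", "fwhm",
                                        "2sd", "3sd", "5sd", "6sd", "nsd",
                                        "otsu", "manual"),
                             ..., density = 1.05, mask = NULL) {
  method <- match.arg(method)
  if (is.null(mask)) mask <- rasterize_contours(contours, stack, density = density)
  switch(method,
    "2sd" = segment_nsd(stack, mask, rois, n = 2, ...),
    "3sd" = segment_nsd(stack, mask, rois, n = 3, ...),
    "5sd" = segment_nsd(stack, mask, rois, n = 5, ...),
    "6sd" = segment_nsd(stack, mask, rois, n = 6, ...),
    nsd = segment_nsd(stack, mask, rois, ...),
    fwhm = segment_fwhm(stack, mask, rois, ...),
    otsu = segment_otsu(stack, mask, ...),
    manual = segment_manual(stack, mask, ...),
    fact = segment_fact(stack, contours, mask = mask, density = density, ...),
    heiberg08 = segment_heiberg08(stack, contours, mask = mask,
                                  density = density, ...),
    ewa = segment_ewa(stack, contours, mask = mask, density = density, ...)
  )
}
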