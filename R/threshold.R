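# Purely threshold-based quantifiers: n-SD from remote, FWHM (zero- and
# remote-anchored; ROI-maximum and seed-growing variants), Otsu, manual.
# All intensity comparisons are inclusive (>= threshold), which makes
# uniform-plateau inputs deterministic.

#' n-SD threshold from a remote intensity sample
#'
#' `threshold = mean(remote) + n * sd(remote)` with the sample (n-1) SD.
#'
#' @param remote_values intensities sampled in remote (viable) myocardium.
#' @param n SD multiplier (> 0); the study presets are 2, 3, 5 and 6.
#' @return `list(threshold, remote_mean, remote_sd, n, method)`.
#' @export
nsd_threshold <- function(remote_values, n) {
  if (length(remote_values) < 2L)
    stop("need at least 2 remote values to estimate mean and SD")
  if (n <= 0) stop("the SD multiplier must be positive")
  m <- mean(remote_values)
  s <- stats::sd(remote_values)
  list(threshold = m + n * s, remote_mean = m, remote_sd = s, n = n,
       method = sprintf("%gsd", n))
}

#' Segment by n-SD from remote
#'
#' The remote ROI provides the threshold, which is applied inside the infarct
#' ROI (cropped to the myocardium). If no infarct ROI exists on any slice the
#' infarct size is set to zero, mirroring the handling of cases where no
#' infarct could be visually identified.
#'
#' @param stack an [lge_stack] (IR or PSIR).
#' @param mask an [lge_mask].
#' @param rois an [lge_rois] with at least one remote ROI.
#' @param n SD multiplier.
#' @param pool `"stack"` pools remote statistics over the whole stack (one
#'   threshold); `"slice"` thresholds each slice from its own remote ROI,
#'   falling back to the pooled value where a slice has none.
#' @return an [infarct_seg] with binary weights.
#' @export
segment_nsd <- function(stack, mask, rois, n = 2, pool = c("stack", "slice")) {
  pool <- match.arg(pool)
  remote <- resolve_rois(rois, "remote", stack, mask)
  if (!any(remote)) stop("n-SD from remote requires a non-empty remote ROI")
  method <- sprintf("%gsd", n)
  if (!has_infarct_roi(rois))
    return(zero_seg(mask, stack, method,
                    details = list(reason = "no infarct ROI identified")))
  roi <- resolve_rois(rois, "infarct", stack, mask)
  thr_all <- nsd_threshold(stack$voxels[remote], n)
  w <- array(0, dim(stack$voxels))
  if (pool == "stack") {
    w[roi & stack$voxels >= thr_all$threshold] <- 1
  } else {
    for (s in seq_len(dim(stack$voxels)[3L])) {
      rs <- remote[, , s]
      thr <- if (sum(rs) >= 2L) nsd_threshold(stack$voxels[, , s][rs], n) else thr_all
      sl <- w[, , s]
      sl[roi[, , s] & stack$voxels[, , s] >= thr$threshold] <- 1
      w[, , s] <- sl
    }
  }
  new_infarct_seg(w, mask, stack, method,
                  thresholds = list(threshold = thr_all$threshold,
                                    remote_mean = thr_all$remote_mean,
                                    remote_sd = thr_all$remote_sd))
}

#' Full-width-at-half-maximum threshold
#'
#' Zero-anchored: `threshold = max / 2` (the original formulation, which
#' presumes a magnitude image with the viable myocardium nulled near zero).
#' Remote-anchored: `threshold = remote_mean + (max - remote_mean) / 2`, the
#' halfway point between the remote level and the maximum.
#'
#' @param values_in_roi intensities inside the infarct ROI.
#' @param anchor `"zero"` or `"remote"`.
#' @param remote_mean required when `anchor = "remote"`.
#' @param convention signal convention of the source stack; zero anchoring is
#'   refused for PSIR because its sign assumption (all intensities positive)
#'   does not hold.
#' @param force_psir override the PSIR refusal (downgrades it to a warning),
#'   for studying the failure mode.
#' @return `list(threshold, max, anchor, remote_mean)`.
#' @export
fwhm_threshold <- function(values_in_roi, anchor = c("zero", "remote"),
                           remote_mean = NULL, convention = "IR",
                           force_psir = FALSE) {
  anchor <- match.arg(anchor)
  if (length(values_in_roi) == 0L) stop("empty ROI: no maximum to anchor FWHM")
  mx <- max(values_in_roi)
  if (anchor == "zero") {
    if (convention == "PSIR" || any(values_in_roi < 0)) {
      msg <- paste("zero-anchored FWHM assumes a nulled magnitude image with",
                   "all intensities positive; refusing PSIR/signed input")
      if (!force_psir) stop(msg)
      warning(msg)
    }
    list(threshold = mx / 2, max = mx, anchor = "zero", remote_mean = NULL)
  } else {
    if (is.null(remote_mean)) stop("remote anchoring requires 'remote_mean'")
    list(threshold = remote_mean + (mx - remote_mean) / 2, max = mx,
         anchor = "remote", remote_mean = remote_mean)
  }
}

#' Segment by full-width at half-maximum
#'
#' `variant = "roi_max"` is the study variant: the maximum is located inside
#' the infarct ROI and the half-maximum threshold applied there. No infarct
#' ROI on any slice gives a zero segmentation. `variant = "seed_grow"` is the
#' original formulation: multi-pass region growing from user seeds, accepting
#' 6-connected voxels at or above half of the current region maximum,
#' re-grown until the region is stable (at most `max_passes` passes).
#'
#' @inheritParams segment_nsd
#' @param variant `"roi_max"` or `"seed_grow"`.
#' @param anchor `"zero"` (original) or `"remote"`; remote anchoring takes
#'   the remote mean from the remote ROI.
#' @param per `"stack"` takes one maximum per stack, `"slice"` one per slice.
#' @param seeds for `"seed_grow"`: integer matrix with columns (row, col,
#'   slice) of seed voxels.
#' @param force_psir allow zero anchoring on PSIR input (warning instead of
#'   error), for studying the failure mode.
#' @param max_passes maximum number of re-grow passes.
#' @return an [infarct_seg] with binary weights.
#' @export
segment_fwhm <- function(stack, mask, rois = NULL,
                         variant = c("roi_max", "seed_grow"),
                         anchor = c("zero", "remote"),
                         per = c("stack", "slice"), seeds = NULL,
                         force_psir = FALSE, max_passes = 100L) {
  variant <- match.arg(variant)
  anchor <- match.arg(anchor)
  per <- match.arg(per)
  rmean <- NULL
  if (anchor == "remote") {
    remote <- resolve_rois(rois, "remote", stack, mask)
    if (!any(remote)) stop("remote-anchored FWHM requires a remote ROI")
    rmean <- mean(stack$voxels[remote])
  }
  if (variant == "roi_max") {
    if (!has_infarct_roi(rois))
      return(zero_seg(mask, stack, "fwhm",
                      details = list(reason = "no infarct ROI identified")))
    roi <- resolve_rois(rois, "infarct", stack, mask)
    w <- array(0, dim(stack$voxels))
    if (per == "stack") {
      th <- fwhm_threshold(stack$voxels[roi], anchor, rmean,
                           stack$convention, force_psir)
      w[roi & stack$voxels >= th$threshold] <- 1
      thr <- list(threshold = th$threshold, max = th$max)
    } else {
      thr <- list(threshold = NA_real_, max = NA_real_)
      for (s in seq_len(dim(stack$voxels)[3L])) {
        rs <- roi[, , s]
        if (!any(rs)) next
        th <- fwhm_threshold(stack$voxels[, , s][rs], anchor, rmean,
                             stack$convention, force_psir)
        sl <- w[, , s]
        sl[rs & stack$voxels[, , s] >= th$threshold] <- 1
        w[, , s] <- sl
      }
    }
    return(new_infarct_seg(w, mask, stack, "fwhm",
                           thresholds = c(thr, list(anchor = anchor))))
  }
  # seed-growing variant
  if (is.null(seeds)) stop("seed_grow requires 'seeds' (row, col, slice)")
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  d <- dim(stack$voxels)
  sidx <- (seeds[, 3L] - 1L) * d[1L] * d[2L] + (seeds[, 2L] - 1L) * d[1L] + seeds[, 1L]
  if (!all(mask$mask[sidx])) stop("seed voxel outside the myocardial mask")
  region <- array(FALSE, d)
  region[sidx] <- TRUE
  thr <- NA_real_
  for (pass in seq_len(max_passes)) {
    mx <- max(stack$voxels[region])
    thr <- if (anchor == "zero") {
      if (stack$convention == "PSIR" && !force_psir)
        stop("zero-anchored FWHM assumes all intensities positive; refusing PSIR input")
      mx / 2
    } else rmean + (mx - rmean) / 2
    allowed <- mask$mask & stack$voxels >= thr
    new_region <- flood_fill(sidx, allowed, d)
    if (identical(new_region, region)) break
    region <- new_region
  }
  w <- array(0, d)
  w[region] <- 1
  new_infarct_seg(w, mask, stack, "fwhm_seed",
                  thresholds = list(threshold = thr, anchor = anchor,
                                    passes = pass))
}

# 6-connected flood fill from seed linear indices within 'allowed'.
flood_fill <- function(seed_idx, allowed, d) {
  region <- array(FALSE, d)
  region[seed_idx[allowed[seed_idx]]] <- TRUE
  repeat {
    grown <- dilate6(region, d) & allowed
    if (identical(grown, region)) return(region)
    region <- grown
  }
}

dilate6 <- function(a, d) {
  out <- a
  out[-1L, , ] <- out[-1L, , ] | a[-d[1L], , ]
  out[-d[1L], , ] <- out[-d[1L], , ] | a[-1L, , ]
  out[, -1L, ] <- out[, -1L, ] | a[, -d[2L], ]
  out[, -d[2L], ] <- out[, -d[2L], ] | a[, -1L, ]
  if (d[3L] > 1L) {
    out[, , -1L] <- out[, , -1L] | a[, , -d[3L]]
    out[, , -d[3L]] <- out[, , -d[3L]] | a[, , -1L]
  }
  out
}

#' Otsu threshold
#'
#' Maximizes the between-class variance over cuts placed at the sorted
#' distinct values (classes `< t` and `>= t`); ties resolve to the lowest
#' threshold.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return `list(threshold, between_var)`.
#' @export
otsu_threshold <- function(values) {
  v <- sort(values)
  u <- unique(v)
  if (length(u) < 2L)
    stop("Otsu needs at least two distinct values (no bimodal split in constant input)")
  n <- length(v)
  # candidate thresholds: each distinct value except the smallest; class
  # split is {v < t} vs {v >= t}
  cnt <- tabulate(match(v, u), nbins = length(u))
  csum <- cumsum(cnt * u)
  cn <- cumsum(cnt)
  total <- csum[length(u)]
  # cut after distinct value k (threshold = u[k+1]): lower class = 1..k
  k <- seq_len(length(u) - 1L)
  n0 <- cn[k]; n1 <- n - n0
  m0 <- csum[k] / n0
  m1 <- (total - csum[k]) / n1
  bv <- n0 / n * n1 / n * (m0 - m1)^2
  best <- which.max(bv)  # which.max returns the first (lowest) maximizer
  list(threshold = u[best + 1L], between_var = bv[best])
}

#' Segment by Otsu auto-thresholding
#'
#' Splits the pooled myocardial intensities into two classes; by design it
#' always finds an "infarct" class, even in infarct-free myocardium.
#'
#' @inheritParams segment_nsd
#' @return an [infarct_seg] with binary weights.
#' @export
segment_otsu <- function(stack, mask) {
  th <- otsu_threshold(stack$voxels[mask$mask])
  w <- array(0, dim(stack$voxels))
  w[mask$mask & stack$voxels >= th$threshold] <- 1
  new_infarct_seg(w, mask, stack, "otsu",
                  thresholds = list(threshold = th$threshold))
}

#' Segment by a manual threshold
#'
#' @inheritParams segment_nsd
#' @param threshold finite intensity threshold applied inside the myocardium.
#' @return an [infarct_seg] with binary weights.
#' @export
segment_manual <- function(stack, mask, threshold) {
  if (!is.finite(threshold)) stop("manual threshold must be finite")
  w <- array(0, dim(stack$voxels))
  w[mask$mask & stack$voxels >= threshold] <- 1
  new_infarct_seg(w, mask, stack, "manual",
                  thresholds = list(threshold = threshold))
}
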