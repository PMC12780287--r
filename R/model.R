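# Composite algorithms (FACT, Heiberg-08, EWA) and their shared machinery:
# automatic remote detection, surface coil correction, two-Gaussian EM,
# artifact cleanup, small-component removal and MVO inclusion.

#' Automatic remote-myocardium estimate
#'
#' Each slice is split into `n_sectors` angular sectors; the midmural half of
#' the sector with the lowest mean signal intensity is taken as remote on that
#' slice, and the selected voxels are pooled over the stack.
#'
#' @param stack an [lge_stack].
#' @param mask an [lge_mask].
#' @param contours the [lge_contours] used to build `mask`.
#' @param n_sectors number of angular sectors.
#' @param sd_warn_frac warn when the pooled remote SD exceeds this fraction
#'   of the myocardial intensity range (a contaminated remote, e.g. when the
#'   infarct is circumferential).
#' @return `list(mean, sd, idx, sectors)` where `idx` are the pooled voxel
#'   indices and `sectors` the selected sector per slice.
#' @export
estimate_remote_auto <- function(stack, mask, contours, n_sectors = 5L,
                                 sd_warn_frac = 0.2) {
  if (!any(mask$mask)) stop("empty myocardial mask: cannot estimate remote")
  lab <- sector_partition(mask, stack, n_sectors = n_sectors)
  band <- midmural_band(mask, contours, stack)
  d <- dim(mask$mask)
  idx <- integer(0)
  sectors <- rep(NA_integer_, d[3L])
  for (s in seq_len(d[3L])) {
    bs <- band[, , s]
    if (!any(bs)) next
    ls <- lab[, , s]
    vs <- stack$voxels[, , s]
    means <- vapply(seq_len(n_sectors), function(k) {
      sel <- bs & !is.na(ls) & ls == k
      if (any(sel)) mean(vs[sel]) else NA_real_
    }, 0)
    if (all(is.na(means))) next
    k <- which.min(means)
    sectors[s] <- k
    sel <- which(bs & !is.na(ls) & ls == k)
    idx <- c(idx, (s - 1L) * d[1L] * d[2L] + sel)
  }
  vals <- stack$voxels[idx]
  out <- list(mean = mean(vals), sd = stats::sd(vals), idx = idx,
              sectors = sectors)
  rng <- diff(range(stack$voxels[mask$mask]))
  if (rng > 0 && is.finite(out$sd) && out$sd > sd_warn_frac * rng)
    warning(sprintf(paste("automatic remote estimate looks contaminated:",
                          "SD %.3g exceeds %.0f%% of the myocardial intensity range"),
                    out$sd, 100 * sd_warn_frac))
  out
}

#' Surface coil intensity correction
#'
#' Estimates a smooth multiplicative bias field from the myocardial
#' intensities -- a low-order polynomial fit to the log-magnitude with
#' iterative down-weighting of high residuals, so enhanced infarct does not
#' drag the field -- and divides it out, preserving the myocardial median.
#' Non-positive intensities (PSIR, or zeros under IR) are handled by shifting
#' the fit domain; the shift is removed after division.
#'
#' @param stack an [lge_stack].
#' @param mask an [lge_mask] (fit support).
#' @param degree total polynomial degree of the in-plane field (default
#'   linear; a linear term in slice position is always included). Higher
#'   degrees can extrapolate into the infarct sector and absorb true
#'   enhancement as coil gain.
#' @param iterations robust reweighting iterations.
#' @return the corrected [lge_stack] with the estimated `field` attached as
#'   an attribute.
#' @export
coil_correction <- function(stack, mask, degree = 1L, iterations = 10L) {
  if (!any(mask$mask)) stop("empty myocardial mask: cannot fit a bias field")
  d <- dim(stack$voxels)
  g <- grid_xy(stack)
  idx <- which(mask$mask)
  ai <- arrayInd(idx, d)
  v <- stack$voxels[idx]
  shift <- if (min(v) <= 0) -min(v) + 0.05 * max(diff(range(v)), 1) else 0
  lv <- log(v + shift)
  # scaled coordinates in [-1, 1]
  sc <- function(u, n, sp) (u - (n - 1) * sp / 2) / pmax((n - 1) * sp / 2, 1)
  px <- sc(g$x[cbind(ai[, 1L], ai[, 2L])], d[2L], stack$spacing[2L])
  py <- sc(g$y[cbind(ai[, 1L], ai[, 2L])], d[1L], stack$spacing[1L])
  pz <- if (d[3L] > 1L) (ai[, 3L] - (d[3L] + 1) / 2) / ((d[3L] - 1) / 2) else rep(0, length(idx))
  terms <- list(rep(1, length(idx)))
  for (i in 0:degree) for (j in 0:degree) {
    if (i + j >= 1L && i + j <= degree) terms <- c(terms, list(px^i * py^j))
  }
  if (d[3L] > 1L) terms <- c(terms, list(pz))
  X <- do.call(cbind, terms)
  # Initial residuals from a flat (median) field so the coherent bright
  # infarct starts as an outlier and cannot tilt the first fit.  The robust
  # scale is frozen at this initial estimate (re-estimating it lets the field
  # creep into the enhanced sector) and is taken from the *negative* residual
  # side only: enhancement contaminates the positive side, the negative side
  # is remote noise plus a thin dark partial-volume rim.
  r0 <- lv - stats::median(lv)
  neg <- r0[r0 <= 0]
  s0 <- if (length(neg) >= 10L) 1.4826 * stats::median(abs(neg)) else stats::mad(r0)
  s0 <- max(s0, 1e-6)
  bisquare <- function(r) {
    u <- r / (3 * s0)
    ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  wgt <- bisquare(r0)
  if (all(wgt == 0)) wgt <- rep(1, length(lv))
  beta <- NULL
  for (it in seq_len(iterations)) {
    fit <- stats::lm.wfit(X, lv, wgt)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    r <- as.vector(lv - X %*% beta)
    wgt <- bisquare(r)
    if (all(wgt == 0)) { wgt <- rep(1, length(lv)); break }
  }
  # evaluate the field everywhere, anchored to mean log level over the mask
  gx <- matrix(sc(g$x, d[2L], stack$spacing[2L]), d[1L], d[2L])
  gy <- matrix(sc(g$y, d[1L], stack$spacing[1L]), d[1L], d[2L])
  field <- array(1, d)
  base <- sum(beta * colMeans(X * wgt) / mean(wgt))
  for (s in seq_len(d[3L])) {
    z <- if (d[3L] > 1L) (s - (d[3L] + 1) / 2) / ((d[3L] - 1) / 2) else 0
    lf <- matrix(beta[1L], d[1L], d[2L])
    k <- 1L
    for (i in 0:degree) for (j in 0:degree) {
      if (i + j >= 1L && i + j <= degree) {
        k <- k + 1L
        lf <- lf + beta[k] * gx^i * gy^j
      }
    }
    if (d[3L] > 1L) lf <- lf + beta[k + 1L] * z
    field[, , s] <- exp(lf - base)
  }
  corrected <- (stack$voxels + shift) / field - shift
  med0 <- stats::median(stack$voxels[idx])
  med1 <- stats::median(corrected[idx])
  if (shift == 0 && med1 > 0) {
    corrected <- corrected * med0 / med1
  } else {
    corrected <- corrected + (med0 - med1)
  }
  if (stack$convention == "IR") corrected[corrected < 0] <- 0
  out <- lge_stack(corrected, spacing = stack$spacing,
                   thickness = stack$thickness, convention = stack$convention)
  attr(out, "field") <- field
  out
}

#' Two-component Gaussian mixture by expectation maximization
#'
#' Standard EM for a two-class Gaussian mixture with an ordering constraint
#' (`mean_infarct > mean_normal`) and an SD floor. Convergence when the
#' log-likelihood gain falls below `tol` or after `max_iter` iterations.
#'
#' @param values numeric vector (>= 10 values, not all equal).
#' @param init `"otsu_split"` initializes from the Otsu cut; or a numeric
#'   vector `c(mean_normal, mean_infarct)`.
#' @param max_iter,tol stopping rule.
#' @param sd_floor lower bound on both SDs; default `1e-3` of the value
#'   range.
#' @return an object of class `gmm2` with fields `mean_normal`, `sd_normal`,
#'   `mean_infarct`, `sd_infarct`, `lambda` (infarct mixing weight),
#'   `loglik` (trace), `iterations`, `converged`.
#' @export
em_two_gaussians <- function(values, init = "otsu_split", max_iter = 200L,
                             tol = 1e-8, sd_floor = NULL) {
  v <- as.numeric(values)
  if (length(v) < 10L) stop("EM needs at least 10 values")
  rng <- diff(range(v))
  if (rng == 0) stop("degenerate input: all values equal")
  if (is.null(sd_floor)) sd_floor <- 1e-3 * rng
  if (identical(init, "otsu_split")) {
    cut <- otsu_threshold(v)$threshold
    lo <- v[v < cut]; hi <- v[v >= cut]
    m <- c(mean(lo), mean(hi))
    s <- pmax(c(stats::sd(lo), stats::sd(hi)), sd_floor, na.rm = TRUE)
    lam <- length(hi) / length(v)
  } else {
    m <- sort(as.numeric(init))
    s <- rep(max(rng / 10, sd_floor), 2L)
    lam <- 0.5
  }
  s[is.na(s)] <- sd_floor
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step in log space
    l1 <- log1p(-lam) + stats::dnorm(v, m[1L], s[1L], log = TRUE)
    l2 <- log(lam) + stats::dnorm(v, m[2L], s[2L], log = TRUE)
    mx <- pmax(l1, l2)
    ll <- sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
    ll_trace <- c(ll_trace, ll)
    g2 <- 1 / (1 + exp(l1 - l2))
    if (is.finite(ll) && ll - ll_old < tol && it > 1L) { converged <- TRUE; break }
    ll_old <- ll
    # M-step
    n2 <- sum(g2); n1 <- length(v) - n2
    if (n2 < 1e-8 || n1 < 1e-8) break
    lam <- n2 / length(v)
    m <- c(sum((1 - g2) * v) / n1, sum(g2 * v) / n2)
    s <- c(sqrt(sum((1 - g2) * (v - m[1L])^2) / n1),
           sqrt(sum(g2 * (v - m[2L])^2) / n2))
    s <- pmax(s, sd_floor)
    if (m[1L] > m[2L]) {  # enforce ordering by relabeling
      m <- rev(m); s <- rev(s); lam <- 1 - lam
    }
  }
  structure(
    list(mean_normal = m[1L], sd_normal = s[1L],
         mean_infarct = m[2L], sd_infarct = s[2L], lambda = lam,
         loglik = ll_trace, iterations = it, converged = converged,
         n = length(v)),
    class = "gmm2"
  )
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf("<gmm2> normal N(%.3g, %.3g), infarct N(%.3g, %.3g), lambda %.3f\n",
              x$mean_normal, x$sd_normal, x$mean_infarct, x$sd_infarct,
              x$lambda))
  cat(sprintf("  logLik %.4f after %d iteration(s)%s\n",
              utils::tail(x$loglik, 1L), x$iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
logLik.gmm2 <- function(object, ...) {
  structure(utils::tail(object$loglik, 1L), df = 5L, nobs = object$n,
            class = "logLik")
}

# Posterior probability of the infarct class.
gmm2_posterior <- function(fit, v) {
  l1 <- log1p(-fit$lambda) + stats::dnorm(v, fit$mean_normal, fit$sd_normal, log = TRUE)
  l2 <- log(fit$lambda) + stats::dnorm(v, fit$mean_infarct, fit$sd_infarct, log = TRUE)
  p <- 1 / (1 + exp(l1 - l2))
  # both densities can underflow far from either mean: fall back to the
  # nearer mean (scaled by its SD)
  und <- !is.finite(l1 - l2)
  if (any(und)) {
    z1 <- abs(v[und] - fit$mean_normal) / fit$sd_normal
    z2 <- abs(v[und] - fit$mean_infarct) / fit$sd_infarct
    p[und] <- as.numeric(z2 < z1)
  }
  p
}

#' Include microvascular obstruction in a binary support
#'
#' Hypointense myocardial components whose in-plane boundary touches only
#' infarct voxels and/or the endocardial border are added with weight 1
#' (MVO is infarct). Components reaching the epicardial border are left
#' alone.
#'
#' @param support logical array of infarct support.
#' @param mask an [lge_mask].
#' @param contours the matching [lge_contours].
#' @param stack the [lge_stack].
#' @return the augmented logical support.
#' @export
include_mvo <- function(support, mask, contours, stack) {
  d <- dim(support)
  holes <- mask$mask & !support
  if (!any(holes)) return(support)
  lab <- label_components(holes)
  g <- grid_xy(stack)
  out <- support
  for (k in seq_len(max(lab))) {
    ci <- which(lab == k)
    ok <- TRUE
    ai <- arrayInd(ci, d)
    for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      r2 <- ai[, 1L] + sh[1L]; c2 <- ai[, 2L] + sh[2L]
      inb <- r2 >= 1L & r2 <= d[1L] & c2 >= 1L & c2 <= d[2L]
      if (!all(inb)) { ok <- FALSE; break }
      lin <- (ai[, 3L] - 1L) * d[1L] * d[2L] + (c2 - 1L) * d[1L] + r2
      nb_out <- !holes[lin]
      if (!any(nb_out)) next
      lin_o <- lin[nb_out]
      # neighbor must be infarct support, or off-mask *inside* the
      # endocardial contour
      bad <- !support[lin_o] & !mask$mask[lin_o]
      if (any(bad)) {
        bi <- lin_o[bad]
        sl <- ceiling(bi / (d[1L] * d[2L]))
        in_endo <- vapply(seq_along(bi), function(q) {
          endo <- contours$slices[[sl[q]]]$endo
          if (is.null(endo)) return(FALSE)
          rc <- arrayInd(bi[q], d)
          point_in_polygon(g$x[rc[1L], rc[2L]], g$y[rc[1L], rc[2L]], endo)
        }, NA)
        if (!all(in_endo)) { ok <- FALSE; break }
      }
      if (any(support[lin_o] == FALSE & mask$mask[lin_o])) {
        # masked non-infarct neighbor outside the hole cannot occur in-plane
        # (it would be part of the same component); defensive
        ok <- FALSE; break
      }
    }
    if (ok) out[ci] <- TRUE
  }
  out
}

#' Remove small connected components
#'
#' Components strictly below the cutoff are dropped; a component exactly at
#' the cutoff is retained.
#'
#' @param support logical array.
#' @param stack an [lge_stack].
#' @param min_mass_g minimal component mass in g (used with `density`).
#' @param min_volume_ml alternatively, minimal component volume in mL
#'   (overrides `min_mass_g` when given).
#' @param density g/mL.
#' @return the filtered logical support.
#' @export
remove_small_components <- function(support, stack, min_mass_g = NULL,
                                    min_volume_ml = NULL, density = 1.05) {
  comps <- connected_components(support, stack, density = density)
  if (!length(comps)) return(support)
  out <- array(FALSE, dim(support))
  for (cp in comps) {
    keep <- if (!is.null(min_volume_ml)) cp$volume_ml >= min_volume_ml
            else cp$mass_g >= min_mass_g
    if (keep) out[cp$idx] <- TRUE
  }
  out
}

# Level-set stand-in for "exclusion of dis-contiguous artifacts": keep the
# largest component plus any component above a mass floor, then one
# morphological opening-closing pass in-plane (constrained to the mask).
artifact_cleanup <- function(support, stack, mask, mass_floor_g = 0.1,
                             density = 1.05, morph = TRUE) {
  if (!any(support)) return(support)
  comps <- connected_components(support, stack, density = density)
  sizes <- vapply(comps, `[[`, 0, "n")
  out <- array(FALSE, dim(support))
  for (i in seq_along(comps)) {
    if (i == which.max(sizes) || comps[[i]]$mass_g >= mass_floor_g)
      out[comps[[i]]$idx] <- TRUE
  }
  if (morph) {
    d <- dim(out)
    for (s in seq_len(d[3L])) {
      sl <- out[, , s, drop = FALSE]; dim(sl) <- c(d[1:2], 1L)
      m <- mask$mask[, , s, drop = FALSE]; dim(m) <- c(d[1:2], 1L)
      opened <- dilate6(erode4(sl), dim(sl)) & sl  # opening, kept within sl
      closed <- erode4(dilate6(opened, dim(sl))) | opened  # then closing
      out[, , s] <- (closed & m)[, , 1L]
    }
  }
  out
}

erode4 <- function(a) {
  d <- dim(a)
  up <- a; up[-d[1L], , ] <- a[-1L, , ]; up[d[1L], , ] <- FALSE
  dn <- a; dn[-1L, , ] <- a[-d[1L], , ]; dn[1L, , ] <- FALSE
  lf <- a; lf[, -d[2L], ] <- a[, -1L, ]; lf[, d[2L], ] <- FALSE
  rt <- a; rt[, -1L, ] <- a[, -d[2L], ]; rt[, 1L, ] <- FALSE
  a & up & dn & lf & rt
}

# FACT feature filters, exposed for testing: keep candidate components with
# (i) mass at or above `min_mass_g` (strictly smaller removed), (ii) minimum
# endocardial distance at most `max_endo_dist_mm`, and (iii) mean intensity
# at least `intensity_frac` of the pooled mean over all candidate voxels.

#' FACT feature filters over candidate components
#'
#' @param support logical array of candidate voxels.
#' @param stack an [lge_stack].
#' @param mask an [lge_mask].
#' @param endo_dist array from [endocardial_distance()].
#' @param min_mass_g volume filter cutoff (components strictly below are
#'   removed).
#' @param max_endo_dist_mm maximal distance of a component from the
#'   endocardium.
#' @param intensity_frac minimal component mean intensity as a fraction of
#'   the pooled candidate mean.
#' @return filtered logical support.
#' @export
fact_feature_filter <- function(support, stack, mask, endo_dist,
                                min_mass_g = 0.1, max_endo_dist_mm = 2,
                                intensity_frac = 0.5) {
  if (!any(support)) return(support)
  comps <- connected_components(support, stack, density = mask$density,
                                endo_dist = endo_dist)
  pooled_mean <- mean(stack$voxels[support])
  out <- array(FALSE, dim(support))
  for (cp in comps) {
    if (cp$mass_g < min_mass_g) next
    if (!is.finite(cp$min_endo_dist) || cp$min_endo_dist > max_endo_dist_mm) next
    if (cp$mean_intensity < intensity_frac * pooled_mean) next
    out[cp$idx] <- TRUE
  }
  out
}

#' FACT: feature analysis and combined thresholding
#'
#' Fully automatic pipeline using only the LV contours (IR or PSIR):
#' initial candidates at 2 SD above the automatically detected remote mean;
#' feature filters (component mass >= 0.1 g, within 2 mm of the endocardium,
#' mean intensity >= 50% of the pooled candidate mean); a remote-anchored
#' FWHM threshold inside the surviving candidates; the filters re-applied;
#' and MVO inclusion. Binary weights.
#'
#' @param stack an [lge_stack].
#' @param contours an [lge_contours].
#' @param mask optional precomputed [lge_mask].
#' @param nsd initial threshold multiplier (SDs above remote).
#' @param min_mass_g,max_endo_dist_mm,intensity_frac feature-filter cutoffs.
#' @param density g/mL.
#' @return an [infarct_seg].
#' @export
segment_fact <- function(stack, contours, mask = NULL, nsd = 2,
                         min_mass_g = 0.1, max_endo_dist_mm = 2,
                         intensity_frac = 0.5, density = 1.05) {
  if (is.null(mask)) mask <- rasterize_contours(contours, stack, density)
  remote <- estimate_remote_auto(stack, mask, contours)
  thr1 <- remote$mean + nsd * remote$sd
  cand <- mask$mask & stack$voxels >= thr1
  ed <- endocardial_distance(mask, contours, stack)
  thresholds <- list(initial = thr1, remote_mean = remote$mean,
                     remote_sd = remote$sd)
  cand <- fact_feature_filter(cand, stack, mask, ed, min_mass_g,
                              max_endo_dist_mm, intensity_frac)
  if (!any(cand))
    return(zero_seg(mask, stack, "fact", thresholds,
                    details = list(reason = "no candidate survived the feature filters")))
  mx <- max(stack$voxels[cand])
  thr2 <- remote$mean + (mx - remote$mean) / 2
  thresholds$fwhm <- thr2
  supp <- cand & stack$voxels >= thr2
  supp <- fact_feature_filter(supp, stack, mask, ed, min_mass_g,
                              max_endo_dist_mm, intensity_frac)
  supp <- include_mvo(supp, mask, contours, stack)
  w <- array(0, dim(stack$voxels))
  w[supp] <- 1
  new_infarct_seg(w, mask, stack, "fact", thresholds)
}

#' Heiberg-08: sector-based remote with weighted infarct size
#'
#' IR only (the method presumes a nulled magnitude image). Automatic remote
#' detection, thresholding at `remote_mean + 1.8 SD`, artifact cleanup,
#' removal of isolated volumes below 1.5 cm^3, MVO inclusion, and linear
#' intensity weighting `w = clip((I - remote_mean) / (I_max - remote_mean),
#' 0, 1)` on the surviving support (MVO voxels weigh 1).
#'
#' @inheritParams segment_fact
#' @param nsd threshold multiplier above remote.
#' @param min_volume_cm3 isolated-volume removal cutoff (cm^3).
#' @param morph run the in-plane opening-closing cleanup pass.
#' @return an [infarct_seg] with weighted voxels.
#' @export
segment_heiberg08 <- function(stack, contours, mask = NULL, nsd = 1.8,
                              min_volume_cm3 = 1.5, morph = TRUE,
                              density = 1.05) {
  if (stack$convention == "PSIR")
    stop("Heiberg-08 was not designed for PSIR images (it assumes a nulled, all-positive myocardium); refusing PSIR input")
  if (is.null(mask)) mask <- rasterize_contours(contours, stack, density)
  remote <- estimate_remote_auto(stack, mask, contours)
  thr <- remote$mean + nsd * remote$sd
  supp <- mask$mask & stack$voxels >= thr
  supp <- artifact_cleanup(supp, stack, mask, density = density, morph = morph)
  # 1 cm^3 == 1 mL
  supp <- remove_small_components(supp, stack, min_volume_ml = min_volume_cm3,
                                  density = density)
  # only voxels that will carry positive weight count as infarct when probing
  # for enclosed MVO; at SD = 0 the threshold equals the remote mean and the
  # raw support also contains weight-zero remote voxels
  supp_enh <- supp & stack$voxels > remote$mean
  supp_mvo <- include_mvo(supp_enh, mask, contours, stack)
  mvo_added <- supp_mvo & !supp_enh & !supp
  imax <- max(stack$voxels[mask$mask])
  w <- array(0, dim(stack$voxels))
  if (imax > remote$mean)
    w[supp] <- pmin(1, pmax(0, (stack$voxels[supp] - remote$mean) /
                                 (imax - remote$mean)))
  w[mvo_added] <- 1
  new_infarct_seg(w, mask, stack, "heiberg08",
                  thresholds = list(threshold = thr, remote_mean = remote$mean,
                                    remote_sd = remote$sd, i_max = imax))
}

#' EWA: expectation maximization, weighted intensity, a priori information
#'
#' Fully automatic, IR or PSIR: surface coil correction, a two-Gaussian EM
#' fit of the myocardial intensities, posterior classification
#' (infarct if posterior > 0.5), artifact cleanup and small-component
#' removal, MVO inclusion, and linear intensity weighting between the two
#' class means on the retained support (MVO voxels weigh 1). If the two
#' fitted classes are not separated (no infarct evidence) the infarct size
#' is zero.
#'
#' @inheritParams segment_fact
#' @param coil run surface coil intensity correction first.
#' @param min_mass_g small-component cutoff (g).
#' @param separation_factor classes count as separated when the mean gap
#'   exceeds this multiple of the smaller class SD (the infarct-class SD is
#'   routinely inflated by partial-volume voxels, so the smaller SD is the
#'   informative one).
#' @param morph run the in-plane opening-closing cleanup pass.
#' @return an [infarct_seg] with weighted voxels.
#' @export
segment_ewa <- function(stack, contours, mask = NULL, coil = TRUE,
                        min_mass_g = 0.1, separation_factor = 4,
                        morph = TRUE, density = 1.05) {
  if (is.null(mask)) mask <- rasterize_contours(contours, stack, density)
  work <- if (coil) coil_correction(stack, mask) else stack
  vals <- work$voxels[mask$mask]
  fit <- tryCatch(em_two_gaussians(vals), error = function(e) NULL)
  if (is.null(fit)) {
    warning("EWA: degenerate myocardial intensities, no infarct evidence; size set to zero")
    return(zero_seg(mask, stack, "ewa"))
  }
  gap <- fit$mean_infarct - fit$mean_normal
  if (gap < separation_factor * min(fit$sd_normal, fit$sd_infarct)) {
    warning("EWA: mixture classes not separated, no infarct evidence; size set to zero")
    return(zero_seg(mask, stack, "ewa",
                    details = list(fit = fit, reason = "classes not separated")))
  }
  post <- array(0, dim(work$voxels))
  post[mask$mask] <- gmm2_posterior(fit, vals)
  supp <- mask$mask & post > 0.5
  supp <- artifact_cleanup(supp, work, mask, mass_floor_g = min_mass_g,
                           density = density, morph = morph)
  supp <- remove_small_components(supp, work, min_mass_g = min_mass_g,
                                  density = density)
  supp_mvo <- include_mvo(supp, mask, contours, work)
  mvo_added <- supp_mvo & !supp
  w <- array(0, dim(work$voxels))
  w[supp] <- pmin(1, pmax(0, (work$voxels[supp] - fit$mean_normal) / gap))
  w[mvo_added] <- 1
  new_infarct_seg(w, mask, stack, "ewa",
                  thresholds = list(mean_normal = fit$mean_normal,
                                    mean_infarct = fit$mean_infarct,
                                    sd_normal = fit$sd_normal,
                                    sd_infarct = fit$sd_infarct),
                  details = list(fit = fit, coil = coil))
}
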