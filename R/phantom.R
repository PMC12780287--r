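#' Specification of a synthetic short-axis LGE phantom
#'
#' Describes an annular myocardial wall over several slices with a bright
#' infarct sector of configurable angular extent and transmurality, optional
#' patchy (insular) morphology, an optional hypointense microvascular
#' obstruction (MVO) core, an optional edema halo, a multiplicative coil
#' sensitivity ramp, and Rician (IR) or Gaussian (PSIR) measurement noise.
#' Per-voxel intensities are partial-volume mixtures of the class means
#' obtained by in-plane supersampling; the same supersampling yields the
#' ground-truth infarct weights.
#'
#' The defaults emulate a typical short-axis acquisition: 8 slices of
#' 1.5 x 1.5 mm pixels, 8 mm slice thickness with no gap, endocardial radius
#' 20 mm and epicardial radius 30 mm. IR intensities put viable (remote)
#' myocardium near the nulled level, well below the enhanced infarct; PSIR
#' defaults make the remote mean negative (-0.2 x infarct mean) to exercise
#' signed-signal behavior.
#'
#' @param n_slices number of slices.
#' @param spacing in-plane spacing mm (length 2 or scalar).
#' @param thickness slice thickness mm.
#' @param grid in-plane grid size (pixels per side).
#' @param endo_radius,epi_radius wall radii in mm (scalar, or per-slice
#'   vectors to taper the wall).
#' @param extent_deg angular extent of the infarct wedge, degrees in
#'   `[0, 360)`.
#' @param start_deg angular start of the wedge (counter-clockwise from +x).
#' @param transmurality fraction of wall thickness occupied by infarct,
#'   endocardium outward, in `(0, 1]`.
#' @param morphology `"solid"` or `"patchy"`.
#' @param patch_density,patch_radius patchy morphology: expected fraction of
#'   the wedge covered by insular patches, and patch radius in mm.
#' @param mvo_fraction transmural fraction of the wedge occupied by a
#'   hypointense MVO core (0 disables); the core sits subendocardially in the
#'   angular middle of the wedge.
#' @param mvo_angular_fraction angular share of the wedge taken by the core.
#' @param remote_mean,remote_sd viable-myocardium intensity mean/SD; `NULL`
#'   mean defaults to 20 (IR) or `-0.2 * infarct_mean` (PSIR).
#' @param infarct_mean,infarct_sd infarct intensity mean/SD.
#' @param mvo_mean MVO core intensity mean.
#' @param cavity_mean blood-pool intensity mean (default 0: the phantom
#'   models the wall classes only; set it high to study bright-blood
#'   partial-volume effects at the endocardial border).
#' @param background_mean air intensity mean.
#' @param edema_width_mm width of an edema halo around the wedge (0 = none).
#' @param edema_mean halo intensity, between remote and infarct means.
#' @param coil_amplitude total relative variation of a linear multiplicative
#'   coil ramp across the field of view (0 = uniform).
#' @param convention `"IR"` (magnitude, Rician noise) or `"PSIR"` (signed,
#'   Gaussian noise).
#' @param noise `"auto"` picks Rician for IR and Gaussian for PSIR.
#' @param supersample in-plane supersampling factor for partial-volume
#'   mixing and truth weights.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 8L, spacing = c(1.5, 1.5), thickness = 8,
                         grid = 64L, endo_radius = 20, epi_radius = 30,
                         extent_deg = 72, start_deg = 0, transmurality = 1,
                         morphology = c("solid", "patchy"),
                         patch_density = 0.6, patch_radius = 2.5,
                         mvo_fraction = 0, mvo_angular_fraction = 0.5,
                         remote_mean = NULL, remote_sd = 0,
                         infarct_mean = 100, infarct_sd = 0,
                         mvo_mean = 10, cavity_mean = 0, background_mean = 0,
                         edema_width_mm = 0, edema_mean = 60,
                         coil_amplitude = 0,
                         convention = c("IR", "PSIR"),
                         noise = c("auto", "rician", "gaussian"),
                         supersample = 4L) {
  convention <- match.arg(convention)
  morphology <- match.arg(morphology)
  noise <- match.arg(noise)
  if (noise == "auto") noise <- if (convention == "IR") "rician" else "gaussian"
  if (is.null(remote_mean))
    remote_mean <- if (convention == "IR") 20 else -0.2 * infarct_mean
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (extent_deg < 0 || extent_deg >= 360) stop("extent_deg must lie in [0, 360)")
  if (extent_deg > 0 && (transmurality <= 0 || transmurality > 1))
    stop("transmurality must lie in (0, 1]: the wedge cannot be thicker than the wall")
  if (infarct_mean <= remote_mean) stop("infarct mean must exceed remote mean")
  if (convention == "IR" && remote_mean < 0)
    stop("IR phantoms are magnitude images; remote mean must be non-negative")
  spec <- as.list(environment())
  spec$n_slices <- as.integer(n_slices)
  spec$grid <- as.integer(grid)
  spec$supersample <- as.integer(supersample)
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d slices %dpx @ %.2gmm, wall %g-%g mm, %s %s\n",
              x$n_slices, x$grid, x$spacing[1L], min(x$endo_radius),
              max(x$epi_radius), x$convention, x$morphology))
  cat(sprintf("  infarct %g deg x %.2f transmural, remote %g+-%g, infarct %g+-%g\n",
              x$extent_deg, x$transmurality, x$remote_mean, x$remote_sd,
              x$infarct_mean, x$infarct_sd))
  invisible(x)
}

per_slice <- function(v, n) if (length(v) == 1L) rep(v, n) else v

wedge_deg <- function(theta, start, extent) {
  extent > 0 & ((theta - start) %% 360) < extent
}

#' Generate a synthetic phantom case
#'
#' Builds the stack, the LV contours (128-gon circles), automatically drawn
#' infarct and remote ROIs, and the ground-truth infarct weights. The truth
#' weight of a myocardial voxel is the infarct share of its wall content
#' (sub-voxel area fractions at `supersample^2` subpoints), matching the
#' whole-voxel accounting used for LV mass; MVO counts as infarct. Identical
#' seeds give bit-identical cases.
#'
#' @param spec a [phantom_spec].
#' @param seed integer RNG seed.
#' @param density myocardial density g/mL for the truth bookkeeping.
#' @return an object of class `phantom_case`: `stack`, `contours`, `rois`,
#'   `mask`, `truth_weights`, `truth_fraction_pct`.
#' @export
generate_phantom <- function(spec, seed = 1L, density = 1.05) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  n <- spec$grid
  ns <- spec$n_slices
  sx <- spec$spacing[2L]; sy <- spec$spacing[1L]
  c0x <- (n - 1) / 2 * sx
  c0y <- (n - 1) / 2 * sy
  g <- list(x = matrix((seq_len(n) - 1) * sx, n, n, byrow = TRUE),
            y = matrix((seq_len(n) - 1) * sy, n, n))
  re <- per_slice(spec$endo_radius, ns)
  rp <- per_slice(spec$epi_radius, ns)
  if (any(re >= rp)) stop("endocardial radius must be smaller than epicardial radius")

  S <- spec$supersample
  off <- ((seq_len(S) - 0.5) / S - 0.5)
  offx <- off * sx; offy <- off * sy
  S2 <- S * S

  voxels <- array(0, c(n, n, ns))
  sigma <- array(0, c(n, n, ns))
  truth <- array(0, c(n, n, ns))

  solid_const <- spec$morphology == "solid" &&
    length(unique(re)) == 1L && length(unique(rp)) == 1L
  cache <- NULL

  for (s in seq_len(ns)) {
    if (solid_const && !is.null(cache)) {
      cls <- cache
    } else {
      cls <- slice_class_counts(spec, g, c0x, c0y, re[s], rp[s], offx, offy)
      if (solid_const) cache <- cls
    }
    mu <- with(cls, (n_inf * spec$infarct_mean + n_mvo * spec$mvo_mean +
                     n_rem * spec$remote_mean + n_ede * spec$edema_mean +
                     n_cav * spec$cavity_mean + n_bg * spec$background_mean) / S2)
    sd_mix <- with(cls, ((n_inf + n_mvo + n_cav) * spec$infarct_sd +
                         (n_rem + n_ede + n_bg) * spec$remote_sd) / S2)
    voxels[, , s] <- mu
    sigma[, , s] <- sd_mix
    wall <- cls$n_inf + cls$n_mvo + cls$n_rem + cls$n_ede
    w <- ifelse(wall > 0, (cls$n_inf + cls$n_mvo) / wall, 0)
    truth[, , s] <- w
  }

  # multiplicative coil sensitivity ramp (linear along x)
  if (spec$coil_amplitude != 0) {
    fx <- 1 + spec$coil_amplitude * ((seq_len(n) - 1) * sx - c0x) / ((n - 1) * sx)
    field <- array(rep(matrix(fx, n, n, byrow = TRUE), ns), c(n, n, ns))
    voxels <- voxels * field
    sigma <- sigma * field
  }

  # measurement noise
  if (spec$noise == "rician") {
    z1 <- array(stats::rnorm(length(voxels)), dim(voxels))
    z2 <- array(stats::rnorm(length(voxels)), dim(voxels))
    voxels <- sqrt((voxels + sigma * z1)^2 + (sigma * z2)^2)
  } else {
    voxels <- voxels + sigma * array(stats::rnorm(length(voxels)), dim(voxels))
  }

  stack <- lge_stack(voxels, spacing = spec$spacing, thickness = spec$thickness,
                     convention = spec$convention)

  contours <- lge_contours(lapply(seq_len(ns), function(s) list(
    endo = circle_polygon(c0x, c0y, re[s]),
    epi = circle_polygon(c0x, c0y, rp[s])
  )), validate = FALSE)

  mask <- rasterize_contours(contours, stack, density = density)
  truth[!mask$mask] <- 0

  case <- structure(
    list(spec = spec, seed = as.integer(seed), stack = stack,
         contours = contours, mask = mask,
         rois = lge_rois(rep(list(list()), ns)),
         truth_weights = truth, center = c(c0x, c0y)),
    class = "phantom_case"
  )
  sz <- infarct_size(truth, mask, stack)
  case$truth_fraction_pct <- sz$fraction_pct
  case$truth_volume_ml <- sz$volume_ml

  case$rois <- auto_infarct_roi(case, margin_mm = 0)
  eff_extent <- spec$extent_deg +
    if (spec$edema_width_mm > 0) 2 * spec$edema_width_mm / mean(re) * 180 / pi else 0
  if (eff_extent <= 300)
    case$rois <- auto_remote_roi(case)
  case
}

# Sub-voxel class counts for one slice geometry.
slice_class_counts <- function(spec, g, c0x, c0y, r_endo, r_epi, offx, offy) {
  n <- nrow(g$x)
  zero <- matrix(0L, n, n)
  cls <- list(n_inf = zero, n_mvo = zero, n_rem = zero, n_ede = zero,
              n_cav = zero, n_bg = zero)
  depth <- spec$transmurality * (r_epi - r_endo)
  r_inf <- r_endo + depth
  has_inf <- spec$extent_deg > 0
  patches <- NULL
  if (has_inf && spec$morphology == "patchy") {
    wedge_area <- spec$extent_deg / 360 * pi * (r_inf^2 - r_endo^2)
    np <- max(0L, round(spec$patch_density * wedge_area / (pi * spec$patch_radius^2)))
    if (np > 0L) {
      rr <- sqrt(stats::runif(np, r_endo^2, r_inf^2))
      th <- (spec$start_deg + stats::runif(np, 0, spec$extent_deg)) * pi / 180
      patches <- cbind(c0x + rr * cos(th), c0y + rr * sin(th))
    }
  }
  mvo_on <- has_inf && spec$mvo_fraction > 0
  ede_on <- spec$edema_width_mm > 0 && has_inf
  ede_ang <- if (ede_on) spec$edema_width_mm / ((r_endo + r_epi) / 2) * 180 / pi else 0
  for (dx in offx) for (dy in offy) {
    px <- g$x + dx; py <- g$y + dy
    r <- sqrt((px - c0x)^2 + (py - c0y)^2)
    theta <- (atan2(py - c0y, px - c0x) * 180 / pi) %% 360
    cav <- r < r_endo
    bg <- r > r_epi
    wall <- !cav & !bg
    inf <- wall & has_inf & r <= r_inf &
      wedge_deg(theta, spec$start_deg, spec$extent_deg)
    if (!is.null(patches)) {
      inp <- matrix(FALSE, n, n)
      for (k in seq_len(nrow(patches)))
        inp <- inp | ((px - patches[k, 1L])^2 + (py - patches[k, 2L])^2 <=
                        spec$patch_radius^2)
      inf <- inf & inp
    } else if (has_inf && spec$morphology == "patchy") {
      inf <- inf & FALSE  # zero patches degenerates to no infarct
    }
    mvo <- if (mvo_on) {
      inf & r <= r_endo + spec$mvo_fraction * depth &
        wedge_deg(theta,
                  spec$start_deg + spec$extent_deg * (1 - spec$mvo_angular_fraction) / 2,
                  spec$extent_deg * spec$mvo_angular_fraction)
    } else matrix(FALSE, n, n)
    ede <- if (ede_on) {
      wall & !inf & r <= min(r_epi, r_inf + spec$edema_width_mm) &
        wedge_deg(theta, spec$start_deg - ede_ang, spec$extent_deg + 2 * ede_ang)
    } else matrix(FALSE, n, n)
    rem <- wall & !inf & !ede
    cls$n_inf <- cls$n_inf + (inf & !mvo)
    cls$n_mvo <- cls$n_mvo + mvo
    cls$n_rem <- cls$n_rem + rem
    cls$n_ede <- cls$n_ede + ede
    cls$n_cav <- cls$n_cav + cav
    cls$n_bg <- cls$n_bg + bg
  }
  cls
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s, truth infarct %.2f%% of LV (%.2f mL), seed %d\n",
              x$spec$convention, x$truth_fraction_pct, x$truth_volume_ml, x$seed))
  print(x$stack)
  invisible(x)
}

#' Automatically drawn infarct ROI
#'
#' Mirrors the manual step of outlining visually identified enhancement: the
#' ground-truth support, dilated in-plane by `margin_mm` and cropped to the
#' myocardial mask. Slices without truth support emit no ROI, so ROI-based
#' methods fall onto their zero-infarct path on infarct-free cases.
#'
#' @param case a [phantom_case].
#' @param margin_mm dilation margin in mm (0 keeps the exact support).
#' @return the case's [lge_rois] with infarct entries replaced.
#' @export
auto_infarct_roi <- function(case, margin_mm = 0) {
  d <- dim(case$stack$voxels)
  g <- grid_xy(case$stack)
  rois <- case$rois
  if (length(rois$slices) < d[3L])
    rois <- lge_rois(rep(list(list()), d[3L]))
  for (s in seq_len(d[3L])) {
    w <- case$truth_weights[, , s]
    supp <- w > 0
    rois$slices[[s]]$infarct <- list()
    if (!any(supp)) next
    sel <- supp
    if (margin_mm > 0) {
      m <- case$mask$mask[, , s]
      cand <- which(m & !supp)
      if (length(cand)) {
        sx <- g$x[supp]; sy <- g$y[supp]
        keep <- vapply(cand, function(i) {
          min((g$x[i] - sx)^2 + (g$y[i] - sy)^2) <= margin_mm^2
        }, NA)
        sel[cand[keep]] <- TRUE
      }
    }
    sel <- sel & case$mask$mask[, , s]
    rois$slices[[s]]$infarct <- list(roi_voxels(which(sel)))
  }
  rois
}

#' Automatically drawn remote ROI
#'
#' A semi-lunar annular sector of viable wall diametrically opposite the
#' infarct wedge, keeping an angular margin from the infarct (and edema halo)
#' borders.
#'
#' @param case a [phantom_case].
#' @param span_deg maximal angular span of the ROI.
#' @param margin_deg angular safety margin from the infarct/edema borders.
#' @return the case's [lge_rois] with remote entries replaced.
#' @export
auto_remote_roi <- function(case, span_deg = 90, margin_deg = 20) {
  spec <- case$spec
  ede_ang <- if (spec$edema_width_mm > 0 && spec$extent_deg > 0)
    spec$edema_width_mm / mean(per_slice(spec$endo_radius, 1L) +
                               per_slice(spec$epi_radius, 1L)) * 2 * 180 / pi else 0
  eff <- spec$extent_deg + 2 * ede_ang
  if (eff > 300)
    stop("infarct spans more than 300 degrees: no clean remote sector exists")
  avail <- 360 - eff - 2 * margin_deg
  span <- min(span_deg, avail)
  center <- (spec$start_deg + spec$extent_deg / 2 + 180) %% 360
  a0 <- (center - span / 2) %% 360
  d <- dim(case$stack$voxels)
  g <- grid_xy(case$stack)
  rois <- case$rois
  for (s in seq_len(d[3L])) {
    m <- case$mask$mask[, , s]
    if (!any(m)) { rois$slices[[s]]$remote <- list(); next }
    theta <- (atan2(g$y - case$center[2L], g$x - case$center[1L]) * 180 / pi) %% 360
    sel <- m & ((theta - a0) %% 360) < span & case$truth_weights[, , s] == 0
    rois$slices[[s]]$remote <- list(roi_voxels(which(sel)))
  }
  rois
}
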