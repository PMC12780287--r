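#' Rasterize LV contours into a myocardial mask
#'
#' A voxel belongs to the myocardium iff its center lies inside the
#' epicardial polygon and outside the endocardial polygon (even-odd rule at
#' voxel centers). Slices without an epicardial contour contribute an empty
#' mask; a slice with only an epicardial contour yields a full disk
#' (papillary handling is whatever the contours enclose). LV wall mass uses a
#' fixed myocardial density.
#'
#' @param contours an [lge_contours].
#' @param stack an [lge_stack] defining the grid.
#' @param density myocardial density in g/mL.
#' @return an object of class `lge_mask`: logical voxel array plus LV
#'   volume/mass bookkeeping.
#' @export
rasterize_contours <- function(contours, stack, density = 1.05) {
  contours <- validate_contours(contours)
  d <- dim(stack$voxels)
  mask <- array(FALSE, d)
  g <- grid_xy(stack)
  for (s in seq_len(min(d[3L], length(contours$slices)))) {
    sl <- contours$slices[[s]]
    if (is.null(sl$epi)) next
    inside <- point_in_polygon(as.vector(g$x), as.vector(g$y), sl$epi)
    if (!is.null(sl$endo))
      inside <- inside & !point_in_polygon(as.vector(g$x), as.vector(g$y), sl$endo)
    mask[, , s] <- inside
  }
  new_lge_mask(mask, stack, density, contours)
}

new_lge_mask <- function(mask, stack, density = 1.05, contours = NULL) {
  vv <- voxel_volume_ml(stack)
  n <- sum(mask)
  structure(
    list(mask = mask, spacing = stack$spacing, thickness = stack$thickness,
         density = density, voxel_volume_ml = vv,
         lv_volume_ml = n * vv, lv_mass_g = n * vv * density,
         contours = contours),
    class = "lge_mask"
  )
}

#' @export
print.lge_mask <- function(x, ...) {
  cat(sprintf("<lge_mask> %d voxels, LV volume %.2f mL, LV mass %.2f g (density %.2f g/mL)\n",
              sum(x$mask), x$lv_volume_ml, x$lv_mass_g, x$density))
  invisible(x)
}

#' Partition the myocardium of each slice into angular sectors
#'
#' Equal angular bins around the per-slice mask centroid, anchored at the +x
#' image axis and advancing counter-clockwise (towards +y).
#'
#' @param mask an [lge_mask].
#' @param stack the matching [lge_stack].
#' @param n_sectors number of sectors (>= 1).
#' @param offset_deg rotation of the first bin boundary, degrees.
#' @return integer array of sector labels (1..n_sectors), `NA` off-mask.
#' @export
sector_partition <- function(mask, stack, n_sectors = 5L, offset_deg = 0) {
  if (n_sectors < 1L) stop("n_sectors must be >= 1")
  d <- dim(mask$mask)
  lab <- array(NA_integer_, d)
  g <- grid_xy(stack)
  width <- 360 / n_sectors
  for (s in seq_len(d[3L])) {
    m <- mask$mask[, , s]
    if (!any(m)) next
    cx <- mean(g$x[m]); cy <- mean(g$y[m])
    ang <- (atan2(g$y[m] - cy, g$x[m] - cx) * 180 / pi - offset_deg) %% 360
    lab[, , s][m] <- pmin(n_sectors, floor(ang / width) + 1L)
  }
  lab
}

#' In-plane distance from myocardial voxels to the endocardial boundary
#'
#' @inheritParams sector_partition
#' @param contours an [lge_contours] providing the endocardial polygons.
#' @return numeric array of distances in mm; `NA` off-mask, and `NaN` (with a
#'   `"missing_endo"` attribute listing slices) on masked slices without an
#'   endocardial contour.
#' @export
endocardial_distance <- function(mask, contours, stack) {
  d <- dim(mask$mask)
  out <- array(NA_real_, d)
  g <- grid_xy(stack)
  missing <- integer(0)
  for (s in seq_len(d[3L])) {
    m <- mask$mask[, , s]
    if (!any(m)) next
    endo <- if (s <= length(contours$slices)) contours$slices[[s]]$endo
    if (is.null(endo)) {
      out[, , s][m] <- NaN
      missing <- c(missing, s)
      next
    }
    out[, , s][m] <- dist_to_polygon(g$x[m], g$y[m], endo)
  }
  attr(out, "missing_endo") <- missing
  out
}

#' Midmural band of the myocardium
#'
#' Voxels whose normalized transmural depth
#' `d = dist_endo / (dist_endo + dist_epi)` lies within `window`. Slices where
#' the wall is too thin for the window to catch any voxel fall back to the
#' mid-most voxel layer, so the band is never empty on a non-empty slice.
#'
#' @inheritParams endocardial_distance
#' @param window depth window, default the midmural half `[0.25, 0.75]`.
#' @return logical array, subset of the mask.
#' @export
midmural_band <- function(mask, contours, stack, window = c(0.25, 0.75)) {
  d <- dim(mask$mask)
  out <- array(FALSE, d)
  g <- grid_xy(stack)
  for (s in seq_len(d[3L])) {
    m <- mask$mask[, , s]
    if (!any(m)) next
    sl <- if (s <= length(contours$slices)) contours$slices[[s]] else list()
    if (is.null(sl$endo) || is.null(sl$epi))
      stop(sprintf("midmural band needs endo and epi contours on slice %d (no transmural axis)", s))
    de <- dist_to_polygon(g$x[m], g$y[m], sl$endo)
    dp <- dist_to_polygon(g$x[m], g$y[m], sl$epi)
    depth <- de / pmax(de + dp, .Machine$double.eps)
    band <- depth >= window[1L] & depth <= window[2L]
    if (!any(band)) {
      # degenerate floor: keep the voxels closest to mid-depth
      mid <- abs(depth - mean(window))
      band <- mid <= min(mid) + 1e-9
    }
    out[, , s][m] <- band
  }
  out
}

#' Connected components of a voxel set
#'
#' 6-connectivity: 4-connected in-plane plus face adjacency across slices.
#'
#' @param support logical array (same grid as `stack`).
#' @param stack an [lge_stack] (for voxel volume).
#' @param density g/mL for mass bookkeeping.
#' @param endo_dist optional array from [endocardial_distance()]; if given,
#'   each component records its minimum endocardial distance.
#' @return list of components, each
#'   `list(idx, n, volume_ml, mass_g, mean_intensity, min_endo_dist, slices)`.
#' @export
connected_components <- function(support, stack, density = 1.05, endo_dist = NULL) {
  idx <- which(support)
  if (length(idx) == 0L) return(list())
  d <- dim(support)
  memb <- label_components(support)
  vv <- voxel_volume_ml(stack)
  comps <- split(idx, memb[idx])
  lapply(unname(comps), function(ci) {
    ai <- arrayInd(ci, d)
    list(idx = ci, n = length(ci),
         volume_ml = length(ci) * vv,
         mass_g = length(ci) * vv * density,
         mean_intensity = mean(stack$voxels[ci]),
         min_endo_dist = if (!is.null(endo_dist)) suppressWarnings(min(endo_dist[ci])) else NA_real_,
         slices = sort(unique(ai[, 3L])))
  })
}

# Integer labels of 6-connected components over a logical array.
label_components <- function(support) {
  d <- dim(support)
  idx <- which(support)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  ai <- arrayInd(idx, d)
  id <- match(idx, idx)  # 1..n in order
  edges <- NULL
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  neighbor_pairs <- function(dr, dc, ds) {
    r2 <- ai[, 1L] + dr; c2 <- ai[, 2L] + dc; s2 <- ai[, 3L] + ds
    ok <- r2 >= 1L & r2 <= d[1L] & c2 >= 1L & c2 <= d[2L] & s2 >= 1L & s2 <= d[3L]
    if (!any(ok)) return(NULL)
    lin2 <- (s2[ok] - 1L) * d[1L] * d[2L] + (c2[ok] - 1L) * d[1L] + r2[ok]
    p2 <- pos[lin2]
    keep <- p2 > 0L
    cbind(seq_along(idx)[ok][keep], p2[keep])
  }
  edges <- rbind(neighbor_pairs(1L, 0L, 0L),
                 neighbor_pairs(0L, 1L, 0L),
                 neighbor_pairs(0L, 0L, 1L))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Infarct volume, mass and fraction of LV mass
#'
#' Linear in the per-voxel weights: `volume = sum(w) * voxel_volume`,
#' `mass = volume * density`, `fraction = 100 * mass / LV mass`.
#'
#' @param weights numeric array of per-voxel weights in `[0, 1]` (values
#'   outside the mask are ignored).
#' @param mask an [lge_mask].
#' @param stack an [lge_stack].
#' @return `list(volume_ml, mass_g, fraction_pct)`.
#' @export
infarct_size <- function(weights, mask, stack) {
  if (mask$lv_mass_g <= 0) stop("zero LV mass: cannot express infarct as %LV")
  w <- weights
  w[!mask$mask] <- 0
  if (any(w < -1e-9 | w > 1 + 1e-9, na.rm = TRUE))
    stop("weights must lie in [0, 1]")
  vol <- sum(w) * mask$voxel_volume_ml
  mass <- vol * mask$density
  list(volume_ml = vol, mass_g = mass,
       fraction_pct = 100 * mass / mask$lv_mass_g)
}
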