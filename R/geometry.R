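#' Per-slice endocardial/epicardial contours
#'
#' @param slices a list, one element per slice, each a list with optional
#'   two-column vertex matrices `endo` and `epi` (mm, image-plane
#'   coordinates). Use `NULL` (or omit) where a contour was not drawn.
#' @param validate check polygon simplicity and endo-inside-epi nesting.
#' @return an object of class `lge_contours`.
#' @export
lge_contours <- function(slices, validate = TRUE) {
  slices <- lapply(slices, function(s) {
    s <- s[intersect(names(s), c("endo", "epi"))]
    lapply(s, function(p) if (is.null(p)) NULL else as_poly(p))
  })
  obj <- structure(list(slices = slices), class = "lge_contours")
  if (validate) obj <- validate_contours(obj)
  obj
}

validate_contours <- function(contours) {
  if (isTRUE(attr(contours, "validated"))) return(invisible(contours))
  for (s in seq_along(contours$slices)) {
    sl <- contours$slices[[s]]
    for (nm in c("endo", "epi")) {
      if (!is.null(sl[[nm]]) && !polygon_is_simple(sl[[nm]]))
        stop(sprintf("self-intersecting %s contour on slice %d", nm, s))
    }
    if (!is.null(sl$endo) && !is.null(sl$epi)) {
      ok <- point_in_polygon(sl$endo[, 1L], sl$endo[, 2L], sl$epi)
      if (!all(ok)) {
        # tolerate vertices on the epicardial boundary (zero-width wall)
        on_epi <- dist_to_polygon(sl$endo[!ok, 1L], sl$endo[!ok, 2L],
                                  sl$epi) <= 1e-9
        if (!all(on_epi))
          stop(sprintf("endocardial contour not inside epicardial contour on slice %d", s))
      }
    }
  }
  attr(contours, "validated") <- TRUE
  invisible(contours)
}

#' @export
print.lge_contours <- function(x, ...) {
  has <- vapply(x$slices, function(s)
    paste0(if (!is.null(s$endo)) "endo" else "-", "/",
           if (!is.null(s$epi)) "epi" else "-"), "")
  cat(sprintf("<lge_contours> %d slices: %s\n", length(x$slices),
              paste(has, collapse = ", ")))
  invisible(x)
}

#' Per-slice infarct and remote regions of interest
#'
#' Each ROI is either a polygon (`list(type = "polygon", xy = <matrix>)`,
#' mm coordinates) or an explicit in-plane voxel set
#' (`list(type = "voxels", idx = <in-slice linear indices>)`). The phantom
#' generator emits voxel ROIs; hand-drawn geometry read from JSON arrives as
#' polygons. Infarct and remote ROIs are cropped to the myocardial mask when
#' resolved.
#'
#' @param slices list, one element per slice, each
#'   `list(infarct = list(...), remote = list(...))` of ROI objects.
#' @return an object of class `lge_rois`.
#' @export
lge_rois <- function(slices = list()) {
  slices <- lapply(slices, function(s) {
    list(infarct = s$infarct %||% list(), remote = s$remote %||% list())
  })
  structure(list(slices = slices), class = "lge_rois")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lge_rois <- function(x, ...) {
  ni <- sum(vapply(x$slices, function(s) length(s$infarct), 0L))
  nr <- sum(vapply(x$slices, function(s) length(s$remote), 0L))
  cat(sprintf("<lge_rois> %d slices, %d infarct ROI(s), %d remote ROI(s)\n",
              length(x$slices), ni, nr))
  invisible(x)
}

roi_polygon <- function(xy) list(type = "polygon", xy = as_poly(xy))
roi_voxels <- function(idx) list(type = "voxels", idx = as.integer(idx))

# Resolve one kind of ROI ("infarct" or "remote") to a logical array on the
# stack grid, cropped to the myocardial mask.
resolve_rois <- function(rois, which, stack, mask) {
  d <- dim(stack$voxels)
  out <- array(FALSE, d)
  if (is.null(rois)) return(out)
  g <- grid_xy(stack)
  for (s in seq_along(rois$slices)) {
    if (s > d[3L]) break
    for (roi in rois$slices[[s]][[which]]) {
      if (roi$type == "polygon") {
        sel <- point_in_polygon(as.vector(g$x), as.vector(g$y), roi$xy)
        sl <- out[, , s]
        sl[sel] <- TRUE
        out[, , s] <- sl
      } else {
        sl <- out[, , s]
        sl[roi$idx] <- TRUE
        out[, , s] <- sl
      }
    }
  }
  out & mask$mask
}

has_infarct_roi <- function(rois) {
  !is.null(rois) && any(vapply(rois$slices, function(s) length(s$infarct) > 0L, NA))
}

#' Read contours and ROIs from JSON
#'
#' The schema is one object per slice, keyed by the 0-based slice index:
#' `{"0": {"endo": [[x,y],...], "epi": [...], "infarct_rois": [[[x,y],...]],
#' "remote_rois": [...]}}`, all coordinates in mm.
#'
#' @param path JSON file path.
#' @param n_slices total number of slices in the stack (defaults to the
#'   largest slice index present).
#' @return `list(contours = <lge_contours>, rois = <lge_rois>)`.
#' @export
read_geometry <- function(path, n_slices = NULL) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  idx <- as.integer(names(raw))
  if (any(is.na(idx))) stop("slice keys must be 0-based integer indices")
  if (is.null(n_slices)) n_slices <- max(idx) + 1L
  cs <- rep(list(list()), n_slices)
  rs <- rep(list(list(infarct = list(), remote = list())), n_slices)
  to_mat <- function(v) do.call(rbind, lapply(v, function(p) unlist(p)[1:2]))
  for (k in seq_along(raw)) {
    s <- idx[k] + 1L
    e <- raw[[k]]
    cs[[s]] <- list(
      endo = if (!is.null(e$endo)) to_mat(e$endo),
      epi  = if (!is.null(e$epi)) to_mat(e$epi)
    )
    rs[[s]]$infarct <- lapply(e$infarct_rois %||% list(),
                              function(p) roi_polygon(to_mat(p)))
    rs[[s]]$remote <- lapply(e$remote_rois %||% list(),
                             function(p) roi_polygon(to_mat(p)))
  }
  list(contours = lge_contours(cs), rois = lge_rois(rs))
}

#' Write contours and ROIs to JSON
#'
#' Voxel-set ROIs are converted to polygons by tracing their half-level
#' outline, so the file round-trips through [read_geometry()] onto the same
#' voxel sets under the voxel-center rule.
#'
#' @param contours an [lge_contours] (or `NULL`).
#' @param rois an [lge_rois] (or `NULL`).
#' @param path output path.
#' @param stack the stack the geometry refers to (needed to trace voxel ROIs).
#' @return `path`, invisibly.
#' @export
write_geometry <- function(contours, rois, path, stack = NULL) {
  n <- max(length(contours$slices %||% list()), length(rois$slices %||% list()))
  out <- list()
  poly_list <- function(roi) {
    if (roi$type == "polygon") return(list(unname(roi$xy)))
    if (is.null(stack)) stop("writing voxel ROIs requires 'stack'")
    d <- dim(stack$voxels)
    bin <- matrix(FALSE, d[1L], d[2L])
    bin[roi$idx] <- TRUE
    lapply(trace_voxel_outline(bin, stack$spacing), unname)
  }
  for (s in seq_len(n)) {
    e <- list()
    cs <- if (!is.null(contours) && s <= length(contours$slices)) contours$slices[[s]]
    if (!is.null(cs$endo)) e$endo <- unname(cs$endo)
    if (!is.null(cs$epi)) e$epi <- unname(cs$epi)
    rsl <- if (!is.null(rois) && s <= length(rois$slices)) rois$slices[[s]]
    if (length(rsl$infarct))
      e$infarct_rois <- do.call(c, lapply(rsl$infarct, poly_list))
    if (length(rsl$remote))
      e$remote_rois <- do.call(c, lapply(rsl$remote, poly_list))
    if (length(e)) out[[as.character(s - 1L)]] <- e
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
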