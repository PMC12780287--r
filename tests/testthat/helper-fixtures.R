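# Shared fixtures built in code.

# Annular test stack: constant remote intensity on an annulus, optional
# bright blobs painted on top. Returns stack, contours, mask.
annulus_fixture <- function(grid = 48L, spacing = 1, thickness = 8,
                            r_endo = 12, r_epi = 20, n_slices = 1L,
                            value = 10) {
  c0 <- (grid - 1) / 2 * spacing
  vox <- array(0, c(grid, grid, n_slices))
  contours <- lge_contours(lapply(seq_len(n_slices), function(s) list(
    endo = circle_polygon(c0, c0, r_endo),
    epi = circle_polygon(c0, c0, r_epi)
  )), validate = FALSE)
  stack <- lge_stack(vox, spacing = spacing, thickness = thickness)
  mask <- rasterize_contours(contours, stack)
  stack$voxels[mask$mask] <- value
  list(stack = stack, contours = contours, mask = mask, center = c(c0, c0),
       r_endo = r_endo, r_epi = r_epi)
}

# Paint a square blob of given side (voxels) at mm position (x, y) on a copy
# of the stack; returns the modified stack and the blob's linear indices.
paint_blob <- function(stack, mask, x, y, side, value, slice = 1L) {
  g <- lgequant:::grid_xy(stack)
  sel <- abs(g$x - x) < side / 2 * stack$spacing[2L] &
    abs(g$y - y) < side / 2 * stack$spacing[1L] & mask$mask[, , slice]
  idx <- which(sel) + (slice - 1L) * prod(dim(stack$voxels)[1:2])
  stack$voxels[idx] <- value
  list(stack = stack, idx = idx)
}

# Default study phantoms.
solid_phantom <- function(seed = 1, ...) generate_phantom(phantom_spec(...), seed = seed)
noisy_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(remote_sd = 5, infarct_sd = 8, ...), seed = seed)
}
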