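# Independent oracles used by the tests. They deliberately use different
# algorithms than the package internals they check.

# Winding-number point-in-polygon (the package uses the even-odd crossing
# rule; for simple polygons both agree).
winding_inside <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    ang <- atan2(poly[, 2L] - y, poly[, 1L] - x)
    d <- diff(c(ang, ang[1L]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi  # ~2*pi inside, ~0 outside
  }, NA)
}

# Exhaustive Otsu search over all integer cuts for 8-bit samples; returns the
# size of the lower class of the best split (tie -> lowest threshold), which
# identifies the induced partition.
otsu_bruteforce_split <- function(v) {
  best <- -Inf; best_n0 <- NA_integer_
  n <- length(v)
  for (t in 1:255) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    bv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bv > best + 1e-12) { best <- bv; best_n0 <- length(lo) }
  }
  best_n0
}

# Random star-convex polygon around (cx, cy): strictly positive radius as a
# function of angle, so the polygon is guaranteed simple.
random_star_polygon <- function(cx, cy, r_base, n_vert = 16L) {
  th <- sort(stats::runif(n_vert, 0, 2 * pi))
  r <- r_base * stats::runif(n_vert, 0.4, 1)
  cbind(cx + r * cos(th), cy + r * sin(th))
}
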