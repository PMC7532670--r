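# Tiling geometry: exact polygon/patch overlap and the grid filter.
#
# Coordinates are 0-based half-open pixel intervals, x right / y down. A patch
# at grid (gx, gy) covers [gx*s, (gx+1)*s) x [gy*s, (gy+1)*s) with s the patch
# size; the grid is anchored at the slide origin with stride = patch size.

# Sutherland-Hodgman clip of a simple ring against one half-plane keep(p)>=0.
clip_halfplane <- function(ring, keep, intersect_fun) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  out <- matrix(numeric(0), ncol = 2)
  kv <- keep(ring)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- ring[i, ]; q <- ring[j, ]
    pin <- kv[i] >= 0; qin <- kv[j] >= 0
    if (pin) out <- rbind(out, p)
    if (xor(pin, qin)) out <- rbind(out, intersect_fun(p, q))
  }
  out
}

# Clip a ring to the axis-aligned rectangle [x0,x1] x [y0,y1]; returns matrix.
clip_ring_rect <- function(ring, x0, y0, x1, y1) {
  r <- ring
  r <- clip_halfplane(r, function(m) m[, 1] - x0,
                      function(p, q) { t <- (x0 - p[1]) / (q[1] - p[1]); p + t * (q - p) })
  r <- clip_halfplane(r, function(m) x1 - m[, 1],
                      function(p, q) { t <- (x1 - p[1]) / (q[1] - p[1]); p + t * (q - p) })
  r <- clip_halfplane(r, function(m) m[, 2] - y0,
                      function(p, q) { t <- (y0 - p[2]) / (q[2] - p[2]); p + t * (q - p) })
  r <- clip_halfplane(r, function(m) y1 - m[, 2],
                      function(p, q) { t <- (y1 - p[2]) / (q[2] - p[2]); p + t * (q - p) })
  r
}

# Shoelace area of a ring (absolute value, so vertex orientation is irrelevant).
ring_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Exact area of ring-rectangle intersection for a simple (possibly concave)
# ring: signed fan triangulation from vertex 1 — each triangle is convex, so
# Sutherland-Hodgman clipping is exact, and the signed indicator identity
# sum_i sign_i * chi(T_i) = chi(polygon) makes the signed clipped areas sum
# to the true intersection area.
ring_rect_area <- function(ring, x0, y0, x1, y1) {
  n <- nrow(ring)
  if (n < 3) return(0)
  total <- 0
  for (i in 2:(n - 1)) {
    tri <- rbind(ring[1, ], ring[i, ], ring[i + 1, ])
    s <- (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
      (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2])
    if (s == 0) next
    a <- ring_area(clip_ring_rect(tri, x0, y0, x1, y1))
    total <- total + sign(s) * a
  }
  abs(total)
}

#' Fraction of a patch covered by the ROI
#'
#' Computes area(patch intersect ROI) / area(patch) by exact polygon clipping
#' (Sutherland-Hodgman against the patch square, shoelace area). Annotation
#' rings are treated as disjoint regions, the usual convention for pathologist
#' ROI outlines, so per-ring areas are summed (and the fraction clamped to 1).
#'
#' @param origin_x,origin_y Level-0 pixel coordinate of the patch top-left.
#' @param size Patch edge in pixels (default 512).
#' @param roi An `roi_annotation` (or a bare list of vertex matrices).
#' @return Overlap fraction in `[0, 1]`.
#' @export
compute_overlap_fraction <- function(origin_x, origin_y, roi, size = 512) {
  polygons <- if (inherits(roi, "roi_annotation")) roi$polygons else roi
  x1 <- origin_x + size; y1 <- origin_y + size
  covered <- sum(vapply(polygons, function(ring) {
    ring_rect_area(ring, origin_x, origin_y, x1, y1)
  }, numeric(1)))
  min(1, covered / (size * size))
}

#' Tile a slide and keep patches inside the carcinoma ROI
#'
#' Lays a non-overlapping patch grid (stride = patch size, anchored at the
#' slide origin) over the slide and retains only patches whose overlap with
#' the ROI polygon set is strictly greater than `min_overlap` — the
#' "greater than 80%" carcinoma-ROI filter.
#'
#' @param roi An `roi_annotation`.
#' @param slide_extent `c(width, height)` in level-0 pixels.
#' @param patch_size Patch edge in pixels (default 512).
#' @param min_overlap Strict lower bound on the overlap fraction (default 0.8).
#' @return A tibble with `slide_id`, `grid_x`, `grid_y`, `origin_x`,
#'   `origin_y`, `size`, `overlap`, one row per retained patch.
#' @export
tile_slide <- function(roi, slide_extent, patch_size = 512, min_overlap = 0.8) {
  stopifnot(length(slide_extent) == 2)
  if (any(slide_extent <= 0)) stop_pathomsi("slide extent must be positive")
  if (min_overlap <= 0 || min_overlap > 1) stop_pathomsi("min_overlap must lie in (0,1]")
  bb <- do.call(rbind, roi$polygons)
  if (min(bb[, 1]) < 0 || min(bb[, 2]) < 0 ||
      max(bb[, 1]) > slide_extent[1] || max(bb[, 2]) > slide_extent[2]) {
    stop_pathomsi("ROI extends outside the slide extent")
  }
  # only grid cells touching the ROI bounding box can pass the filter
  gx_range <- floor(min(bb[, 1]) / patch_size):floor((max(bb[, 1]) - 1e-9) / patch_size)
  gy_range <- floor(min(bb[, 2]) / patch_size):floor((max(bb[, 2]) - 1e-9) / patch_size)
  grid <- expand.grid(grid_x = gx_range, grid_y = gy_range)
  ov <- mapply(function(gx, gy) {
    compute_overlap_fraction(gx * patch_size, gy * patch_size, roi, patch_size)
  }, grid$grid_x, grid$grid_y)
  keep <- ov > min_overlap
  tibble(
    slide_id = roi$slide_id,
    grid_x = as.integer(grid$grid_x[keep]),
    grid_y = as.integer(grid$grid_y[keep]),
    origin_x = as.integer(grid$grid_x[keep]) * patch_size,
    origin_y = as.integer(grid$grid_y[keep]) * patch_size,
    size = patch_size,
    overlap = ov[keep]
  )
}
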