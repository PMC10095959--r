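#' Landmarked leaf contour
#'
#' A closed, simple, counterclockwise 2D polygon (micrometres) with the
#' three blade landmarks (base-left, base-right, apex vertex indices) and
#' an ordered table of tooth landmark triples (sinus, tip, sinus) per
#' half-leaf. Vertex indices are 1-based in R; the JSON interchange format
#' uses 0-based indices (see \code{\link{read_contours}}).
#'
#' @param points numeric n x 2 matrix of vertices (closing edge implicit).
#' @param base_left,base_right,apex landmark vertex indices.
#' @param teeth data frame with columns \code{side} ("left"/"right"),
#'   \code{sinus_prev}, \code{tip}, \code{sinus_next} (vertex indices),
#'   ordered base to apex within each side; may be empty.
#' @param id contour identifier.
#' @param age_h optional assigned age (hours since organ initiation).
#' @param check validate polygon simplicity (O(n^2); disable for bulk
#'   loading of trusted data).
#' @return Object of class \code{leaf_contour}.
#' @export
leaf_contour <- function(points, base_left, base_right, apex,
                         teeth = empty_teeth(), id = NA_character_,
                         age_h = NULL, check = TRUE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 4)
  n <- nrow(points)
  idx <- c(base_left, base_right, apex,
           if (nrow(teeth) > 0) unlist(teeth[, c("sinus_prev", "tip", "sinus_next")]))
  if (any(idx < 1 | idx > n)) stop("landmark index out of range")
  if (polygon_signed_area(points) <= 0)
    stop("polygon must be counterclockwise (signed area > 0)")
  if (check && !polygon_is_simple(points))
    stop("polygon is self-intersecting")
  structure(list(id = id, points = unname(points),
                 landmarks = list(base_left = as.integer(base_left),
                                  base_right = as.integer(base_right),
                                  apex = as.integer(apex)),
                 teeth = teeth, age_h = age_h),
            class = "leaf_contour")
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat(sprintf("leaf contour '%s': %d vertices, %d teeth (%d left, %d right)%s\n",
              x$id, nrow(x$points), nrow(x$teeth),
              sum(x$teeth$side == "left"), sum(x$teeth$side == "right"),
              if (!is.null(x$age_h)) sprintf(", age %.4g h", x$age_h) else ""))
  invisible(x)
}

empty_teeth <- function() {
  data.frame(side = character(0), sinus_prev = integer(0),
             tip = integer(0), sinus_next = integer(0))
}

# signed (shoelace) area; > 0 for counterclockwise polygons
polygon_signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# brute-force simplicity test: no two non-adjacent edges properly intersect
# and no vertex lies strictly inside a non-incident edge
polygon_is_simple <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  p1 <- pts
  p2 <- pts[c(2:n, 1), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1 & !(i == 1 & j == n)), arr.ind = TRUE)
  if (nrow(idx) == 0) return(TRUE)
  a1 <- p1[idx[, 1], , drop = FALSE]; a2 <- p2[idx[, 1], , drop = FALSE]
  b1 <- p1[idx[, 2], , drop = FALSE]; b2 <- p2[idx[, 2], , drop = FALSE]
  cross2 <- function(o, p, q)
    (p[, 1] - o[, 1]) * (q[, 2] - o[, 2]) - (p[, 2] - o[, 2]) * (q[, 1] - o[, 1])
  d1 <- cross2(a1, a2, b1); d2 <- cross2(a1, a2, b2)
  d3 <- cross2(b1, b2, a1); d4 <- cross2(b1, b2, a2)
  proper <- (d1 * d2 < -tol) & (d3 * d4 < -tol)
  !any(proper)
}

# area of the convex hull of a point set
convex_hull_area <- function(pts) {
  h <- chull(pts)
  abs(polygon_signed_area(pts[h, , drop = FALSE]))
}

# cumulative arc length along an open polyline (n x 2)
arc_lengths <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

# resample an open polyline to n_out points uniform in arc length,
# endpoints preserved
resample_polyline <- function(pts, n_out) {
  s <- arc_lengths(pts)
  total <- s[length(s)]
  if (total <= 0) stop("degenerate (zero-length) margin")
  si <- seq(0, total, length.out = n_out)
  cbind(approx(s, pts[, 1], xout = si)$y,
        approx(s, pts[, 2], xout = si)$y)
}

# iterate resampling to its fixed point (equal chord lengths), so that
# normalization is idempotent to numerical tolerance
resample_fixed_point <- function(pts, n_out, max_iter = 12L) {
  p <- resample_polyline(pts, n_out)
  tol <- 1e-12 * max(arc_lengths(p))
  for (i in seq_len(max_iter)) {
    q <- resample_polyline(p, n_out)
    moved <- max(abs(q - p))
    p <- q
    if (moved < tol) break
  }
  p
}

# cyclic index path from vertex i to vertex j following polygon order
cyclic_path <- function(i, j, n) {
  if (i <= j) i:j else c(i:n, 1:j)
}

#' Resample and register a contour for averaging
#'
#' Resamples each margin (base-right to apex, apex to base-left, following
#' polygon order) uniformly in arc length to \code{points_per_side}
#' subdivisions, yielding \code{2 * points_per_side + 1} vertices with the
#' landmarks at fixed indices (base_right = 1, apex = points_per_side + 1,
#' base_left = last). The contour is rigidly registered: base midpoint at
#' the origin, blade axis (base midpoint to apex) along +y. No size
#' normalization is applied — trajectories must carry absolute scale.
#' Tooth landmarks are snapped to the nearest resampled vertex on their
#' margin. Idempotent at fixed \code{points_per_side}.
#'
#' @param contour a \code{\link{leaf_contour}}.
#' @param points_per_side number of arc-length subdivisions per margin
#'   (default 200).
#' @return A registered \code{leaf_contour} with attribute
#'   \code{normalized = points_per_side}.
#' @export
normalize_contour <- function(contour, points_per_side = 200L) {
  stopifnot(inherits(contour, "leaf_contour"), points_per_side >= 2)
  m <- as.integer(points_per_side)
  pts <- contour$points
  n <- nrow(pts)
  lm <- contour$landmarks
  path_r <- cyclic_path(lm$base_right, lm$apex, n)
  path_l <- cyclic_path(lm$apex, lm$base_left, n)
  right <- resample_fixed_point(pts[path_r, , drop = FALSE], m + 1L)
  left <- resample_fixed_point(pts[path_l, , drop = FALSE], m + 1L)
  new_pts <- rbind(right, left[-1, , drop = FALSE])  # 2m + 1 vertices
  i_br <- 1L; i_apex <- m + 1L; i_bl <- 2L * m + 1L

  # rigid registration: base midpoint -> origin, blade axis -> +y
  base_mid <- (new_pts[i_br, ] + new_pts[i_bl, ]) / 2
  new_pts <- sweep(new_pts, 2, base_mid)
  axis <- new_pts[i_apex, ]
  theta <- atan2(axis[2], axis[1]) - pi / 2
  Rm <- matrix(c(cos(-theta), -sin(-theta), sin(-theta), cos(-theta)),
               2, 2, byrow = TRUE)
  new_pts <- new_pts %*% t(Rm)

  # snap tooth landmarks to nearest resampled vertex on the same margin
  teeth <- contour$teeth
  if (nrow(teeth) > 0) {
    s_r <- arc_lengths(pts[path_r, , drop = FALSE])
    s_l <- arc_lengths(pts[path_l, , drop = FALSE])
    snap <- function(v_idx) {
      pos_r <- match(v_idx, path_r)
      if (!is.na(pos_r)) {
        frac <- s_r[pos_r] / s_r[length(s_r)]
        return(1L + as.integer(round(frac * m)))
      }
      pos_l <- match(v_idx, path_l)
      if (is.na(pos_l)) stop("tooth landmark lies on neither margin")
      frac <- s_l[pos_l] / s_l[length(s_l)]
      (m + 1L) + as.integer(round(frac * m))
    }
    for (col in c("sinus_prev", "tip", "sinus_next"))
      teeth[[col]] <- vapply(teeth[[col]], snap, integer(1))
  }
  out <- leaf_contour(new_pts, base_left = i_bl, base_right = i_br,
                      apex = i_apex, teeth = teeth, id = contour$id,
                      age_h = contour$age_h, check = FALSE)
  attr(out, "normalized") <- m
  out
}

#' Blade-scale shape measures
#'
#' Length is the distance from the base midpoint to the apex; width is the
#' maximal extent perpendicular to that axis; area by the shoelace formula;
#' hull area from the convex hull. The dissection index (hull area / blade
#' area) is 1 for convex outlines and grows with serration; the aspect
#' ratio (length / width) tracks blade elongation.
#'
#' @param contour a \code{\link{leaf_contour}}.
#' @return List of class \code{blade_measures}: \code{length_um},
#'   \code{width_um}, \code{area_um2}, \code{hull_area_um2},
#'   \code{aspect_ratio}, \code{dissection_index}.
#' @export
blade_measures <- function(contour) {
  stopifnot(inherits(contour, "leaf_contour"))
  pts <- contour$points
  lm <- contour$landmarks
  if (!polygon_is_simple(pts)) stop("polygon is self-intersecting")
  base_mid <- (pts[lm$base_left, ] + pts[lm$base_right, ]) / 2
  apex <- pts[lm$apex, ]
  axis <- apex - base_mid
  len <- sqrt(sum(axis^2))
  if (len <= 0) stop("degenerate blade axis")
  u <- axis / len
  perp <- c(-u[2], u[1])
  proj <- as.vector(pts %*% perp)
  width <- max(proj) - min(proj)
  area <- abs(polygon_signed_area(pts))
  hull <- convex_hull_area(pts)
  structure(list(length_um = len, width_um = width, area_um2 = area,
                 hull_area_um2 = hull, aspect_ratio = len / width,
                 dissection_index = hull / area),
            class = "blade_measures")
}

#' @export
print.blade_measures <- function(x, ...) {
  cat(sprintf("blade: length %.6g um, width %.6g um, aspect %.4g, DI %.6g\n",
              x$length_um, x$width_um, x$aspect_ratio, x$dissection_index))
  invisible(x)
}

#' Tooth-scale shape measures
#'
#' Tooth width is the Euclidean distance between its two sinus landmarks;
#' height is the perpendicular distance from the tip to the sinus-sinus
#' chord; the aspect ratio is height / width. Normalized variants divide
#' width by blade length and height by blade width, removing global blade
#' growth from the local tooth signal.
#'
#' @param contour a \code{\link{leaf_contour}}.
#' @param tooth_index row of \code{contour$teeth} to measure.
#' @param blade optional precomputed \code{\link{blade_measures}} (used for
#'   the normalizations; computed on demand when \code{NULL}).
#' @return List of class \code{tooth_measures}: \code{width_um},
#'   \code{height_um}, \code{aspect_ratio}, \code{width_over_blade_length},
#'   \code{height_over_blade_width}, \code{side}.
#' @export
tooth_measures <- function(contour, tooth_index, blade = NULL) {
  stopifnot(inherits(contour, "leaf_contour"),
            tooth_index >= 1, tooth_index <= nrow(contour$teeth))
  tth <- contour$teeth[tooth_index, ]
  p_prev <- contour$points[tth$sinus_prev, ]
  p_tip <- contour$points[tth$tip, ]
  p_next <- contour$points[tth$sinus_next, ]
  chord <- p_next - p_prev
  w <- sqrt(sum(chord^2))
  if (w <= 0) stop("zero-width tooth (coincident sinus landmarks)")
  # perpendicular distance from the tip to the sinus-sinus chord
  h <- abs(chord[1] * (p_tip[2] - p_prev[2]) -
             chord[2] * (p_tip[1] - p_prev[1])) / w
  if (is.null(blade)) blade <- blade_measures(contour)
  structure(list(width_um = w, height_um = h, aspect_ratio = h / w,
                 width_over_blade_length = w / blade$length_um,
                 height_over_blade_width = h / blade$width_um,
                 side = tth$side),
            class = "tooth_measures")
}

#' Count teeth per half-leaf
#'
#' @param contour a \code{\link{leaf_contour}}.
#' @param pooled also return the pooled per-half-leaf count stream (both
#'   sides as separate records), mirroring analyses that pool the two
#'   blade sides.
#' @return List with \code{left}, \code{right} counts; when
#'   \code{pooled = TRUE} also \code{pooled}, an integer vector of length
#'   2 (one count per side).
#' @export
count_teeth <- function(contour, pooled = FALSE) {
  stopifnot(inherits(contour, "leaf_contour"))
  left <- sum(contour$teeth$side == "left")
  right <- sum(contour$teeth$side == "right")
  out <- list(left = left, right = right)
  if (pooled) out$pooled <- c(left, right)
  out
}
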