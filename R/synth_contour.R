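#' Synthesize a landmarked serrated leaf contour
#'
#' Builds a lens-shaped blade (two circular arcs meeting at a short base
#' segment and at the apex) whose length follows the rank's Hill growth
#' curve and whose width is length / aspect_ratio(age), with one
#' raised-cosine marginal bump per initiated tooth. Tooth geometry is
#' imposed exactly on the landmarks: the sinus-to-sinus chord equals the
#' tooth width Hill curve and the perpendicular tip height equals the
#' tooth height Hill curve, both evaluated at (leaf age - tooth offset).
#' Landmark indices are exact by construction, so measuring the emitted
#' contour round-trips the generating values up to polygon discretization.
#'
#' @param leaf_age leaf age since initiation, hours (> 0).
#' @param rank organ rank (selects the blade Hill curve in
#'   \code{config$hill_by_rank}).
#' @param config a \code{\link{synth_config}}.
#' @param tooth_fractions margin arc-length fractions (base to apex) at
#'   which tooth ranks sit; default evenly spaced.
#' @param id contour identifier.
#' @return A \code{\link{leaf_contour}} with \code{age_h = leaf_age}.
#' @export
synthesize_leaf_contour <- function(leaf_age, rank, config,
                                    tooth_fractions = NULL, id = NULL) {
  stopifnot(inherits(config, "synth_config"), leaf_age > 0)
  hp <- config$hill_by_rank[[as.character(rank)]]
  if (is.null(hp)) stop(sprintf("no Hill parameters for rank %s", rank))
  L <- hill_eval(hp, leaf_age)
  AR <- config$aspect_ratio(leaf_age)
  stopifnot(L > 0, AR > 0)
  W <- L / AR
  wb <- 0.02 * W  # base half-width: short straight base segment

  # right-margin circular arc through base_right (wb, 0) and apex (0, L),
  # with sagitta solved so the widest point of the arc sits at x = W / 2
  P0 <- c(wb, 0); P1 <- c(0, L)
  chord <- sqrt(sum((P1 - P0)^2))
  M <- (P0 + P1) / 2
  d <- (P1 - P0) / chord
  nrm <- c(d[2], -d[1])  # points to +x for an upward chord
  geom_for <- function(hs) {
    R <- (chord^2 / 4 + hs^2) / (2 * hs)
    C <- M - (R - hs) * nrm
    list(R = R, C = C)
  }
  max_x <- function(hs) {
    # easternmost point of the circle; it lies on the arc for any sagitta
    # above ~wb/4 (the bulge direction is nearly due east)
    g <- geom_for(hs)
    g$C[1] + g$R
  }
  target <- W / 2
  lo <- wb / 2
  if (max_x(lo) > target)
    stop("aspect ratio too large for the base width; cannot fit arc")
  hs <- uniroot(function(h) max_x(h) - target,
                lower = lo, upper = W, tol = 1e-12 * W)$root
  g <- geom_for(hs)
  R <- g$R; C <- g$C

  ang <- function(p) atan2(p[2] - C[2], p[1] - C[1])
  a0 <- ang(P0); a1 <- ang(P1)
  # traverse from base_right to apex counterclockwise through the bulge
  da <- (a1 - a0) %% (2 * pi)
  S <- R * da  # margin arc length

  # teeth initiated so far on this margin
  ts <- tooth_schedule_for_rank(config, rank)
  tau <- leaf_age - ts$offsets_h
  present <- which(tau > 0)
  n_teeth <- length(present)
  if (is.null(tooth_fractions))
    tooth_fractions <- seq_len(length(ts$offsets_h)) / (length(ts$offsets_h) + 1)
  tooth_geo <- list()
  for (j in present) {
    w_t <- hill_eval(ts$width, tau[j])
    h_t <- hill_eval(ts$height, tau[j])
    if (w_t >= 2 * R)
      stop("tooth width exceeds the margin arc diameter; reduce tooth size or density")
    th_w <- asin(w_t / (2 * R))           # angular half-width: chord = width
    sag <- R * (1 - cos(th_w))            # margin arc sagitta under the chord
    A <- h_t - sag                        # radial amplitude so that
    if (A <= 0)                           # measured height = h_t exactly
      stop("tooth height too small for the local margin curvature; reduce bump density")
    phi_c <- a0 + tooth_fractions[j] * da
    tooth_geo[[length(tooth_geo) + 1]] <-
      list(phi_c = phi_c, th_w = th_w, A = A, rank = j)
  }
  # non-overlapping angular supports
  if (n_teeth >= 2) {
    ctr <- vapply(tooth_geo, function(tg) tg$phi_c, numeric(1))
    hw <- vapply(tooth_geo, function(tg) tg$th_w, numeric(1))
    o <- order(ctr)
    if (any(diff(ctr[o]) < hw[o][-n_teeth] + hw[o][-1]))
      stop("tooth bumps overlap; reduce bump height or density")
  }

  # vertex angles: uniform grid plus exact tooth landmark angles
  m_g <- max(16L, config$n_contour_points %/% 2L)
  phis <- seq(a0, a0 + da, length.out = m_g)
  for (tg in tooth_geo)
    phis <- c(phis, tg$phi_c - tg$th_w, tg$phi_c, tg$phi_c + tg$th_w)
  phis <- sort(unique(phis))
  # drop grid angles indistinguishable from a landmark angle
  keep <- c(TRUE, diff(phis) > 1e-12)
  phis <- phis[keep]

  bump <- rep(0, length(phis))
  lm_idx <- list()
  for (tg in tooth_geo) {
    inside <- abs(phis - tg$phi_c) < tg$th_w
    bump[inside] <- bump[inside] +
      tg$A * 0.5 * (1 + cos(pi * (phis[inside] - tg$phi_c) / tg$th_w))
    lm_idx[[length(lm_idx) + 1]] <-
      c(which.min(abs(phis - (tg$phi_c - tg$th_w))),
        which.min(abs(phis - tg$phi_c)),
        which.min(abs(phis - (tg$phi_c + tg$th_w))))
  }
  r_phi <- R + bump
  right <- cbind(C[1] + r_phi * cos(phis), C[2] + r_phi * sin(phis))
  n_r <- nrow(right)

  # left margin: mirror of the right, traversed apex -> base_left
  left <- right[(n_r - 1):1, , drop = FALSE]
  left[, 1] <- -left[, 1]
  pts <- rbind(right, left)
  n_tot <- nrow(pts)  # = 2 n_r - 1

  mirror_idx <- function(i) 2L * n_r - i  # right index -> left index
  right_rows <- list(); left_rows <- list()
  for (jj in seq_along(tooth_geo)) {
    li <- lm_idx[[jj]]
    right_rows[[jj]] <-
      data.frame(side = "right", sinus_prev = li[1], tip = li[2],
                 sinus_next = li[3])
    left_rows[[jj]] <-
      data.frame(side = "left", sinus_prev = mirror_idx(li[3]),
                 tip = mirror_idx(li[2]), sinus_next = mirror_idx(li[1]))
  }
  # base-to-apex ordering: ascending tip index on the right margin,
  # descending on the left (the left margin runs apex -> base)
  teeth <- if (length(right_rows) > 0) {
    r <- do.call(rbind, right_rows); r <- r[order(r$tip), , drop = FALSE]
    l <- do.call(rbind, left_rows); l <- l[order(-l$tip), , drop = FALSE]
    rbind(r, l)
  } else empty_teeth()
  rownames(teeth) <- NULL

  out <- tryCatch(
    leaf_contour(pts, base_left = n_tot, base_right = 1L, apex = n_r,
                 teeth = teeth,
                 id = if (is.null(id)) sprintf("synthetic_r%d_t%g", rank, leaf_age) else id,
                 age_h = leaf_age, check = TRUE),
    error = function(e)
      stop(sprintf("synthetic contour invalid (%s); reduce bump height or density",
                   conditionMessage(e))))
  out
}
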