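#' Date tooth ranks from tooth-count observations
#'
#' Applies the organ-apparition machinery at the sub-organ scale: the
#' observations are (leaf age, number of teeth) pairs, the clock is leaf
#' age instead of plant age, and the recovered 50%-crossing times are
#' per-tooth-rank initiation times (hours after leaf initiation).
#'
#' @param tooth_counts data frame with columns \code{leaf_age_h} and
#'   \code{count} (teeth per half-leaf; pool sides upstream if desired).
#' @param seed seed forwarded to the resampling and the fit.
#' @param ... further arguments to \code{\link{fit_initiation_model}}.
#' @return List: \code{initiation_times_h} (per tooth rank), \code{fit}
#'   (the underlying \code{initiation_fit}).
#' @export
date_teeth <- function(tooth_counts, seed = 1L, ...) {
  stopifnot(is.data.frame(tooth_counts),
            all(c("leaf_age_h", "count") %in% names(tooth_counts)))
  obs <- data.frame(individual_id = seq_len(nrow(tooth_counts)),
                    age_h = tooth_counts$leaf_age_h,
                    organ_count = tooth_counts$count)
  cat_obs <- categorize(obs, category_map("identity"))
  bal <- resample_categories(cat_obs, seed = seed)
  emp <- empirical_dynamics(bal)
  fit <- fit_initiation_model(emp, seed = seed, ...)
  list(initiation_times_h = fit$initiation_times_h, fit = fit)
}

#' Time-weighted mean contour at a query age
#'
#' Vertex-wise weighted mean of normalized, dated contours with Gaussian
#' kernel weights \eqn{w_i = \exp(-(age_i - t)^2 / 2h^2)}. The bandwidth
#' adapts to the sampling density: h is the distance from the query age to
#' the \code{knn}-th nearest sample age. Local asymmetry in the temporal
#' sampling is bounded by capping the total weight contributed by each
#' temporal side of the query at \code{side_ratio_cap} times the lighter
#' side (the heavier side is scaled down). Contours must share a vertex
#' count (use \code{\link{normalize_contour}}); the result inherits the
#' tooth landmarks of the highest-weight contributor.
#'
#' @param contours list of normalized \code{\link{leaf_contour}}s with
#'   \code{age_h} set.
#' @param query_age_h query age, hours.
#' @param knn neighbour order used for the adaptive bandwidth (default 15,
#'   capped at the sample size).
#' @param side_ratio_cap maximal before/after weight ratio (default 3).
#' @param gap_factor error if no sample age lies within
#'   \code{gap_factor * h} of the query (default 5): a sampling gap.
#' @return A \code{leaf_contour} at the query age; attributes \code{ess}
#'   (effective sample size \eqn{(\sum w)^2 / \sum w^2}) and
#'   \code{bandwidth_h}.
#' @export
mean_contour <- function(contours, query_age_h, knn = 15L,
                         side_ratio_cap = 3, gap_factor = 5) {
  stopifnot(length(contours) >= 1)
  ages <- vapply(contours, function(ct) {
    if (is.null(ct$age_h)) stop("all contours must be dated (age_h set)")
    ct$age_h
  }, numeric(1))
  nv <- vapply(contours, function(ct) nrow(ct$points), integer(1))
  if (length(unique(nv)) != 1L)
    stop("contours must share a vertex count; normalize them first")
  d <- abs(ages - query_age_h)
  # gap guard: the nearest sample must lie within gap_factor typical
  # knn-neighbourhood widths (typical width from the median age spacing,
  # so that stretching the adaptive bandwidth cannot hide a real gap)
  u_ages <- sort(unique(ages))
  if (length(u_ages) >= 2) {
    h_ref <- min(knn, length(u_ages)) * mean(diff(u_ages))
    if (min(d) > gap_factor * h_ref)
      stop(sprintf("no contour within %g bandwidths of query age %g h (sampling gap)",
                   gap_factor, query_age_h))
  }
  h <- sort(d)[min(knn, length(d))]
  if (h <= 0) {
    # query coincides with >= knn sample ages: average the coincident ones
    w <- as.numeric(d == 0)
  } else {
    w <- exp(-d^2 / (2 * h^2))
  }
  # side-balance cap
  before <- ages < query_age_h
  after <- ages > query_age_h
  s_b <- sum(w[before]); s_a <- sum(w[after])
  if (s_b > 0 && s_a > 0) {
    if (s_b > side_ratio_cap * s_a) w[before] <- w[before] * side_ratio_cap * s_a / s_b
    if (s_a > side_ratio_cap * s_b) w[after] <- w[after] * side_ratio_cap * s_b / s_a
  }
  w <- w / sum(w)
  acc <- matrix(0, nrow = nv[1], ncol = 2)
  for (i in seq_along(contours))
    if (w[i] > 0) acc <- acc + w[i] * contours[[i]]$points
  dominant <- contours[[which.max(w)]]
  out <- leaf_contour(acc, base_left = dominant$landmarks$base_left,
                      base_right = dominant$landmarks$base_right,
                      apex = dominant$landmarks$apex,
                      teeth = dominant$teeth,
                      id = sprintf("mean_age_%g", query_age_h),
                      age_h = query_age_h, check = FALSE)
  attr(out, "ess") <- 1 / sum(w^2)
  attr(out, "bandwidth_h") <- h
  out
}

#' Reconstruct an age-indexed mean-shape trajectory
#'
#' Computes the time-weighted mean contour at each query age and measures
#' blade morphology on each mean shape, producing the trajectory table of
#' shape descriptors as continuous functions of organ age. Query ages in
#' sampling gaps are skipped with a message and reported in
#' \code{skipped}.
#'
#' @param contours list of dated \code{\link{leaf_contour}}s; normalized
#'   internally when needed.
#' @param query_ages_h ages (hours) at which to reconstruct mean shapes.
#' @param points_per_side forwarded to \code{\link{normalize_contour}}.
#' @param ... forwarded to \code{\link{mean_contour}}.
#' @return Object of class \code{mean_trajectory}: \code{contours} (list
#'   of mean \code{leaf_contour}s), \code{measures} (data frame
#'   \code{age_h, length_um, width_um, area_um2, hull_area_um2,
#'   aspect_ratio, dissection_index, ess}), \code{skipped} (ages that
#'   failed, with reasons).
#' @export
reconstruct_trajectory <- function(contours, query_ages_h,
                                   points_per_side = 200L, ...) {
  stopifnot(length(contours) >= 1, length(query_ages_h) >= 1)
  normed <- lapply(contours, function(ct) {
    if (is.null(attr(ct, "normalized")) ||
        attr(ct, "normalized") != points_per_side)
      normalize_contour(ct, points_per_side) else ct
  })
  means <- list(); rows <- list(); skipped <- list()
  for (q in query_ages_h) {
    mc <- tryCatch(mean_contour(normed, q, ...), error = function(e) e)
    if (inherits(mc, "error")) {
      message(sprintf("skipping query age %g h: %s", q, conditionMessage(mc)))
      skipped[[length(skipped) + 1]] <- data.frame(age_h = q,
                                                   reason = conditionMessage(mc))
      next
    }
    bm <- blade_measures(mc)
    means[[length(means) + 1]] <- mc
    rows[[length(rows) + 1]] <-
      data.frame(age_h = q, length_um = bm$length_um, width_um = bm$width_um,
                 area_um2 = bm$area_um2, hull_area_um2 = bm$hull_area_um2,
                 aspect_ratio = bm$aspect_ratio,
                 dissection_index = bm$dissection_index,
                 ess = attr(mc, "ess"))
  }
  structure(list(contours = means,
                 measures = if (length(rows) > 0) do.call(rbind, rows)
                 else data.frame(),
                 skipped = if (length(skipped) > 0) do.call(rbind, skipped)
                 else data.frame()),
            class = "mean_trajectory")
}

#' @export
print.mean_trajectory <- function(x, ...) {
  cat(sprintf("mean-shape trajectory: %d ages reconstructed (%d skipped)\n",
              length(x$contours), nrow(x$skipped)))
  if (nrow(x$measures) > 0)
    cat(sprintf("age range %.4g-%.4g h; blade length %.4g-%.4g um\n",
                min(x$measures$age_h), max(x$measures$age_h),
                min(x$measures$length_um), max(x$measures$length_um)))
  invisible(x)
}

#' Per-tooth measurement table across dated contours
#'
#' Measures every annotated tooth on every dated contour and attaches the
#' tooth age (leaf age minus the tooth rank's initiation time) when
#' initiation times are supplied. Teeth not yet initiated at the leaf's
#' age are flagged with \code{NA} tooth age.
#'
#' @param contours list of dated \code{\link{leaf_contour}}s.
#' @param tooth_initiation_h optional per-tooth-rank initiation times
#'   (hours after leaf initiation); tooth rank is the base-to-apex order
#'   within each side.
#' @return Data frame \code{contour_id, side, tooth_rank, leaf_age_h,
#'   tooth_age_h, width_um, height_um, aspect, width_norm, height_norm}.
#' @export
tooth_measure_table <- function(contours, tooth_initiation_h = NULL) {
  rows <- list()
  for (ct in contours) {
    if (nrow(ct$teeth) == 0) next
    bm <- blade_measures(ct)
    for (side in c("left", "right")) {
      idx <- which(ct$teeth$side == side)
      for (r in seq_along(idx)) {
        tm <- tooth_measures(ct, idx[r], bm)
        t_age <- if (!is.null(tooth_initiation_h) && r <= length(tooth_initiation_h) &&
                     !is.null(ct$age_h))
          as.numeric(tooth_age(ct$age_h, tooth_initiation_h[r])) else NA_real_
        rows[[length(rows) + 1]] <-
          data.frame(contour_id = ct$id, side = side, tooth_rank = r,
                     leaf_age_h = if (is.null(ct$age_h)) NA_real_ else ct$age_h,
                     tooth_age_h = t_age,
                     width_um = tm$width_um, height_um = tm$height_um,
                     aspect = tm$aspect_ratio,
                     width_norm = tm$width_over_blade_length,
                     height_norm = tm$height_over_blade_width)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contour_id = character(0), side = character(0),
                      tooth_rank = integer(0), leaf_age_h = numeric(0),
                      tooth_age_h = numeric(0), width_um = numeric(0),
                      height_um = numeric(0), aspect = numeric(0),
                      width_norm = numeric(0), height_norm = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
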