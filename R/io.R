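#' Read and write static organ-count observations
#'
#' CSV schema: \code{individual_id,age_h,organ_count}.
#'
#' @param path file path.
#' @return \code{read_counts}: data frame with those columns.
#' @export
read_counts <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "age_h", "organ_count")
  if (!all(need %in% names(d)))
    stop(sprintf("counts CSV must have columns %s", paste(need, collapse = ", ")))
  if (any(d$age_h < 0)) stop("negative ages in counts CSV")
  if (any(d$organ_count < 0)) stop("negative organ counts in counts CSV")
  d[, need]
}

#' @param counts data frame to write.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  write.csv(counts[, c("individual_id", "age_h", "organ_count")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read and write static blade-length observations
#'
#' CSV schema: \code{individual_id,plant_age_h,length_um}.
#'
#' @param path file path.
#' @return \code{read_lengths}: data frame with those columns.
#' @export
read_lengths <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "plant_age_h", "length_um")
  if (!all(need %in% names(d)))
    stop(sprintf("lengths CSV must have columns %s", paste(need, collapse = ", ")))
  d[, need]
}

#' @param lengths data frame to write.
#' @rdname read_lengths
#' @export
write_lengths <- function(lengths, path) {
  write.csv(lengths[, c("individual_id", "plant_age_h", "length_um")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read and write landmarked contours (JSON)
#'
#' Interchange schema: a JSON list of objects \code{\{id, age_h
#' (optional), points: [[x_um, y_um], ...], landmarks: \{base_left,
#' base_right, apex, teeth: [[s_prev, tip, s_next], ...],
#' teeth_sides: ["left"|"right", ...] (optional)\}\}} with 0-based vertex
#' indices. When \code{teeth_sides} is absent, the side of each tooth is
#' inferred from the margin its tip index falls on (before vs after the
#' apex in polygon order).
#'
#' @param path file path.
#' @return \code{read_contours}: list of \code{\link{leaf_contour}}s.
#' @export
read_contours <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(o) {
    pts <- do.call(rbind, lapply(o$points, function(p) c(p[[1]], p[[2]])))
    lm <- o$landmarks
    apex1 <- lm$apex + 1L
    teeth <- empty_teeth()
    if (!is.null(lm$teeth) && length(lm$teeth) > 0) {
      tri <- do.call(rbind, lapply(lm$teeth, function(tt)
        c(tt[[1]], tt[[2]], tt[[3]]) + 1L))
      sides <- if (!is.null(lm$teeth_sides))
        unlist(lm$teeth_sides)
      else ifelse(tri[, 2] <= apex1, "right", "left")
      teeth <- data.frame(side = sides, sinus_prev = tri[, 1],
                          tip = tri[, 2], sinus_next = tri[, 3])
    }
    leaf_contour(pts,
                 base_left = lm$base_left + 1L,
                 base_right = lm$base_right + 1L,
                 apex = apex1, teeth = teeth,
                 id = if (is.null(o$id)) NA_character_ else o$id,
                 age_h = o$age_h, check = FALSE)
  })
}

#' @param contours list of \code{\link{leaf_contour}}s to write.
#' @rdname read_contours
#' @export
write_contours <- function(contours, path) {
  payload <- lapply(contours, function(ct) {
    o <- list(id = ct$id,
              points = unname(apply(ct$points, 1, as.list, simplify = FALSE)),
              landmarks = list(
                base_left = ct$landmarks$base_left - 1L,
                base_right = ct$landmarks$base_right - 1L,
                apex = ct$landmarks$apex - 1L,
                teeth = unname(apply(
                  as.matrix(ct$teeth[, c("sinus_prev", "tip", "sinus_next")]) - 1L,
                  1, as.list, simplify = FALSE)),
                teeth_sides = as.list(ct$teeth$side)))
    if (!is.null(ct$age_h)) o$age_h <- ct$age_h
    o
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an initiation-model fit report (JSON)
#'
#' Schema: \code{\{K, params: [\{k, a, b, c\}], cost,
#' initiation_times_h: [...], seed\}}.
#'
#' @param fit an \code{\link{initiation_fit}}.
#' @param path file path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "initiation_fit"))
  payload <- list(K = fit$K,
                  params = lapply(seq_len(nrow(fit$params)), function(i)
                    as.list(fit$params[i, c("k", "a", "b", "c")])),
                  cost = fit$cost,
                  initiation_times_h = fit$initiation_times_h,
                  seed = fit$diagnostics$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write predicted-versus-empirical dynamics (CSV)
#'
#' Long-format table \code{age_h,k,N_emp,N_pred} over the event-time grid.
#'
#' @param fit an \code{\link{initiation_fit}}.
#' @param path file path.
#' @export
write_dynamics_csv <- function(fit, path) {
  stopifnot(inherits(fit, "initiation_fit"))
  emp <- fit$empirical
  pred <- fit$predicted
  idx <- match(emp$times, pred$times)
  rows <- do.call(rbind, lapply(0:emp$K, function(k)
    data.frame(age_h = emp$times, k = k,
               N_emp = emp$occupancy[, k + 1],
               N_pred = pred$occupancy[idx, k + 1])))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a growth-calibration report (JSON)
#'
#' Schema: \code{\{rank, l_max_um, t_half_h, n, weighted_sse, t_infl_h,
#' v_max_um_per_h, rgr_per_h, T_h\}}.
#'
#' @param hill_fit a \code{\link{fit_hill}} result.
#' @param rank organ rank the calibration belongs to.
#' @param T_h initiation time used for the age shift.
#' @param path file path.
#' @export
write_calibration <- function(hill_fit, rank, T_h, path) {
  gf <- growth_features(hill_fit$params)
  payload <- list(rank = rank,
                  l_max_um = hill_fit$params$l_max,
                  t_half_h = hill_fit$params$t_half,
                  n = hill_fit$params$n,
                  weighted_sse = hill_fit$weighted_sse,
                  t_infl_h = gf$t_infl, v_max_um_per_h = gf$v_max,
                  rgr_per_h = gf$rgr_at_infl, T_h = T_h)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate an on-disk synthetic dataset bundle
#'
#' Writes the three dataset types (counts CSV, per-rank lengths CSV,
#' contours JSON) plus a ground-truth JSON recording every generating
#' parameter and the realized initiation schedule. Identical config and
#' seed produce identical bundles.
#'
#' @param config a \code{\link{synth_config}}.
#' @param dir output directory (created if needed).
#' @param length_ranks ranks for which length datasets are written
#'   (default: all ranks with Hill parameters).
#' @param contour_rank rank for which a contour series is written.
#' @param contour_ages leaf ages of the contour series.
#' @return Invisibly, a named list of the written paths.
#' @export
generate_dataset <- function(config, dir,
                             length_ranks = as.integer(names(config$hill_by_rank)),
                             contour_rank = min(length_ranks),
                             contour_ages = seq(80, 500, by = 60)) {
  stopifnot(inherits(config, "synth_config"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop(sprintf("cannot create output directory '%s'", dir))
  paths <- list()
  schedule <- simulate_initiation_schedule(config)
  counts <- simulate_static_counts(schedule, config)
  paths$counts <- file.path(dir, "counts.csv")
  write_counts(counts, paths$counts)
  paths$lengths <- character(0)
  for (r in length_ranks) {
    lr <- simulate_length_observations(config, r)
    p <- file.path(dir, sprintf("lengths_rank%02d.csv", r))
    write_lengths(lr, p)
    paths$lengths <- c(paths$lengths, p)
  }
  contours <- lapply(seq_along(contour_ages), function(i)
    synthesize_leaf_contour(contour_ages[i], contour_rank, config,
                            id = sprintf("c%03d", i)))
  paths$contours <- file.path(dir, "contours.json")
  write_contours(contours, paths$contours)
  ts <- config$tooth_schedule
  shared <- all(c("offsets_h", "width", "height") %in% names(ts))
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(n_individuals = config$n_individuals, K = config$K,
         plastochron_h = config$plastochron_h,
         jitter_sd_h = config$jitter_sd_h,
         sampling_window_h = config$sampling_window_h,
         length_noise_cv = config$length_noise_cv,
         n_contour_points = config$n_contour_points,
         seed = config$seed,
         hill_by_rank = lapply(config$hill_by_rank, unclass),
         tooth_schedule = if (shared)
           list(offsets_h = ts$offsets_h, width = unclass(ts$width),
                height = unclass(ts$height))
         else lapply(ts, function(s)
           list(offsets_h = s$offsets_h, width = unclass(s$width),
                height = unclass(s$height))),
         contour_rank = contour_rank, contour_ages = contour_ages,
         schedule = schedule),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(paths)
}
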