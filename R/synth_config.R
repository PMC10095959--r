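#' Configuration of the synthetic-data generator
#'
#' Bundles every parameter of the ground-truthed generator that emulates the
#' three static dataset types the pipeline consumes: organ-count snapshots,
#' blade-length snapshots, and landmarked serrated contours.
#'
#' @param n_individuals number of individuals; each contributes exactly one
#'   destructive snapshot (matching the dissection protocol that motivates
#'   the ergodic reconstruction).
#' @param K maximal organ rank (>= 1).
#' @param plastochron_h mean interval between successive organ initiations,
#'   hours (> 0).
#' @param jitter_sd_h SD of per-individual Gaussian jitter added to each
#'   initiation time (>= 0); draws violating the strict rank ordering are
#'   resampled.
#' @param sampling_window_h length-2 vector (min, max) of plant ages at
#'   which snapshots are drawn uniformly.
#' @param hill_by_rank list mapping rank (as character or position) to a
#'   \code{\link{hill_params}} object for blade-length growth.
#' @param length_noise_cv coefficient of variation of the multiplicative
#'   Gaussian noise applied to synthetic lengths (>= 0).
#' @param tooth_schedule list with \code{offsets_h} (per-tooth initiation
#'   offsets, hours after leaf initiation, strictly increasing),
#'   \code{width} and \code{height} (\code{hill_params} of the tooth growth
#'   laws). A single schedule shared across ranks encodes the shared tooth
#'   growth law; per-rank overrides may be supplied as a list of such lists
#'   named by rank.
#' @param aspect_ratio function age_h -> blade length/width ratio; the
#'   default reproduces the elongation-rounding-elongation pattern of
#'   rosette leaf blades.
#' @param n_contour_points approximate vertex budget per synthetic contour
#'   (even, >= 32).
#' @param emit_zero_lengths if \code{TRUE}, pre-initiation size snapshots
#'   are emitted with length 0 instead of being omitted.
#' @param seed RNG seed consumed by the generator functions.
#'
#' @return An object of class \code{synth_config}.
#' @seealso \code{\link{wt_default_config}} for the headline preset.
#' @export
synth_config <- function(n_individuals, K, plastochron_h, jitter_sd_h,
                         sampling_window_h,
                         hill_by_rank = default_hill_by_rank(K),
                         length_noise_cv = 0,
                         tooth_schedule = default_tooth_schedule(),
                         aspect_ratio = default_aspect_ratio,
                         n_contour_points = 256L,
                         emit_zero_lengths = FALSE,
                         seed = 1L) {
  stopifnot(n_individuals >= 1, K >= 1, length(sampling_window_h) == 2L,
            sampling_window_h[1] < sampling_window_h[2],
            length_noise_cv >= 0, is.function(aspect_ratio))
  if (!(plastochron_h > 0)) stop("plastochron_h must be > 0")
  if (jitter_sd_h < 0) stop("jitter_sd_h must be >= 0")
  if (n_contour_points < 32L || n_contour_points %% 2L != 0L)
    stop("n_contour_points must be even and >= 32")
  for (hp in hill_by_rank)
    stopifnot(inherits(hp, "hill_params"))
  validate_tooth_schedule(tooth_schedule)
  structure(list(n_individuals = as.integer(n_individuals), K = as.integer(K),
                 plastochron_h = plastochron_h, jitter_sd_h = jitter_sd_h,
                 sampling_window_h = as.numeric(sampling_window_h),
                 hill_by_rank = hill_by_rank,
                 length_noise_cv = length_noise_cv,
                 tooth_schedule = tooth_schedule,
                 aspect_ratio = aspect_ratio,
                 n_contour_points = as.integer(n_contour_points),
                 emit_zero_lengths = emit_zero_lengths,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic-data config: %d individuals, K = %d, ",
                     "plastochron %.3g h (jitter SD %.3g h), window (%g, %g) h\n"),
              x$n_individuals, x$K, x$plastochron_h, x$jitter_sd_h,
              x$sampling_window_h[1], x$sampling_window_h[2]))
  invisible(x)
}

validate_tooth_schedule <- function(ts) {
  one <- function(s) {
    stopifnot(is.list(s), all(c("offsets_h", "width", "height") %in% names(s)),
              all(diff(s$offsets_h) > 0), all(s$offsets_h > 0),
              inherits(s$width, "hill_params"), inherits(s$height, "hill_params"))
  }
  if (all(c("offsets_h", "width", "height") %in% names(ts))) one(ts)
  else for (s in ts) one(s)
  invisible(TRUE)
}

# per-rank tooth schedule lookup: shared schedule unless overridden by rank
tooth_schedule_for_rank <- function(config, rank) {
  ts <- config$tooth_schedule
  if (all(c("offsets_h", "width", "height") %in% names(ts))) return(ts)
  key <- as.character(rank)
  if (!key %in% names(ts)) stop(sprintf("no tooth schedule for rank %s", key))
  ts[[key]]
}

#' Default per-rank blade growth laws
#'
#' Mature length and half-max age increase linearly with rank, emulating the
#' graded, homothetically related growth kinetics of successive rosette
#' leaves (later leaves grow larger and reach maximal growth later).
#'
#' @param K maximal rank.
#' @return Named list (ranks \code{"1"} .. \code{"K"}) of
#'   \code{\link{hill_params}}.
#' @export
default_hill_by_rank <- function(K) {
  setNames(lapply(seq_len(K), function(r)
    hill_params(l_max = 4000 + 1200 * r, t_half = 200 + 12 * r, n = 4)),
    as.character(seq_len(K)))
}

#' Default tooth growth schedule
#'
#' Three teeth initiated at increasing offsets after leaf initiation, all
#' following one shared Hill growth law for width and one for height —
#' the registration property that lets width-versus-tooth-age curves of
#' different tooth ranks collapse onto a single curve.
#'
#' @return A tooth schedule list (\code{offsets_h}, \code{width},
#'   \code{height}).
#' @export
default_tooth_schedule <- function() {
  list(offsets_h = c(60, 132, 210),
       width = hill_params(l_max = 600, t_half = 150, n = 2.5),
       height = hill_params(l_max = 220, t_half = 180, n = 2.5))
}

#' Default blade aspect-ratio trajectory
#'
#' Length/width ratio as a function of leaf age (hours): elongated early,
#' transiently rounder around 260 h, elongating again towards maturity.
#'
#' @param age_h leaf age(s), hours.
#' @return Aspect ratio(s) (dimensionless, > 1).
#' @export
default_aspect_ratio <- function(age_h) {
  2.5 - 1.2 * exp(-((age_h - 260) / 130)^2)
}

#' The headline synthetic regime
#'
#' Preset encoding the reference wild-type-like regime: 300 individuals,
#' K = 11 organ ranks, a 24 h plastochron with 6 h initiation jitter, and
#' snapshots drawn uniformly over (0, 600) h.
#'
#' @param ... overrides forwarded to \code{\link{synth_config}}.
#' @return A \code{\link{synth_config}}.
#' @examples
#' cfg <- wt_default_config(seed = 7)
#' @export
wt_default_config <- function(...) {
  args <- list(n_individuals = 300L, K = 11L, plastochron_h = 24,
               jitter_sd_h = 6, sampling_window_h = c(0, 600),
               length_noise_cv = 0.1)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}
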