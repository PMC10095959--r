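#' Simulate ground-truth organ initiation schedules
#'
#' Draws, for every individual, the true initiation time of each organ rank:
#' \eqn{T_{i,r} = r \cdot plastochron + \epsilon_{i,r}} with
#' \eqn{\epsilon \sim N(0, jitter\_sd^2)}, truncated so that
#' \eqn{T_{i,r} > T_{i,r-1}} (violating draws are resampled, preserving the
#' strictly sequential acquisition the initiation model assumes).
#'
#' @param config a \code{\link{synth_config}}.
#' @return Data frame \code{individual_id, rank, T_h}; reproducible under
#'   the config seed.
#' @export
simulate_initiation_schedule <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_individuals; K <- config$K
  p <- config$plastochron_h; sdj <- config$jitter_sd_h
  Tm <- matrix(NA_real_, nrow = n, ncol = K)
  for (i in seq_len(n)) {
    prev <- 0
    for (r in seq_len(K)) {
      repeat {
        t_r <- r * p + if (sdj > 0) rnorm(1, 0, sdj) else 0
        if (t_r > prev) break
      }
      Tm[i, r] <- t_r
      prev <- t_r
    }
  }
  data.frame(individual_id = rep(seq_len(n), each = K),
             rank = rep(seq_len(K), times = n),
             T_h = as.vector(t(Tm)))
}

#' Simulate static organ-count snapshots
#'
#' Each individual is observed destructively exactly once, at an age drawn
#' uniformly from the sampling window; its organ count is the number of
#' ranks whose true initiation time lies at or before that age.
#'
#' @param schedule output of \code{\link{simulate_initiation_schedule}}.
#' @param config the \code{\link{synth_config}} used to build the schedule.
#' @return Data frame \code{individual_id, age_h, organ_count} (one row per
#'   individual, counts in 0..K).
#' @export
simulate_static_counts <- function(schedule, config) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(schedule) || nrow(schedule) == 0L) stop("empty schedule")
  ids <- sort(unique(schedule$individual_id))
  set.seed(config$seed + 1L)
  ages <- runif(length(ids), config$sampling_window_h[1], config$sampling_window_h[2])
  counts <- vapply(seq_along(ids), function(j) {
    Ti <- schedule$T_h[schedule$individual_id == ids[j]]
    sum(Ti <= ages[j])
  }, numeric(1))
  data.frame(individual_id = ids, age_h = ages, organ_count = as.integer(counts))
}

#' Simulate static blade-length snapshots for one rank
#'
#' Fresh individuals (destructive protocol: disjoint from the count
#' snapshots) are sampled once each; the blade length of the requested rank
#' is the rank's Hill curve evaluated at (plant age - initiation time),
#' perturbed by multiplicative Gaussian noise of coefficient of variation
#' \code{length_noise_cv}. Pre-initiation rows are omitted by default, or
#' emitted with length 0 when \code{config$emit_zero_lengths} is set.
#'
#' @param config a \code{\link{synth_config}}.
#' @param rank organ rank to measure; must have an entry in
#'   \code{config$hill_by_rank}.
#' @param n_obs number of individuals sampled (default
#'   \code{config$n_individuals}).
#' @return Data frame \code{individual_id, plant_age_h, length_um} plus the
#'   ground-truth columns \code{T_h} (initiation time) and
#'   \code{true_length_um} (noiseless length).
#' @export
simulate_length_observations <- function(config, rank,
                                         n_obs = config$n_individuals) {
  stopifnot(inherits(config, "synth_config"))
  key <- as.character(rank)
  if (!key %in% names(config$hill_by_rank))
    stop(sprintf("no Hill parameters for rank %s in config$hill_by_rank", key))
  hp <- config$hill_by_rank[[key]]
  set.seed(config$seed + 2L + as.integer(rank))
  p <- config$plastochron_h; sdj <- config$jitter_sd_h
  # initiation time of this rank: same generative law as the schedule
  T_h <- rank * p + if (sdj > 0) rnorm(n_obs, 0, sdj) else rep(0, n_obs)
  T_h <- pmax(T_h, 1e-6)
  age <- runif(n_obs, config$sampling_window_h[1], config$sampling_window_h[2])
  leaf_age <- age - T_h
  true_len <- ifelse(leaf_age > 0, hill_eval(hp, pmax(leaf_age, 0)), 0)
  noise <- if (config$length_noise_cv > 0)
    rnorm(n_obs, 0, config$length_noise_cv) else rep(0, n_obs)
  len <- true_len * (1 + noise)
  out <- data.frame(individual_id = seq_len(n_obs), plant_age_h = age,
                    length_um = len, T_h = T_h, true_length_um = true_len)
  if (!config$emit_zero_lengths) out <- out[leaf_age > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
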