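# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the event-driven simulator integrates hazards
# per individual, and the backward counter replays the event-by-event
# reconstruction literally.

# cumulative logistic hazard integral: Lambda(t0, t) for sigma(t) =
# c / (1 + exp(-b (t - a))); closed form via softplus
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

cum_hazard <- function(a, b, cc, t0, t1) {
  if (b == 0) return(cc / 2 * (t1 - t0))
  (cc / b) * (softplus(b * (t1 - a)) - softplus(b * (t0 - a)))
}

# draw the next transition time after t0 under the time-inhomogeneous
# hazard, by inverting the cumulative hazard against an Exp(1) draw
draw_transition <- function(a, b, cc, t0) {
  target <- rexp(1)
  lo <- t0
  hi <- t0 + target / cc + 1
  while (cum_hazard(a, b, cc, t0, hi) < target) {
    hi <- t0 + 2 * (hi - t0)
    if (hi > t0 + 1e7) return(Inf)
  }
  uniroot(function(t) cum_hazard(a, b, cc, t0, t) - target,
          lower = lo, upper = hi, tol = 1e-8)$root
}

# event-driven simulation of N individuals flowing through K transitions;
# returns an N x K matrix of transition times
simulate_individuals <- function(params, N) {
  K <- nrow(params)
  Tm <- matrix(Inf, nrow = N, ncol = K)
  for (i in seq_len(N)) {
    t_cur <- 0
    for (k in seq_len(K)) {
      t_cur <- draw_transition(params$a[k], params$b[k], params$c[k], t_cur)
      if (!is.finite(t_cur)) break
      Tm[i, k] <- t_cur
    }
  }
  Tm
}

# occupancy counts (categories 0..K) of the individual-level simulation
occupancy_counts <- function(Tm, t) {
  n_done <- rowSums(Tm <= t)
  vapply(0:ncol(Tm), function(k) sum(n_done == k), numeric(1))
}

# literal backward event-by-event reconstruction of the category dynamics;
# returns occupancy values at the sorted unique observation ages
backward_count_oracle <- function(obs, N, K) {
  ages <- sort(unique(obs$age_h), decreasing = TRUE)
  occ <- matrix(NA_real_, nrow = length(ages), ncol = K + 1)
  # state at t = +infinity: everyone has reached category K
  state <- c(rep(0, K), N)
  for (j in seq_along(ages)) {
    s <- ages[j]
    # value at s includes events at age exactly s (right-continuity):
    # record before passing them on the way backwards
    occ[j, ] <- state
    at_s <- obs[obs$age_h == s, , drop = FALSE]
    for (r in seq_len(nrow(at_s))) {
      k <- at_s$category[r]
      if (k < K) {
        state[k + 1] <- state[k + 1] + 1        # N_k gains going backwards
        state[k + 2] <- state[k + 2] - 1        # N_{k+1} loses
      }
      # a category-K observation carries no transition information
    }
  }
  occ[rev(seq_len(nrow(occ))), , drop = FALSE]  # ascending ages
}

# dense-grid numerical maximization of the growth rate of a Hill curve,
# independent of the package's analytic formulas
numeric_growth_max <- function(hp, n_grid = 40001L) {
  a <- seq(1e-9, 3 * hp$t_half, length.out = n_grid)
  l <- hill_eval(hp, a)
  da <- a[2] - a[1]
  slope <- (l[-1] - l[-length(l)]) / da
  mid <- (a[-1] + a[-length(a)]) / 2
  i <- which.max(slope)
  list(t_infl = mid[i], v_max = slope[i])
}

# small helper: a fresh synthetic config suitable for quick tests
quick_config <- function(seed = 1L, ...) {
  args <- list(n_individuals = 60L, K = 3L, plastochron_h = 24,
               jitter_sd_h = 3, sampling_window_h = c(0, 150), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}
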