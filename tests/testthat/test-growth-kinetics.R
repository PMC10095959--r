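test_that("Hill curve evaluation, inversion and derived features are consistent", {
  hp <- hill_params(100, 200, 3)
  expect_equal(hill_eval(hp, 200), 50)
  expect_equal(hill_eval(hp, 0), 0)
  expect_equal(hill_eval(hp, 100), 100 * 1e6 / (8e6 + 1e6))
  # strict monotonicity
  a <- seq(1, 2000, by = 1)
  expect_true(all(diff(hill_eval(hp, a)) > 0))

  # inverse round-trips to 1e-9 relative
  for (age in c(10, 100, 1000)) {
    back <- hill_inverse(hp, hill_eval(hp, age))
    expect_lt(abs(back - age) / age, 1e-9)
  }
  expect_equal(hill_inverse(hp, 50), 200)
  expect_error(hill_inverse(hp, 100), "l_max")
  expect_warning(out <- hill_inverse(hp, 99.9, clamp = TRUE), "clamped")
  expect_true(is.finite(out))

  # closed-form inflection features against the numerical oracle
  gf <- growth_features(hp)
  expect_equal(gf$t_infl, 200 * 0.5^(1 / 3), tolerance = 1e-12)
  num <- numeric_growth_max(hp)
  expect_lt(abs(gf$t_infl - num$t_infl) / num$t_infl, 1e-3)
  expect_lt(abs(gf$v_max - num$v_max) / num$v_max, 1e-3)
  expect_lt(gf$t_infl, hp$t_half)
  expect_equal(gf$rgr_at_infl, gf$v_max / hill_eval(hp, gf$t_infl))
  # n <= 1: no interior inflection
  flat <- growth_features(hill_params(100, 200, 0.8))
  expect_false(flat$defined)

  # large-n limit approaches a step at t_half
  steep <- hill_params(100, 200, 400)
  expect_lt(hill_eval(steep, 0.9 * 200), 1e-9)
  expect_gt(hill_eval(steep, 1.1 * 200), 100 - 1e-9)
})

test_that("age shifting drops and logs pre-initiation rows", {
  d <- data.frame(individual_id = 1:3, plant_age_h = c(300, 100, 130),
                  length_um = c(500, 50, 80))
  s <- shift_to_leaf_age(d, 120, quiet = TRUE)
  expect_equal(s$leaf_age_h, c(180, 10))
  expect_equal(attr(s, "n_dropped"), 1L)
  s0 <- shift_to_leaf_age(d, 0, quiet = TRUE)
  expect_equal(s0$leaf_age_h, d$plant_age_h)
  expect_error(shift_to_leaf_age(d, 1000), "predate")
})

test_that("inverse-variance weights follow the binned variances", {
  sh <- data.frame(leaf_age_h = c(rep(10, 3), rep(40, 3), 70, 70),
                   length_um = c(10, 12, 14, 20, 20, 20, 5, 6))
  w <- estimate_time_variances(sh, bin_width_h = 24)
  expect_equal(w[1:3], rep(1 / 4, 3))             # var({10,12,14}) = 4
  expect_equal(w[4:6], rep(1e6, 3))               # zero variance capped
  expect_equal(attr(w, "n_fallback"), 1L)         # 2-obs bin pooled
  # uniform weights when variances are equal: weighted fit == unweighted
  hp <- hill_params(800, 120, 3)
  set.seed(3)
  ages <- runif(60, 5, 400)
  d <- data.frame(leaf_age_h = ages,
                  length_um = hill_eval(hp, ages) + rnorm(60, 0, 5))
  f_w <- fit_hill(d, weights = rep(2, 60))
  f_u <- fit_hill(d)
  expect_equal(unclass(f_w$params), unclass(f_u$params), tolerance = 1e-6)
})

test_that("the Hill fit recovers generating parameters", {
  hp <- hill_params(1200, 250, 3.5)
  set.seed(11)
  ages <- runif(200, 5, 900)
  noise_free <- data.frame(leaf_age_h = ages, length_um = hill_eval(hp, ages))
  f <- fit_hill(noise_free)
  expect_lt(abs(f$params$l_max - hp$l_max) / hp$l_max, 0.01)
  expect_lt(abs(f$params$t_half - hp$t_half) / hp$t_half, 0.01)
  expect_lt(abs(f$params$n - hp$n) / hp$n, 0.01)
  expect_true(f$plateau_seen)

  noisy <- data.frame(leaf_age_h = rep(ages, length.out = 500))
  noisy$length_um <- hill_eval(hp, noisy$leaf_age_h) *
    (1 + rnorm(500, 0, 0.1))
  fn <- fit_hill(noisy, estimate_time_variances(noisy))
  expect_lt(abs(fn$params$l_max - hp$l_max) / hp$l_max, 0.05)

  # truncation before the plateau flags a poorly identified asymptote
  trunc <- noise_free[noise_free$leaf_age_h < 150, ]
  if (nrow(trunc) >= 10) {
    ft <- fit_hill(trunc)
    expect_false(ft$plateau_seen)
  }
})

test_that("weighting helps under heteroscedastic noise", {
  # noise SD grows with the mean: inverse-variance weights should reduce
  # parameter error on average across seeded replicates
  hp <- hill_params(1000, 200, 3)
  err_w <- err_u <- matrix(NA_real_, nrow = 100, ncol = 3)
  for (r in 1:100) {
    set.seed(1000 + r)
    ages <- runif(80, 10, 700)
    d <- data.frame(leaf_age_h = ages)
    mu <- hill_eval(hp, ages)
    d$length_um <- abs(mu * (1 + rnorm(80, 0, 0.15)))
    w <- estimate_time_variances(d)
    fw <- tryCatch(fit_hill(d, w, n_starts = 3L), error = function(e) NULL)
    fu <- tryCatch(fit_hill(d, n_starts = 3L), error = function(e) NULL)
    if (is.null(fw) || is.null(fu)) next
    truth <- c(hp$l_max, hp$t_half, hp$n)
    err_w[r, ] <- (unlist(fw$params) - truth) / truth
    err_u[r, ] <- (unlist(fu$params) - truth) / truth
  }
  rmse <- function(e) sqrt(colMeans(e^2, na.rm = TRUE))
  # aggregate over the three parameters
  expect_lt(mean(rmse(err_w)), mean(rmse(err_u)))
})

test_that("model comparison ranks the generating sigmoid first", {
  set.seed(21)
  ages <- runif(150, 5, 800)
  hp <- hill_params(1000, 220, 2.2)
  from_hill <- data.frame(leaf_age_h = ages,
                          length_um = hill_eval(hp, ages) * (1 + rnorm(150, 0, 0.03)))
  cmp_h <- compare_sigmoid_models(from_hill)
  expect_equal(cmp_h$model[1], "hill")

  from_log <- data.frame(leaf_age_h = ages,
                         length_um = 1000 / (1 + exp(-0.03 * (ages - 250))) *
                           (1 + rnorm(150, 0, 0.03)))
  cmp_l <- compare_sigmoid_models(from_log)
  expect_equal(cmp_l$model[1], "logistic")

  flat <- data.frame(leaf_age_h = ages, length_um = rep(500, 150))
  expect_error(compare_sigmoid_models(flat), "constant")
})

test_that("organ and tooth dating compose ages correctly", {
  hp <- hill_params(900, 180, 3)
  d <- date_organs(hp, T_h = 120, lengths_um = c(450, 100, 800))
  expect_equal(d$age_since_init_h[1], 180)
  expect_equal(d$absolute_age_h[1], 300)
  # round-trip a batch of noise-free synthetic lengths
  ages <- c(30, 90, 250, 600)
  lens <- hill_eval(hp, ages)
  dd <- date_organs(hp, T_h = 50, lengths_um = lens)
  expect_equal(dd$age_since_init_h, ages, tolerance = 1e-6)
  # overlong lengths are collected, not fatal
  expect_warning(bad <- date_organs(hp, T_h = 0, lengths_um = c(450, 950)),
                 "could not be dated")
  expect_equal(attr(bad, "failed"), 2L)
  expect_true(is.na(bad$age_since_init_h[2]))
  # dating increases with length
  expect_true(all(diff(date_organs(hp, 0, c(100, 400, 800))$age_since_init_h) > 0))

  expect_equal(as.numeric(tooth_age(336, 236)), 100)
  expect_equal(as.numeric(tooth_age(100, 100)), 0)
  flagged <- tooth_age(100, 150)
  expect_true(is.na(flagged[1]))
  expect_equal(attr(flagged, "flagged"), 1L)
})
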