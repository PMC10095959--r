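test_that("category maps bin counts as specified", {
  obs <- data.frame(individual_id = 1:6, age_h = 10 * (1:6),
                    organ_count = c(0, 1, 2, 3, 5, 11))
  ident <- categorize(obs, category_map("identity"))
  expect_equal(ident$category, c(0, 1, 2, 3, 5, 11))
  expect_equal(attr(ident, "K"), 11L)

  odd <- categorize(obs, category_map("odd"))
  # counts 0-2 -> category 0; 3,4 -> 1; 5,6 -> 2; ...; 11 -> 5
  expect_equal(odd$category, c(0, 0, 0, 1, 2, 5))

  expect_error(categorize(obs[0, ]), "empty")
  bad_map <- category_map("custom", fun = function(x) ifelse(x > 3, NA, x))
  expect_error(categorize(obs, bad_map), "outside")
})

test_that("resampling balances categories to the largest one", {
  obs <- data.frame(individual_id = 1:13, age_h = seq(5, 125, by = 10),
                    organ_count = rep(c(0, 1, 2), times = c(5, 3, 5)))
  cat_obs <- categorize(obs)
  bal <- resample_categories(cat_obs, seed = 1)
  expect_equal(bal$N, 5L)
  sizes <- table(bal$observations$category)
  expect_true(all(sizes == 5))
  # upsampled rows reuse existing ages only
  expect_true(all(bal$observations$age_h[bal$observations$category == 1] %in%
                    obs$age_h[obs$organ_count == 1]))
  # reproducible under seed; already-balanced input passes through
  bal2 <- resample_categories(cat_obs, seed = 1)
  expect_identical(bal$observations, bal2$observations)
  even <- categorize(data.frame(individual_id = 1:4, age_h = 1:4,
                                organ_count = c(0, 0, 1, 1)))
  bal3 <- resample_categories(even, seed = 1)
  expect_equal(nrow(bal3$observations), 4L)

  gap <- categorize(data.frame(individual_id = 1:2, age_h = 1:2,
                               organ_count = c(0, 2)))
  expect_error(resample_categories(gap), "categor")
})

test_that("empirical dynamics match the hand-enumerated example and conserve N", {
  # K = 1, N = 2: category-0 observations at 10, 20; category-1 at 15, 25
  obs <- data.frame(individual_id = 1:4, age_h = c(10, 20, 15, 25),
                    organ_count = c(0, 0, 1, 1))
  bal <- resample_categories(categorize(obs), seed = 1)
  emp <- empirical_dynamics(bal)
  expect_equal(emp$times, c(10, 15, 20, 25))
  # N_0: 2 on [0,10), 1 on [10,20), 0 from 20; right-continuous at events
  expect_equal(emp$occupancy[, 1], c(1, 1, 0, 0))
  expect_equal(emp$occupancy[, 2], c(1, 1, 2, 2))
  expect_true(all(rowSums(emp$occupancy) == emp$N))

  # K = 0 degenerate: N_0 steps from N down to 0
  only0 <- list(observations = data.frame(individual_id = 1:3,
                                          age_h = c(1, 2, 3),
                                          category = 0L),
                N = 3L, K = 0L)
  emp0 <- empirical_dynamics(only0)
  expect_equal(emp0$occupancy[, 1], c(2, 1, 0))
})

test_that("empirical reconstruction equals the literal backward counter", {
  set.seed(42)
  for (rep in 1:25) {
    K <- sample(1:4, 1)
    n_per <- sample(3:8, 1)
    obs <- data.frame(
      age_h = sample(1:30, (K + 1) * n_per, replace = TRUE),  # forces ties
      category = rep(0:K, each = n_per))
    bal <- list(observations = obs, N = n_per, K = K)
    emp <- suppressWarnings(empirical_dynamics(bal))
    oracle <- backward_count_oracle(obs, n_per, K)
    expect_equal(emp$occupancy, oracle)
  }
})

test_that("the logistic hazard has the stated limits and monotonicity", {
  p <- list(a = 100, b = 0.2, c = 0.5)
  expect_equal(transition_hazard(p, 100), 0.25)
  expect_lt(transition_hazard(p, -1e5), 1e-12)
  expect_equal(transition_hazard(p, 1e5), 0.5)
  tgrid <- seq(0, 300, by = 1)
  expect_true(all(diff(transition_hazard(p, tgrid)) >= 0))
  # near-step limit
  steep <- list(a = 100, b = 50, c = 0.5)
  expect_lt(transition_hazard(steep, 99), 1e-9)
  expect_equal(transition_hazard(steep, 101), 0.5, tolerance = 1e-9)
})

test_that("the population model conserves N and solves known special cases", {
  # no transitions: everyone stays in category 0
  still <- simulate_population_model(
    data.frame(k = 1:2, a = c(50, 100), b = c(0.1, 0.1), c = c(1e-12, 1e-12)),
    N = 50, K = 2, t_span = c(0, 200))
  expect_true(all(abs(still$occupancy[, 1] - 50) < 1e-6))

  # K = 1 with b = 0: constant hazard c/2, exponential decay
  sol <- simulate_population_model(data.frame(k = 1, a = 50, b = 0, c = 0.1),
                                   N = 100, K = 1, t_span = c(0, 100))
  expect_equal(sol$occupancy[, 1], 100 * exp(-0.05 * sol$times),
               tolerance = 1e-6)

  # ordered occupancy waves for spaced inflection points
  waves <- simulate_population_model(
    data.frame(k = 1:3, a = c(50, 120, 210), b = 0.3, c = 0.4),
    N = 100, K = 3, t_span = c(0, 400),
    grid = seq(0, 400, by = 0.5))
  peaks <- apply(waves$occupancy[, 2:3], 2, function(col)
    waves$times[which.max(col)])
  expect_true(all(diff(c(waves$times[which.min(abs(waves$occupancy[, 1] - 50))],
                         peaks)) > 0))
  expect_true(all(abs(rowSums(waves$occupancy) - 100) <= 1e-6 * 100))
  expect_true(all(waves$occupancy > -1e-6))
})
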