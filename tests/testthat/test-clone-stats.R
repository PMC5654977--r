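test_that("neutral clone-size law matches the closed form and decays in n", {
  # at r*lambda*t = e the log term is 1, so P_1 = exp(-1/e)
  expect_equal(neutral_pmf(1, r_lambda = 1, t = exp(1)), exp(-1 / exp(1)))
  # frozen high-precision evaluation (mpmath, 50 digits) at n = 100, a = 100
  expect_equal(neutral_pmf(100, r_lambda = 0.5, t = 200),
               0.0007988400565320468, tolerance = 1e-12)
  p <- neutral_pmf(1:500, r_lambda = 0.5, t = 100)
  expect_true(all(diff(p) < 0))
  expect_error(neutral_pmf(5, r_lambda = 0.5, t = 1), "exceed 1")
  expect_error(neutral_pmf(0, r_lambda = 0.5, t = 100), ">= 1")
})

test_that("cumulative tail equals the brute-force sum and is monotone", {
  brute <- sum(neutral_pmf(1:50, r_lambda = 1, t = 10))
  expect_equal(cumulative_tail(1, 50, r_lambda = 1, t = 10), brute,
               tolerance = 1e-12)
  expect_equal(cumulative_tail(51, 50, r_lambda = 1, t = 10), 0)

  s_grid <- c(1, 10, 100, 1000)
  tails <- sapply(s_grid, cumulative_tail, N = 5000, r_lambda = 0.5, t = 100)
  expect_true(all(diff(tails) < 0))
  t_grid <- c(50, 80, 120) * 365.25 / 7
  tails_t <- sapply(t_grid, function(t)
    cumulative_tail(1000, 5000, r_lambda = 0.5, t = t))
  expect_true(all(diff(tails_t) > 0))
})

test_that("saturation time follows N(ln N + 1/(2r))/lambda and grows with N", {
  expect_equal(klein_saturation_time(1, lam = 0.5), 2)  # ln 1 = 0
  N <- c(10, 100, 1e4, 64000)
  T_w <- klein_saturation_time(N, lam = 0.5)
  expect_equal(T_w, N * (log(N) + 1) / 0.5)
  expect_true(all(diff(T_w) > 0))
  expect_equal(weeks_to_years(365.25 / 7), 1)
})

test_that("empirical incomplete moment is normalised, monotone, and matches analytics", {
  # identical sizes: the whole mass sits at one point
  m <- first_incomplete_moment(rep(7, 20))
  expect_equal(m$moment, 1)
  expect_equal(m$n, 7)

  set.seed(1)
  x <- stats::rexp(2e5, rate = 1 / 100)
  cur <- first_incomplete_moment(x)
  expect_equal(cur$moment[1], 1)
  expect_true(all(diff(cur$moment) <= 0))
  # analytic tail moment of an exponential: (1 + n/m) exp(-n/m)
  grid <- c(50, 100, 200, 400)
  emp <- stats::approx(cur$n, cur$moment, grid)$y
  expect_equal(emp, (1 + grid / 100) * exp(-grid / 100), tolerance = 0.03)
  expect_error(first_incomplete_moment(numeric(0)), "empty")
})

test_that("incomplete-moment fit recovers the neutral decay constant", {
  # the neutral law P_n ~ exp(-n/a)/n has an exactly exponential
  # incomplete moment (geometric sum), so the decay is identifiable
  s <- sample_clone_sizes("neutral", list(r_lambda_t = 500),
                          n_clones = 5000, seed = 42)
  fit <- fit_incomplete_moment(s$size)
  expect_lt(abs(fit$r_lambda_t - 500) / 500, 0.05)
  expect_gt(fit$r_squared, 0.98)

  # a small uniform shift perturbs the decay only mildly
  fit_c <- fit_incomplete_moment(s$size + 25)
  expect_lt(abs(fit_c$r_lambda_t - fit$r_lambda_t) / fit$r_lambda_t, 0.05)

  # detection truncation (what n0 corrects for): censoring below a threshold
  # leaves the decay intact and moves n0 to about the threshold
  big <- sample_clone_sizes("neutral", list(r_lambda_t = 500),
                            n_clones = 20000, seed = 7)
  ft <- fit_incomplete_moment(big$size[big$size >= 500])
  expect_lt(abs(ft$r_lambda_t - 500) / 500, 0.1)
  expect_lt(abs(ft$n0 - 500), 50)

  expect_error(fit_incomplete_moment(c(10, 20)), "at least 10")
  expect_error(fit_incomplete_moment(rep(5, 50)), "degenerate")

  td <- tidy(fit)
  expect_equal(td$term, c("r_lambda_t", "n0"))
  expect_equal(glance(fit)$n_clones, 5000)
})

test_that("boundary-nucleation density matches its chain-rule construction", {
  sigma <- 1; R <- 100
  A <- 10^seq(0, 5, length.out = 30)
  # independent route: M = N(t) * dt/dr * dr/dA with r(A) and alpha = 1
  r_of_A <- sqrt((A / sigma)^2 + R^2) - A / sigma
  dr_dA <- A / (sigma^2 * sqrt((A / sigma)^2 + R^2)) - 1 / sigma
  M_chain <- abs((2 * pi * r_of_A / sigma) * 1 * dr_dA)
  expect_equal(boundary_M(A, sigma, R), M_chain, tolerance = 1e-12)
  expect_error(boundary_M(-1, sigma, R), "positive")
})

test_that("boundary density approaches the inverse-cubic asymptote", {
  sigma <- 2; R <- 50; gam <- 3; alp <- 0.5
  ratio <- function(A) boundary_M(A, sigma, R, gam, alp) /
    ((2 * pi * gam / alp) * sigma * R^4 / (4 * A^3))
  expect_lt(abs(ratio(10 * sigma * R) - 1), 0.01)
  expect_lt(abs(ratio(100 * sigma * R) - 1), 1e-4)
  expect_true(abs(ratio(100 * sigma * R) - 1) < abs(ratio(10 * sigma * R) - 1))
})

test_that("boundary exponent matches the numerical log-log derivative", {
  sigma <- 1; R <- 100
  h <- 1e-6
  for (A in c(0.1, 1, 10, 100, 1e4) * sigma * R) {
    num <- (log(boundary_M(A * exp(h), sigma, R)) -
              log(boundary_M(A * exp(-h), sigma, R))) / (2 * h)
    expect_lt(abs(boundary_beta(A, sigma, R) - num) / abs(num), 1e-6)
  }
  expect_equal(boundary_beta(1 * 100, 1, 100), -(1 + 2 * sqrt(2)) / 2,
               tolerance = 1e-12)
  expect_lt(abs(boundary_beta(1e-6, 1, 100)), 1e-6)
  expect_lt(abs(boundary_beta(1e8, 1, 100) - (-3)), 1e-3)
})

test_that("exponential-growth density is an exact inverse square law", {
  b <- 0.8; T_obs <- 10; sigma <- 1
  a <- pi / 4
  A1 <- a * 10; A2 <- a * 1000
  slope <- (log(exponential_M(A2, b, T_obs)) - log(exponential_M(A1, b, T_obs))) /
    (log(A2) - log(A1))
  expect_equal(slope, -2)
  expect_equal(exponential_M(2 * A1, b, T_obs) / exponential_M(A1, b, T_obs), 0.25)
  # nucleation-time inversion round-trips through the forward map
  t <- exponential_nucleation_time(A1, b, T_obs, sigma)
  expect_equal(pi * (sigma / 2)^2 * exp(b * (T_obs - t)), A1, tolerance = 1e-12)
  expect_error(exponential_M(a / 2, b, T_obs), "support")
})

test_that("power-law fitting recovers known exponents from sampled sizes", {
  s3 <- sample_clone_sizes("custom_powerlaw",
                           list(exponent = -3, xmin = 1, xmax = 1e4),
                           n_clones = 1e5, seed = 8)
  f3 <- fit_power_law(s3$size, fit_range = c(1, 1e4))
  expect_lt(abs(f3$exponent - (-3)), 0.1)
  expect_lt(f3$rss_slope3, f3$rss_slope2)

  s2 <- sample_clone_sizes("custom_powerlaw",
                           list(exponent = -2, xmin = 1, xmax = 1e4),
                           n_clones = 1e5, seed = 9)
  f2 <- fit_power_law(s2$size, fit_range = c(1, 1e4))
  expect_lt(abs(f2$exponent - (-2)), 0.1)
  expect_lt(f2$rss_slope2, f2$rss_slope3)

  expect_error(fit_power_law(rep(5, 100)), "equal")
  expect_error(fit_power_law(stats::runif(10)), "at least 20")
})

test_that("VAF converts to cell counts under the heterozygous diploid convention", {
  res <- vaf_to_cells(0.2, area_mm2 = 16, linear_density = 100)
  expect_equal(res$cells, 64000)
  expect_equal(res$area_mm2, 6.4)
  expect_equal(vaf_to_cells(0.5, 16)$cell_fraction, 1)
  expect_equal(vaf_to_cells(0.05, 16)$area_mm2, 16 * 0.1)  # 10% of the biopsy
  expect_error(vaf_to_cells(0.6, 16), "bound")
  expect_error(vaf_to_cells(0, 16), "positive")
})
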