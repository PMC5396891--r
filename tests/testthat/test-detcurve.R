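test_that("noiseless curves are recovered exactly and pass through the origin", {
  S <- seq(10, 350, by = 20)
  d <- data.frame(season_length = S, p_star = 0.8 * (1 - exp(-0.02 * S)))
  fit <- fit_detcurve(p_star ~ season_length, d)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["A"]] - 0.8), 1e-6)
  expect_lt(abs(coef(fit)[["R"]] - 0.02), 1e-6)
  expect_equal(predict(fit, 0), 0)  # A(1 - e^0) = 0 by construction
  expect_lt(fit$rss, 1e-10)
})

test_that("the optimiser agrees with a dense grid search on noisy data", {
  set.seed(501)
  S <- seq(10, 350, by = 20)
  y <- 0.6 * (1 - exp(-0.015 * S)) + rnorm(length(S), 0, 0.03)
  y <- pmin(pmax(y, 0), 1)
  fit <- fit_detcurve(p_star ~ season_length,
                      data.frame(season_length = S, p_star = y))
  A_grid <- seq(0, 1, by = 0.002)
  R_grid <- seq(5e-4, 0.06, by = 2.5e-4)
  rss <- outer(A_grid, R_grid, function(a, r) {
    vapply(seq_along(a), function(i) {
      sum((y - a[i] * (1 - exp(-r[i] * S)))^2)
    }, 0)
  })
  best <- arrayInd(which.min(rss), dim(rss))
  expect_lt(abs(coef(fit)[["A"]] - A_grid[best[1]]), 0.002 + 1e-9)
  expect_lt(abs(coef(fit)[["R"]] - R_grid[best[2]]), 2.5e-4 + 1e-9)
  expect_lte(fit$rss, min(rss) + 1e-9)
})

test_that("curve inversion solves the design question and round-trips", {
  S <- seq(10, 350, by = 20)
  d <- data.frame(season_length = S, p_star = 1.0 * (1 - exp(-0.01 * S)))
  fit1 <- fit_detcurve(p_star ~ season_length, d)
  expect_lt(abs(invert_detcurve(fit1, 0.5) - log(2) / coef(fit1)[["R"]]), 1e-6)

  d8 <- data.frame(season_length = S, p_star = 0.8 * (1 - exp(-0.02 * S)))
  fit8 <- fit_detcurve(p_star ~ season_length, d8)
  s40 <- invert_detcurve(fit8, 0.4)
  expect_lt(abs(s40 - (-log(0.5) / 0.02)), 1e-4)
  # round trip to 1e-9
  expect_lt(abs(predict(fit8, s40) - 0.4), 1e-9)

  unreach <- invert_detcurve(fit8, 0.9)  # above the asymptote
  expect_true(is.na(unreach))
  expect_true(attr(unreach, "unreachable"))
  expect_error(invert_detcurve(fit8, 1.2), "inside")
})

test_that("degenerate data signal non-convergence instead of silent defaults", {
  S <- seq(10, 100, by = 10)
  flat <- data.frame(season_length = S, p_star = rep(0, length(S)))
  expect_warning(fit0 <- fit_detcurve(p_star ~ season_length, flat),
                 "not converge")
  expect_false(fit0$converged)
  expect_true(all(is.na(coef(fit0))))
  expect_error(predict(fit0, 10), "unconverged")
  expect_error(invert_detcurve(fit0, 0.4), "unconverged")

  expect_error(fit_detcurve(p_star ~ season_length,
                            data.frame(season_length = c(1, 1, 2),
                                       p_star = c(0.1, 0.1, 0.2))),
               "3 distinct")
})

test_that("fitted curves are non-decreasing and bounded by the asymptote", {
  set.seed(502)
  for (rep in 1:5) {
    A <- runif(1, 0.3, 1)
    R <- runif(1, 0.005, 0.05)
    S <- sort(sample(5:365, 25))
    y <- pmin(pmax(A * (1 - exp(-R * S)) + rnorm(25, 0, 0.04), 0), 1)
    fit <- fit_detcurve(p_star ~ season_length,
                        data.frame(season_length = S, p_star = y))
    if (!fit$converged) next
    grid <- predict(fit, seq(0, 400, by = 5))
    expect_true(all(diff(grid) >= -1e-12))
    expect_true(all(grid <= coef(fit)[["A"]] + 1e-12))
    ci <- confint(fit)
    expect_true(all(ci[, "lower"] <= ci[, "upper"]))
  }
})

test_that("model methods behave like a standard fitted-model object", {
  set.seed(503)
  S <- seq(10, 350, by = 20)
  y <- pmin(pmax(0.7 * (1 - exp(-0.018 * S)) + rnorm(length(S), 0, 0.03), 0), 1)
  d <- data.frame(season_length = S, p_star = y)
  fit <- fit_detcurve(p_star ~ season_length, d)

  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(fitted(fit) + residuals(fit), y, ignore_attr = TRUE)
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  expect_output(print(fit), "asymptote")
  expect_output(print(summary(fit)), "Std. Error")

  pr <- predict(fit, data.frame(season_length = c(30, 60)), se.fit = TRUE)
  expect_true(all(pr$se.fit >= 0))

  # binned fit averages within season length first
  d2 <- rbind(d, d)
  fb <- fit_detcurve(p_star ~ season_length, d2, bin = TRUE)
  expect_equal(fb$n_points, length(unique(S)))
  expect_equal(coef(fb), coef(fit), tolerance = 1e-6)
})
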