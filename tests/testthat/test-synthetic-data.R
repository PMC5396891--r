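test_that("deployment generator reproduces the clustered field geometry", {
  dep <- generate_deployment(4, 2, 5, seed = 1)
  expect_equal(nrow(dep), 40)
  expect_equal(unname(table(dep$site_id)), rep(10L, 4), ignore_attr = TRUE)

  sp <- spacing_config()
  for (cl in unique(dep$cluster_id)) {
    sub <- dep[dep$cluster_id == cl, ]
    d <- mean(dist(cbind(sub$x_m, sub$y_m)))
    expect_gte(d, sp$intra_mean_m - sp$intra_tol_m)
    expect_lte(d, sp$intra_mean_m + sp$intra_tol_m)
  }
  # centroids of the two clusters in a site sit near the configured
  # inter-cluster distance (random camera scatter moves each centroid by
  # ~sd 13 m per axis)
  for (s in unique(dep$site_id)) {
    sub <- dep[dep$site_id == s, ]
    cents <- do.call(rbind, lapply(split(sub, sub$cluster_id), function(g) {
      c(mean(g$x_m), mean(g$y_m))
    }))
    expect_lt(abs(dist(cents)[1] - sp$inter_cluster_m), 80)
  }
})

test_that("degenerate and small deployments satisfy the distance band", {
  one <- generate_deployment(1, 1, 1, seed = 7)
  expect_equal(nrow(one), 1L)

  dep <- generate_deployment(2, 2, 5, seed = 3)
  expect_equal(nrow(dep), 20L)
  sp <- spacing_config()
  for (cl in unique(dep$cluster_id)) {
    sub <- dep[dep$cluster_id == cl, ]
    # brute-force pairwise distances
    dd <- c()
    for (i in 1:4) for (j in (i + 1):5) {
      dd <- c(dd, sqrt((sub$x_m[i] - sub$x_m[j])^2 + (sub$y_m[i] - sub$y_m[j])^2))
    }
    expect_gte(mean(dd), sp$intra_mean_m - sp$intra_tol_m)
    expect_lte(mean(dd), sp$intra_mean_m + sp$intra_tol_m)
  }

  expect_error(generate_deployment(0, 2, 5), "positive")
  expect_error(generate_deployment(2, 2, 5, spacing = list(inter_cluster_m = -5)),
               "positive")
})

test_that("deployment generation is deterministic under a fixed seed", {
  a <- generate_deployment(2, 2, 3, seed = 11)
  b <- generate_deployment(2, 2, 3, seed = 11)
  c <- generate_deployment(2, 2, 3, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("event counts follow the configured rate and zero rate gives no events", {
  dep <- mk_deployment(1, 1)
  dep <- dep[1, ]

  zero <- simulate_events(dep, species_model("none", 0), n_days = 50, seed = 1)
  expect_equal(nrow(zero), 0L)

  # analytic moment check: Poisson(2/day) over 365 days -> mean 730, var 730
  sm <- species_model("sp", daily_event_rate = 2)
  ev <- simulate_events(dep, sm, start_date = test_origin, n_days = 365,
                        seed = 42)
  expect_lt(abs(nrow(ev) - 730), 3 * sqrt(730))

  # all timestamps inside [start, start + n_days)
  mins <- as.numeric(difftime(ev$timestamp,
                              as.POSIXct(paste(test_origin, "00:00:00"), tz = "UTC"),
                              units = "mins"))
  expect_true(all(mins >= 0 & mins < 365 * 1440))
})

test_that("event stream is byte-identical under a fixed seed", {
  dep <- mk_deployment(2, 3)
  sms <- default_species_models()
  a <- simulate_events(dep, sms, n_days = 20, seed = 5)
  b <- simulate_events(dep, sms, n_days = 20, seed = 5)
  expect_identical(a, b)
})

test_that("doubling the event rate approximately doubles the event count", {
  dep <- mk_deployment(1, 5)
  n1 <- nrow(simulate_events(dep, species_model("a", 0.5), n_days = 365, seed = 9))
  n2 <- nrow(simulate_events(dep, species_model("a", 1.0), n_days = 365, seed = 9))
  # totals ~ Poisson(912.5) and Poisson(1825); ratio within 3 SE bands
  expect_lt(abs(n1 - 912.5), 3 * sqrt(912.5))
  expect_lt(abs(n2 - 1825), 3 * sqrt(1825))
  expect_lt(abs(n2 / n1 - 2), 0.3)
})

test_that("companion events always land within the deduplication window", {
  dep <- mk_deployment(1, 2)  # two co-located cameras in one cluster
  sm <- species_model("sp", daily_event_rate = 0.5,
                      within_day_cluster_prob = 1)
  ev <- simulate_events(dep, sm, start_date = test_origin, n_days = 30,
                        seed = 3)
  expect_gt(nrow(ev), 10)
  mins <- as.numeric(difftime(ev$timestamp,
                              as.POSIXct(paste(test_origin, "00:00:00"), tz = "UTC"),
                              units = "mins"))
  end <- 30 * 1440
  # exhaustive scan: every event has another event strictly within 30
  # minutes (companions follow primaries; only events so close to the end
  # of the simulation that their companion would fall outside are exempt)
  for (i in seq_along(mins)) {
    gaps <- abs(mins[-i] - mins[i])
    if (mins[i] < end - 29) expect_lt(min(gaps), 30)
  }
})
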