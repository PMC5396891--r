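test_that("collapsed design ranges force the drawn design", {
  dep <- mk_deployment(2, 10)
  des <- design_config(m_range = c(3, 3), season_length_range = c(90, 90),
                       replicate_length_range = c(10, 10))
  set.seed(1)
  for (i in 1:10) {
    d <- draw_design(des, dep)
    expect_equal(d$m, 3L)
    expect_equal(d$season_length, 90L)
    expect_equal(d$replicate_length, 10L)
    expect_equal(d$n_replicates, 9L)
    expect_true(all(lengths(d$selected_cameras) == 3L))
  }

  # m = 10 at a 10-camera site selects the whole site
  des10 <- design_config(m_range = c(10, 10))
  set.seed(2)
  d10 <- draw_design(des10, dep)
  expect_setequal(d10$selected_cameras$s1, dep$camera_id[dep$site_id == "s1"])
})

test_that("replicate lengths exceeding the season are rejected and redrawn", {
  dep <- mk_deployment(1, 2)
  des <- design_config(m_range = c(1, 1), season_length_range = c(5, 5),
                       replicate_length_range = c(1, 28))
  set.seed(3)
  for (i in 1:50) {
    d <- draw_design(des, dep)
    expect_lte(d$replicate_length, d$season_length)
    expect_gte(d$n_replicates, 1L)
  }
  # no admissible length at all
  des_bad <- design_config(m_range = c(1, 1), season_length_range = c(5, 5),
                           replicate_length_range = c(10, 28))
  expect_error(draw_design(des_bad, dep), "replicate length")
})

test_that("array sizes are drawn uniformly", {
  dep <- mk_deployment(1, 10)
  des <- design_config(m_range = c(1, 10))
  set.seed(4)
  ms <- integer(10000)
  for (i in seq_along(ms)) ms[i] <- draw_design(des, dep)$m
  counts <- tabulate(ms, 10)
  # multinomial oracle: each cell Binomial(10000, 0.1), sd = 30
  expect_true(all(abs(counts - 1000) <= 3 * sqrt(10000 * 0.1 * 0.9)))
})

test_that("replicate windows wrap around the year boundary", {
  map <- camarray:::replicate_day_map(360, 10, 5)
  expect_equal(which(map == 1L), 360:364)
  expect_equal(sort(which(map == 2L)), c(1:4, 365))
  # trailing S - kL days are discarded
  map2 <- camarray:::replicate_day_map(1, 10, 3)
  expect_equal(sum(map2 > 0), 9)
  expect_equal(unname(table(map2[map2 > 0])), rep(3L, 3), ignore_attr = TRUE)
})

test_that("replicate matrix extraction matches the exhaustive enumeration oracle", {
  dep <- mk_deployment(2, 3)
  set.seed(405)
  for (rep in 1:40) {
    n <- sample(10:60, 1)
    ev <- mk_events(sort(round(runif(n, 0, 365 * 1440 - 1))),
                    camera_id = sample(dep$camera_id, n, replace = TRUE),
                    site_id = NA, species_id = "x")
    ev$site_id <- dep$site_id[match(ev$camera_id, dep$camera_id)]
    sel <- lapply(split(dep$camera_id, dep$site_id),
                  function(cs) sort(sample(cs, 2)))
    S <- sample(6:80, 1)
    L <- sample(1:min(28, S), 1)
    draw <- mk_draw(sel, season_start = sample(1:365, 1),
                    season_length = S, replicate_length = L)
    mine <- extract_replicate_matrix(ev, draw, "x", year_start = test_origin)
    oracle <- bf_replicate_matrix(ev, draw, "x")
    expect_equal(unname(unclass(mine))[, ], unname(oracle)[, ],
                 ignore_attr = TRUE)
    expect_equal(dim(mine), c(2L, S %/% L))
  }
})

test_that("zero events give an all-zero matrix and unknown species error", {
  dep <- mk_deployment(1, 2)
  sel <- list(s1 = dep$camera_id)
  draw <- mk_draw(sel, 10, 20, 5)
  empty <- mk_events(numeric(0), character(0))
  mat <- extract_replicate_matrix(empty, draw, "x", year_start = test_origin)
  expect_true(all(mat == 0))
  ev <- mk_events(100, dep$camera_id[1], species_id = "x")
  expect_error(extract_replicate_matrix(ev, draw, "nope", year_start = test_origin),
               "unknown species")
})

test_that("Monte Carlo runs are reproducible and correctly shaped", {
  dep <- mk_deployment(2, 3)
  ev <- simulate_events(dep, list(species_model("common", 0.6),
                                  species_model("rare", 0.05,
                                                camera_heterogeneity_sd = 1)),
                        start_date = test_origin, n_days = 365, seed = 10)
  des <- design_config(m_range = c(1, 3))
  one <- run_monte_carlo(ev, dep, des, n_iterations = 1, master_seed = 5,
                         year_start = test_origin)
  expect_equal(nrow(one), 2L)  # one row per species

  a <- run_monte_carlo(ev, dep, des, n_iterations = 30, master_seed = 6,
                       year_start = test_origin)
  b <- run_monte_carlo(ev, dep, des, n_iterations = 30, master_seed = 6,
                       year_start = test_origin)
  expect_identical(a, b)
  expect_equal(nrow(a), 60L)
  expect_true(all(a$n_replicates == a$season_length %/% a$replicate_length))
  expect_true(all(a$p >= 0 & a$p <= 1))
  expect_true(all(a$p_star >= 0 & a$p_star <= 1))
})

test_that("adding a camera never removes a replicate detection when visits are separated", {
  # with all same-site events >= 30 min apart, deduplication cannot merge
  # across cameras, so detection data grow monotonically with the array
  dep <- mk_deployment(2, 4)
  set.seed(406)
  rows <- list()
  for (s in c("s1", "s2")) {
    cams <- dep$camera_id[dep$site_id == s]
    mins <- sort(sample(seq(0, 365 * 1440 - 1, by = 45), 120))
    rows[[s]] <- mk_events(mins, sample(cams, 120, replace = TRUE),
                           site_id = s, species_id = "x")
  }
  ev <- do.call(rbind, rows)
  sel_small <- lapply(split(dep$camera_id, dep$site_id), function(cs) cs[1:2])
  sel_big <- lapply(split(dep$camera_id, dep$site_id), function(cs) cs[1:3])
  for (i in 1:10) {
    S <- sample(20:100, 1)
    L <- sample(1:14, 1)
    st <- sample(1:365, 1)
    m_small <- extract_replicate_matrix(ev, mk_draw(sel_small, st, S, L), "x",
                                        year_start = test_origin)
    m_big <- extract_replicate_matrix(ev, mk_draw(sel_big, st, S, L), "x",
                                      year_start = test_origin)
    expect_true(all(m_big >= m_small))
  }
})
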