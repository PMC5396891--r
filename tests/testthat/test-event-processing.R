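test_that("observations within the window across cameras merge into one detection", {
  ev <- mk_events(c(100, 110), c("A", "B"), species_id = "raccoon")
  det <- deduplicate_events(ev)
  expect_equal(nrow(det), 1L)
  expect_equal(det$contributing_cameras, "A;B")
  expect_equal(det$n_events, 2L)

  single <- deduplicate_events(mk_events(50, "A"))
  expect_equal(nrow(single), 1L)
  expect_identical(single$timestamp_first, single$timestamp_last)
})

test_that("chaining is sliding-window: gaps are measured from the latest event", {
  # 0, 25, 50: each consecutive gap is 25 < 30, so one chain even though
  # the first and last events are 50 minutes apart
  ev <- mk_events(c(0, 25, 50), c("A", "A", "A"))
  expect_equal(nrow(deduplicate_events(ev)), 1L)
  # a 30-minute gap starts a new chain (the half hour must have passed)
  ev2 <- mk_events(c(0, 30), c("A", "A"))
  expect_equal(nrow(deduplicate_events(ev2)), 2L)
})

test_that("deduplication matches the brute-force chaining oracle on random inputs", {
  set.seed(401)
  for (rep in 1:150) {
    n <- sample(1:12, 1)
    ev <- mk_events(sort(round(runif(n, 0, 1500))),
                    camera_id = sample(c("A", "B", "C"), n, replace = TRUE),
                    site_id = sample(c("s1", "s2"), n, replace = TRUE),
                    species_id = sample(c("x", "y"), n, replace = TRUE))
    subset <- if (rep %% 3 == 0) c("A", "B") else NULL
    mine <- deduplicate_events(ev, camera_subset = subset)
    oracle <- bf_dedup(ev, camera_subset = subset)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine)) {
      origin <- as.POSIXct(paste(test_origin, "00:00:00"), tz = "UTC")
      expect_equal(as.numeric(difftime(mine$timestamp_first, origin, units = "mins")),
                   oracle$first)
      expect_equal(as.numeric(difftime(mine$timestamp_last, origin, units = "mins")),
                   oracle$last)
      expect_equal(mine$contributing_cameras, oracle$cams)
    }
  }
})

test_that("consecutive detections within a site and species are separated by the window", {
  set.seed(402)
  ev <- mk_events(sort(round(runif(300, 0, 20000))),
                  camera_id = sample(c("A", "B"), 300, replace = TRUE))
  det <- deduplicate_events(ev)
  if (nrow(det) > 1) {
    gaps <- as.numeric(diff(det$timestamp_first)) # minutes... use first vs last
    gap2 <- as.numeric(difftime(det$timestamp_first[-1],
                                det$timestamp_last[-nrow(det)], units = "mins"))
    expect_true(all(gap2 >= 30))
  }
  expect_lte(nrow(det), nrow(ev))
})

test_that("a vanishing window leaves every distinct event its own detection", {
  set.seed(403)
  ev <- mk_events(sample(0:5000, 80), sample(c("A", "B"), 80, replace = TRUE))
  det <- deduplicate_events(ev, window_minutes = 1e-6)
  n_distinct <- nrow(unique(ev[c("site_id", "species_id", "timestamp")]))
  expect_equal(nrow(det), n_distinct)
})

test_that("subset detections always lie within a full-site detection span", {
  # adding cameras can merge detections but never lose one: every
  # detection derived from a camera subset is contained in the time span
  # of exactly one full-site detection
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    ev <- mk_events(sort(round(runif(n, 0, 4000))),
                    camera_id = sample(c("A", "B", "C"), n, replace = TRUE))
    full <- deduplicate_events(ev)
    sub <- deduplicate_events(ev, camera_subset = c("A", "B"))
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        containing <- sum(full$timestamp_first <= sub$timestamp_first[i] &
                            full$timestamp_last >= sub$timestamp_last[i])
        expect_equal(containing, 1L)
      }
    }
  }
})

test_that("events referencing unknown cameras are rejected", {
  dep <- mk_deployment(1, 2)
  ev <- mk_events(10, "ghost")
  expect_error(deduplicate_events(ev, deployment = dep), "not present")
  ev2 <- mk_events(10, dep$camera_id[1], site_id = "wrong_site")
  expect_error(deduplicate_events(ev2, deployment = dep), "wrong site")
})

test_that("first-camera attribution filters detections by their earliest camera", {
  # A at t=0, B at t=10: one site-level detection started by camera A
  ev <- mk_events(c(0, 10), c("A", "B"))
  resample_b <- deduplicate_events(ev, camera_subset = "B")
  first_b <- deduplicate_events(ev, camera_subset = "B",
                                attribution = "first_camera")
  expect_equal(nrow(resample_b), 1L)  # B would still have seen the animal
  expect_equal(nrow(first_b), 0L)     # but the merged detection belongs to A
})

test_that("daily history marks exactly the detection-start cells", {
  dep <- mk_deployment(1, 2)
  empty <- build_daily_history(
    deduplicate_events(mk_events(numeric(0), character(0))), dep,
    year_start = test_origin)
  expect_equal(sum(empty$detected), 0L)

  det <- deduplicate_events(mk_events(16 * 1440 + 60, dep$camera_id[1]))
  h <- build_daily_history(det, dep, year_start = test_origin)
  expect_equal(sum(h$detected), 1L)
  hit <- h[h$detected == 1, ]
  expect_equal(hit$day, 17L)
  expect_equal(hit$camera_id, dep$camera_id[1])

  out_of_year <- deduplicate_events(mk_events(400 * 1440, dep$camera_id[1]))
  expect_error(build_daily_history(out_of_year, dep, year_start = test_origin),
               "outside")
})

test_that("daily history equals a brute-force per-day recount", {
  dep <- mk_deployment(2, 2)
  set.seed(405)
  n <- 100
  ev <- mk_events(round(runif(n, 0, 364 * 1440)),
                  camera_id = sample(dep$camera_id, n, replace = TRUE),
                  site_id = NA, species_id = sample(c("x", "y"), n, TRUE))
  ev$site_id <- dep$site_id[match(ev$camera_id, dep$camera_id)]
  det <- deduplicate_events(ev)
  h <- build_daily_history(det, dep, year_start = test_origin)

  # brute force: for every (camera, species, day), scan all detections
  origin <- as.POSIXct(paste(test_origin, "00:00:00"), tz = "UTC")
  day <- floor(as.numeric(difftime(det$timestamp_first, origin, units = "days"))) + 1
  cams <- strsplit(det$contributing_cameras, ";")
  for (cell in which(h$detected == 1L)) {
    found <- FALSE
    for (i in seq_len(nrow(det))) {
      if (det$species_id[i] == h$species_id[cell] && day[i] == h$day[cell] &&
          h$camera_id[cell] %in% cams[[i]]) found <- TRUE
    }
    expect_true(found)
  }
  bf_total <- 0L
  seen <- character(0)
  for (i in seq_len(nrow(det))) {
    for (cm in cams[[i]]) {
      key <- paste(cm, det$species_id[i], day[i])
      if (!key %in% seen) {
        seen <- c(seen, key)
        bf_total <- bf_total + 1L
      }
    }
  }
  expect_equal(sum(h$detected), bf_total)
})
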