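#' Simulate raw camera-trap trigger events
#'
#' Generates a stream of raw trigger events (one row per event) for each
#' species at each camera over `n_days` days. Event counts per camera-day
#' are Poisson with rate `daily_event_rate * season(t) * camera_effect`:
#' trigger events of unmarked animals passing a camera independently are
#' well approximated by a point process. Camera effects are fixed
#' log-normal multipliers (mean 1) per camera per species; the seasonal
#' term is a sinusoid with the configured amplitude and period 365 days.
#' Event times are uniform within the day, at minute resolution. With
#' probability `within_day_cluster_prob` an event additionally spawns a
#' companion event 1–29 minutes later at a random camera in the same
#' cluster, which exercises the downstream 30-minute deduplication rule.
#'
#' Under a fixed `seed` the returned table is identical across runs.
#'
#' @param deployment Deployment data.frame from [generate_deployment()].
#' @param species_models List of [species_model()] objects.
#' @param start_date First simulated day (`Date`).
#' @param n_days Number of simulated days (>= 1).
#' @param seed Optional integer seed (restores the caller's RNG stream).
#'
#' @return A data.frame with columns `site_id`, `camera_id`, `species_id`,
#'   `timestamp` (POSIXct, UTC, minute resolution), sorted by timestamp.
#' @export
#' @examples
#' dep <- generate_deployment(n_sites = 1, seed = 1)
#' ev <- simulate_events(dep, default_species_models(), n_days = 30, seed = 2)
#' head(ev)
simulate_events <- function(deployment,
                            species_models,
                            start_date = as.Date("2014-11-01"),
                            n_days = 365,
                            seed = NULL) {
  validate_deployment(deployment)
  if (nrow(deployment) == 0L) stop_invalid("`deployment` is empty")
  if (!is_count(n_days)) stop_invalid("`n_days` must be a positive integer")
  if (inherits(species_models, "species_model")) {
    species_models <- list(species_models)
  }
  ok <- vapply(species_models, inherits, TRUE, "species_model")
  if (length(species_models) == 0L || !all(ok)) {
    stop_invalid("`species_models` must be a list of species_model objects")
  }
  start_date <- as.Date(start_date)

  ncam <- nrow(deployment)
  cams <- deployment$camera_id
  cluster_members <- split(seq_len(ncam), deployment$cluster_id)
  cam_cluster <- deployment$cluster_id
  total_minutes <- n_days * 1440

  with_seed(seed, {
    days <- seq_len(n_days)
    pieces <- vector("list", length(species_models))
    for (si in seq_along(species_models)) {
      sm <- species_models[[si]]
      season <- 1 + sm$seasonal_amplitude * sin(2 * pi * days / 365)
      effects <- if (sm$camera_heterogeneity_sd > 0) {
        exp(rnorm(ncam, -sm$camera_heterogeneity_sd^2 / 2,
                  sm$camera_heterogeneity_sd))
      } else {
        rep(1, ncam)
      }
      lambda <- sm$daily_event_rate * outer(effects, season)  # ncam x n_days
      counts <- matrix(rpois(length(lambda), lambda), nrow = ncam)
      n_ev <- sum(counts)
      if (n_ev == 0L) next
      cam_idx <- rep(rep(seq_len(ncam), ncol(counts)), as.vector(counts))
      day_idx <- rep(rep(days, each = ncam), as.vector(counts))
      minute <- (day_idx - 1) * 1440 + floor(runif(n_ev) * 1440)

      if (sm$within_day_cluster_prob > 0) {
        spawn <- runif(n_ev) < sm$within_day_cluster_prob
        n_sp <- sum(spawn)
        if (n_sp > 0L) {
          offset <- floor(runif(n_sp, 1, 29))
          comp_min <- minute[spawn] + offset
          comp_cam <- vapply(cam_idx[spawn], function(ci) {
            members <- cluster_members[[cam_cluster[ci]]]
            members[sample.int(length(members), 1L)]
          }, integer(1))
          keep <- comp_min < total_minutes
          cam_idx <- c(cam_idx, comp_cam[keep])
          minute <- c(minute, comp_min[keep])
        }
      }

      pieces[[si]] <- data.frame(
        site_id = deployment$site_id[cam_idx],
        camera_id = cams[cam_idx],
        species_id = sm$species_id,
        minute = minute,
        stringsAsFactors = FALSE
      )
    }
    ev <- do.call(rbind, pieces)
    if (is.null(ev)) {
      ev <- data.frame(site_id = character(), camera_id = character(),
                       species_id = character(), minute = numeric(),
                       stringsAsFactors = FALSE)
    }
    ev <- ev[order(ev$minute, ev$site_id, ev$camera_id, ev$species_id), ,
             drop = FALSE]
    rownames(ev) <- NULL
    origin <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
    out <- data.frame(
      site_id = ev$site_id,
      camera_id = ev$camera_id,
      species_id = ev$species_id,
      timestamp = origin + ev$minute * 60,
      stringsAsFactors = FALSE
    )
    out
  })
}

validate_events <- function(events) {
  need <- c("site_id", "camera_id", "species_id", "timestamp")
  if (!is.data.frame(events) || !all(need %in% names(events))) {
    stop_invalid("`events` must be a data.frame with columns ",
                 paste(need, collapse = ", "))
  }
  if (!inherits(events$timestamp, "POSIXct")) {
    stop_invalid("`events$timestamp` must be POSIXct")
  }
  invisible(events)
}

# Integer minutes since local midnight of `year_start` for each event.
event_minutes <- function(events, year_start) {
  origin <- as.POSIXct(paste(as.Date(year_start), "00:00:00"), tz = "UTC")
  as.numeric(difftime(events$timestamp, origin, units = "mins"))
}

#' Write / read raw trigger events as CSV
#'
#' Events are stored with ISO-8601 minute-resolution timestamps. Comment
#' lines starting with `#` are ignored on read.
#'
#' @param events Events data.frame from [simulate_events()].
#' @param path File path.
#' @param header_comment Optional `# `-prefixed header line(s).
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns the events data.frame.
#' @export
write_events_csv <- function(events, path, header_comment = NULL) {
  validate_events(events)
  out <- events
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M", tz = "UTC")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  ev$timestamp <- as.POSIXct(ev$timestamp, format = "%Y-%m-%dT%H:%M",
                             tz = "UTC")
  validate_events(ev)
  ev
}
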