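#' Merge raw trigger events into independent site-level detections
#'
#' Applies the independence rule used for clustered camera arrays: within a
#' site, observations of the same species are merged into a single
#' detection unless at least `window_minutes` (default 30) have passed
#' since the previous observation. The rule operates across all cameras at
#' the site, so a raccoon recorded 10 minutes apart at two different
#' cameras counts as one detection. Chaining is sliding-window: an event
#' joins the current chain iff its gap to the chain's *latest* event is
#' strictly less than the window, so continuous activity is treated as one
#' visit.
#'
#' When `camera_subset` is supplied only events from those cameras are
#' considered, which answers the counterfactual "what would this array have
#' seen" — detections are re-derived from scratch for the subset rather
#' than attributed to single cameras. Set `attribution = "first_camera"`
#' to instead deduplicate once over all cameras and date each detection to
#' its earliest event's camera (the alternative reading; results differ
#' only when cross-camera merges occur).
#'
#' @param events Events data.frame (see [simulate_events()]).
#' @param window_minutes Positive merge window in minutes (default 30).
#' @param camera_subset Optional character vector of camera ids to keep.
#' @param deployment Optional deployment table; if given, events referring
#'   to cameras absent from it (or listed under a different site) raise a
#'   validation error.
#' @param attribution `"resample"` (default; deduplicate within the
#'   subset) or `"first_camera"` (deduplicate over all cameras first, then
#'   keep detections whose earliest camera is in the subset).
#'
#' @return A data.frame of independent detections with columns `site_id`,
#'   `species_id`, `timestamp_first`, `timestamp_last`, `n_events`,
#'   `contributing_cameras` (semicolon-separated camera ids), ordered by
#'   site, species, time.
#' @export
#' @examples
#' dep <- generate_deployment(n_sites = 1, seed = 1)
#' ev <- simulate_events(dep, default_species_models(), n_days = 10, seed = 2)
#' det <- deduplicate_events(ev)
#' nrow(det) <= nrow(ev)
deduplicate_events <- function(events,
                               window_minutes = 30,
                               camera_subset = NULL,
                               deployment = NULL,
                               attribution = c("resample", "first_camera")) {
  validate_events(events)
  attribution <- match.arg(attribution)
  if (!is.numeric(window_minutes) || length(window_minutes) != 1L ||
      !is.finite(window_minutes) || window_minutes <= 0) {
    stop_invalid("`window_minutes` must be a single positive number")
  }
  if (!is.null(deployment)) {
    validate_deployment(deployment)
    m <- match(events$camera_id, deployment$camera_id)
    if (anyNA(m)) {
      stop_invalid("events reference cameras not present in the deployment: ",
                   paste(unique(events$camera_id[is.na(m)]), collapse = ", "))
    }
    bad <- events$site_id != deployment$site_id[m]
    if (any(bad)) {
      stop_invalid("events list cameras under the wrong site: ",
                   paste(unique(events$camera_id[bad]), collapse = ", "))
    }
  }

  subset_events <- events
  if (!is.null(camera_subset) && attribution == "resample") {
    subset_events <- events[events$camera_id %in% camera_subset, , drop = FALSE]
  }
  if (nrow(subset_events) == 0L) {
    return(data.frame(site_id = character(), species_id = character(),
                      timestamp_first = as.POSIXct(character(), tz = "UTC"),
                      timestamp_last = as.POSIXct(character(), tz = "UTC"),
                      n_events = integer(),
                      contributing_cameras = character(),
                      stringsAsFactors = FALSE))
  }

  key <- paste(subset_events$site_id, subset_events$species_id, sep = "\r")
  groups <- split(seq_len(nrow(subset_events)), key)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    g <- subset_events[rows, , drop = FALSE]
    o <- order(g$timestamp, g$camera_id)
    g <- g[o, , drop = FALSE]
    tmins <- as.numeric(g$timestamp) / 60
    new_chain <- c(TRUE, diff(tmins) >= window_minutes)
    chain_id <- cumsum(new_chain)
    first_i <- which(new_chain)
    last_i <- c(first_i[-1] - 1L, length(tmins))
    cams <- vapply(split(g$camera_id, chain_id), function(cs) {
      paste(sort(unique(cs)), collapse = ";")
    }, "")
    first_cam <- g$camera_id[first_i]
    d <- data.frame(
      site_id = g$site_id[1],
      species_id = g$species_id[1],
      timestamp_first = g$timestamp[first_i],
      timestamp_last = g$timestamp[last_i],
      n_events = as.integer(last_i - first_i + 1L),
      contributing_cameras = unname(cams),
      stringsAsFactors = FALSE
    )
    if (attribution == "first_camera") d$first_camera <- first_cam
    out[[gi]] <- d
  }
  det <- do.call(rbind, out)
  if (attribution == "first_camera" && !is.null(camera_subset)) {
    det <- det[det$first_camera %in% camera_subset, , drop = FALSE]
  }
  det <- det[order(det$site_id, det$species_id, det$timestamp_first), ,
             drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Build a daily binary detection history
#'
#' Expands independent detections into a long-format table over the full
#' grid (site, camera, species, day-of-year): cell value 1 iff some
#' detection at that site/species lists the camera among its contributing
#' cameras and starts (`timestamp_first`) on that day. Days are indexed
#' 1..`n_days` from local midnight of `year_start`.
#'
#' @param detections Detections from [deduplicate_events()].
#' @param deployment Deployment table (defines the site/camera grid).
#' @param year_start First day of the indexed year (`Date`).
#' @param n_days Number of days in the indexed year (default 365).
#' @param species Optional character vector fixing the species axis;
#'   defaults to the species present in `detections`.
#'
#' @return A data.frame with columns `site_id`, `camera_id`, `species_id`,
#'   `day`, `detected` (0/1), covering the full grid.
#' @export
build_daily_history <- function(detections, deployment,
                                year_start = as.Date("2014-11-01"),
                                n_days = 365,
                                species = NULL) {
  validate_deployment(deployment)
  need <- c("site_id", "species_id", "timestamp_first", "contributing_cameras")
  if (!is.data.frame(detections) || !all(need %in% names(detections))) {
    stop_invalid("`detections` must have columns ", paste(need, collapse = ", "))
  }
  year_start <- as.Date(year_start)
  if (is.null(species)) species <- sort(unique(detections$species_id))
  if (length(species) == 0L) species <- character()

  grid <- expand.grid(
    day = seq_len(n_days),
    camera_id = deployment$camera_id,
    species_id = species,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$site_id <- deployment$site_id[match(grid$camera_id, deployment$camera_id)]
  grid <- grid[, c("site_id", "camera_id", "species_id", "day")]
  grid$detected <- rep(0L, nrow(grid))
  if (nrow(detections) > 0L) {
    origin <- as.POSIXct(paste(year_start, "00:00:00"), tz = "UTC")
    day <- floor(as.numeric(difftime(detections$timestamp_first, origin,
                                     units = "days"))) + 1L
    if (any(day < 1L | day > n_days)) {
      stop_invalid("detections fall outside the indexed year")
    }
    cams <- strsplit(detections$contributing_cameras, ";", fixed = TRUE)
    n_per <- lengths(cams)
    hit <- data.frame(
      camera_id = unlist(cams),
      species_id = rep(detections$species_id, n_per),
      day = rep(day, n_per),
      stringsAsFactors = FALSE
    )
    key_hit <- paste(hit$camera_id, hit$species_id, hit$day, sep = "\r")
    key_grid <- paste(grid$camera_id, grid$species_id, grid$day, sep = "\r")
    grid$detected[key_grid %in% key_hit] <- 1L
  }
  rownames(grid) <- NULL
  grid
}

#' Write / read independent detections as CSV
#'
#' @param detections Detections data.frame from [deduplicate_events()].
#' @param path File path.
#' @param header_comment Optional `# `-prefixed header line(s).
#' @return `write_detections_csv()` returns `path` invisibly;
#'   `read_detections_csv()` returns the detections data.frame.
#' @export
write_detections_csv <- function(detections, path, header_comment = NULL) {
  out <- detections
  out$timestamp_first <- format(out$timestamp_first, "%Y-%m-%dT%H:%M", tz = "UTC")
  out$timestamp_last <- format(out$timestamp_last, "%Y-%m-%dT%H:%M", tz = "UTC")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  det <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  det$timestamp_first <- as.POSIXct(det$timestamp_first,
                                    format = "%Y-%m-%dT%H:%M", tz = "UTC")
  det$timestamp_last <- as.POSIXct(det$timestamp_last,
                                   format = "%Y-%m-%dT%H:%M", tz = "UTC")
  det
}
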