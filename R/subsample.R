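#' Design-space configuration for Monte Carlo subsampling
#'
#' Defines the space of hypothetical study designs the subsampler draws
#' from: the number of cameras per site (`m`, the array size), the season
#' length in days (`S`), and the replicate length in days (`L`, how the
#' continuous record is cut into survey replicates). In `"random_season"`
#' mode every component is drawn uniformly from its range each iteration;
#' in `"fixed_grid"` mode the array size and season length are swept over
#' explicit grids (used for season-length detectability curves) while the
#' season start and replicate length remain random.
#'
#' @param m_range Integer range `c(lo, hi)` for array size, within 1..10.
#' @param season_length_range Integer range for season length in days,
#'   within 1..365 (default 2..365).
#' @param replicate_length_range Integer range for replicate length in
#'   days, within 1..28.
#' @param mode `"random_season"` or `"fixed_grid"`.
#' @param m_grid,season_grid Grids used in `"fixed_grid"` mode.
#'
#' @return A list of class `design_config`.
#' @export
design_config <- function(m_range = c(1, 10),
                          season_length_range = c(2, 365),
                          replicate_length_range = c(1, 28),
                          mode = c("random_season", "fixed_grid"),
                          m_grid = c(1, 2, 3, 5, 7, 10),
                          season_grid = seq(15, 365, by = 25)) {
  mode <- match.arg(mode)
  chk_range <- function(r, lo, hi, what) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < lo || r[2] > hi ||
        any(r != round(r))) {
      stop_invalid("`", what, "` must be an integer range within [", lo, ", ",
                   hi, "]")
    }
  }
  chk_range(m_range, 1, 10, "m_range")
  chk_range(season_length_range, 1, 365, "season_length_range")
  chk_range(replicate_length_range, 1, 28, "replicate_length_range")
  if (mode == "fixed_grid") {
    if (any(m_grid < 1 | m_grid > 10) || any(m_grid != round(m_grid))) {
      stop_invalid("`m_grid` must be integers in 1..10")
    }
    if (any(season_grid < 1 | season_grid > 365)) {
      stop_invalid("`season_grid` must lie in 1..365")
    }
  }
  structure(
    list(m_range = as.integer(m_range),
         season_length_range = as.integer(season_length_range),
         replicate_length_range = as.integer(replicate_length_range),
         mode = mode,
         m_grid = as.integer(m_grid),
         season_grid = as.integer(round(season_grid))),
    class = "design_config"
  )
}

sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
}

#' Draw one hypothetical study design
#'
#' Draws an array size `m`, a season start day (uniform on the year), a
#' season length `S`, a replicate length `L` (uniform on its range,
#' rejecting and redrawing any `L > S`), and a uniform without-replacement
#' subset of `m` cameras per site. The number of replicates is
#' `k = floor(S / L)`; the trailing `S - kL` days are discarded downstream.
#' Uses the current RNG stream (seed at the caller).
#'
#' @param design A [design_config()].
#' @param deployment Deployment table (supplies each site's cameras).
#' @param iteration_id Integer label stored in the draw.
#' @param m,season_length Optional forced values (used by the fixed-grid
#'   sweep); when `NULL` they are drawn from the configured ranges.
#' @param year_days Days in the indexed year (default 365).
#'
#' @return An object of class `subsample_draw`: list with `iteration_id`,
#'   `m`, `season_start`, `season_length`, `replicate_length`,
#'   `n_replicates`, `selected_cameras` (named list site -> camera ids),
#'   `n_rejected` (count of rejected `L > S` draws).
#' @export
draw_design <- function(design, deployment, iteration_id = 1L,
                        m = NULL, season_length = NULL, year_days = 365L) {
  if (!inherits(design, "design_config")) stop_invalid("`design` must be a design_config")
  validate_deployment(deployment)
  site_cams <- split(deployment$camera_id, deployment$site_id)

  if (is.null(m)) m <- sample_range(design$m_range)
  min_site <- min(lengths(site_cams))
  if (m > min_site) {
    stop_invalid("array size m = ", m, " exceeds the ", min_site,
                 " cameras available at the smallest site")
  }
  S <- if (is.null(season_length)) sample_range(design$season_length_range) else as.integer(season_length)
  if (S < 1 || S > year_days) stop_invalid("season length outside 1..", year_days)
  season_start <- sample.int(year_days, 1L)

  lr <- design$replicate_length_range
  if (lr[1] > S) {
    stop_invalid("no admissible replicate length: min replicate length ",
                 lr[1], " exceeds season length ", S)
  }
  n_rejected <- 0L
  repeat {
    L <- sample_range(lr)
    if (L <= S) break
    n_rejected <- n_rejected + 1L
    if (n_rejected > 10000L) stop_invalid("replicate-length rejection did not terminate")
  }
  k <- S %/% L

  structure(
    list(iteration_id = as.integer(iteration_id),
         m = as.integer(m),
         season_start = as.integer(season_start),
         season_length = as.integer(S),
         replicate_length = as.integer(L),
         n_replicates = as.integer(k),
         selected_cameras = lapply(site_cams, function(cs) sort(sample(cs, m))),
         n_rejected = n_rejected),
    class = "subsample_draw"
  )
}

#' @export
print.subsample_draw <- function(x, ...) {
  cat(sprintf(
    "<subsample_draw #%d> m = %d cameras/site, season start day %d, S = %d d, L = %d d, k = %d replicates, %d sites\n",
    x$iteration_id, x$m, x$season_start, x$season_length,
    x$replicate_length, x$n_replicates, length(x$selected_cameras)))
  invisible(x)
}

# Map day-of-year (1..year_days) -> replicate index (0 = outside the
# season or in the discarded S - kL trailing days). The season wraps
# modulo the year, mirroring a yearlong record looped on itself.
replicate_day_map <- function(season_start, S, L, year_days = 365L) {
  k <- S %/% L
  map <- integer(year_days)
  offs <- 0:(k * L - 1)
  days <- ((season_start - 1 + offs) %% year_days) + 1
  map[days] <- rep(seq_len(k), each = L)
  map
}

# Detection-start days from a sorted vector of event minutes: chains are
# built with the sliding 30-minute rule and each chain contributes the day
# of its first event.
chain_start_days <- function(minutes_sorted, window_minutes) {
  if (!length(minutes_sorted)) return(integer())
  new_chain <- c(TRUE, diff(minutes_sorted) >= window_minutes)
  unique(minutes_sorted[new_chain] %/% 1440 + 1)
}

# Pre-split events into per-species, per-site sorted minute/camera-code
# vectors so the Monte Carlo loop avoids repeated data.frame subsetting.
prepare_event_index <- function(events, deployment, year_start,
                                year_days = 365L) {
  validate_events(events)
  minutes <- event_minutes(events, year_start)
  if (nrow(events) > 0L &&
      (min(minutes) < 0 || max(minutes) >= year_days * 1440)) {
    stop_invalid("events fall outside the indexed year starting ",
                 as.Date(year_start))
  }
  cam_code <- match(events$camera_id, deployment$camera_id)
  if (anyNA(cam_code)) stop_invalid("events reference cameras missing from the deployment")
  idx <- list()
  for (sp in unique(events$species_id)) {
    sel <- events$species_id == sp
    per_site <- list()
    for (site in unique(events$site_id[sel])) {
      ss <- sel & events$site_id == site
      o <- order(minutes[ss])
      per_site[[site]] <- list(minutes = minutes[ss][o],
                               cam = cam_code[ss][o])
    }
    idx[[sp]] <- per_site
  }
  attr(idx, "camera_ids") <- deployment$camera_id
  idx
}

matrix_from_index <- function(index, draw, species_id, window_minutes,
                              year_days = 365L) {
  map <- replicate_day_map(draw$season_start, draw$season_length,
                           draw$replicate_length, year_days)
  k <- draw$n_replicates
  sites <- names(draw$selected_cameras)
  mat <- matrix(0L, nrow = length(sites), ncol = k,
                dimnames = list(sites, NULL))
  cam_ids <- attr(index, "camera_ids")
  per_site <- index[[species_id]]
  for (i in seq_along(sites)) {
    sd <- per_site[[sites[i]]]
    if (is.null(sd)) next
    codes <- match(draw$selected_cameras[[sites[i]]], cam_ids)
    keep <- sd$cam %in% codes
    days <- chain_start_days(sd$minutes[keep], window_minutes)
    reps <- unique(map[days])
    reps <- reps[reps > 0L]
    if (length(reps)) mat[i, reps] <- 1L
  }
  attr(mat, "species_id") <- species_id
  attr(mat, "array_size") <- draw$m
  attr(mat, "draw") <- draw
  mat
}

#' Extract the replicate detection matrix for one design draw
#'
#' Rebuilds, for one hypothetical design, the site x replicate binary
#' detection matrix that design would have produced: per site, events from
#' the draw's selected cameras are deduplicated with the 30-minute
#' sliding-window rule, detection days are assigned from each merged
#' detection's first event, and replicate `j` (days
#' `season_start + (j-1)L .. season_start + jL - 1`, wrapping modulo the
#' year) is marked 1 iff at least one detection starts inside it. The
#' trailing `S - kL` days are discarded.
#'
#' @param events Events data.frame covering the indexed year.
#' @param draw A [draw_design()] result.
#' @param species_id Species to extract (must occur in `events` unless the
#'   event table is empty).
#' @param year_start First day of the indexed year.
#' @param window_minutes Deduplication window (default 30).
#' @param year_days Days in the indexed year (default 365).
#'
#' @return An `N x k` binary matrix with attributes `species_id`,
#'   `array_size` and `draw`.
#' @export
extract_replicate_matrix <- function(events, draw, species_id,
                                     year_start = as.Date("2014-11-01"),
                                     window_minutes = 30,
                                     year_days = 365L) {
  validate_events(events)
  if (!inherits(draw, "subsample_draw")) stop_invalid("`draw` must come from draw_design()")
  if (nrow(events) > 0L && !species_id %in% events$species_id) {
    stop_invalid("unknown species: ", species_id)
  }
  dep_stub <- data.frame(camera_id = sort(unique(c(events$camera_id,
                                                   unlist(draw$selected_cameras)))))
  minutes <- event_minutes(events, year_start)
  if (nrow(events) > 0L && (min(minutes) < 0 || max(minutes) >= year_days * 1440)) {
    stop_invalid("events fall outside the indexed year starting ",
                 as.Date(year_start))
  }
  index <- structure(list(), camera_ids = dep_stub$camera_id)
  if (nrow(events) > 0L) {
    sel <- events$species_id == species_id
    per_site <- list()
    for (site in unique(events$site_id[sel])) {
      ss <- sel & events$site_id == site
      o <- order(minutes[ss])
      per_site[[site]] <- list(minutes = minutes[ss][o],
                               cam = match(events$camera_id[ss][o],
                                           dep_stub$camera_id))
    }
    index[[species_id]] <- per_site
  } else {
    index[[species_id]] <- list()
  }
  attr(index, "camera_ids") <- dep_stub$camera_id
  matrix_from_index(index, draw, species_id, window_minutes, year_days)
}

#' Run the Monte Carlo subsampling study
#'
#' Repeatedly parses a yearlong event record into hypothetical study
#' designs and computes, for every iteration and species, the survey
#' detection probability `p = sum(P)/(N k)` and the season detection
#' probability `p* = 1 - (1-p)^k`. In `"random_season"` mode each of
#' `n_iterations` iterations draws a fresh design; in `"fixed_grid"` mode
#' `n_iterations` draws are made for every (array size, season length)
#' grid cell. One design draw is shared by all species within an
#' iteration.
#'
#' Per-iteration seeds are derived deterministically from `master_seed`,
#' so a rerun with the same seed reproduces the result table exactly.
#'
#' @param events Events data.frame covering the indexed year.
#' @param deployment Deployment table.
#' @param design A [design_config()].
#' @param n_iterations Iterations (per grid cell in `"fixed_grid"` mode);
#'   default 5000.
#' @param species Character vector of species to evaluate (default: all
#'   species present in `events`).
#' @param master_seed Integer master seed (required: no silent
#'   nondeterminism).
#' @param year_start First day of the indexed year.
#' @param window_minutes Deduplication window (default 30).
#' @param year_days Days in the indexed year (default 365).
#'
#' @return A data.frame with one row per iteration x species: columns
#'   `iteration_id`, `species_id`, `array_size`, `season_start`,
#'   `season_length`, `replicate_length`, `n_replicates`, `p`, `p_star`.
#'   Attribute `n_rejected_draws` counts rejected `L > S` draws.
#' @export
run_monte_carlo <- function(events, deployment,
                            design = design_config(),
                            n_iterations = 5000,
                            species = NULL,
                            master_seed,
                            year_start = as.Date("2014-11-01"),
                            window_minutes = 30,
                            year_days = 365L) {
  if (missing(master_seed) || !is_count(master_seed, min = 0L)) {
    stop_invalid("`master_seed` must be supplied as a non-negative integer")
  }
  if (!is_count(n_iterations)) stop_invalid("`n_iterations` must be >= 1")
  validate_deployment(deployment)
  if (is.null(species)) species <- sort(unique(events$species_id))
  if (length(species) == 0L) stop_invalid("no species to evaluate")

  index <- prepare_event_index(events, deployment, year_start, year_days)

  cells <- if (design$mode == "fixed_grid") {
    expand.grid(m = design$m_grid, S = design$season_grid,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(m = NA_integer_, S = NA_integer_)
  }
  n_total <- nrow(cells) * n_iterations
  iter_seeds <- with_seed(as.integer(master_seed),
                          sample.int(.Machine$integer.max, n_total))

  rows_per <- length(species)
  out_iter <- integer(n_total * rows_per)
  out_sp <- character(n_total * rows_per)
  out_num <- matrix(NA_real_, nrow = n_total * rows_per, ncol = 7)
  colnames(out_num) <- c("array_size", "season_start", "season_length",
                         "replicate_length", "n_replicates", "p", "p_star")
  n_rejected <- 0L
  pos <- 0L
  it <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (rep_i in seq_len(n_iterations)) {
      it <- it + 1L
      set.seed(iter_seeds[it])
      draw <- draw_design(design, deployment, iteration_id = it,
                          m = if (design$mode == "fixed_grid") cells$m[ci] else NULL,
                          season_length = if (design$mode == "fixed_grid") cells$S[ci] else NULL,
                          year_days = year_days)
      n_rejected <- n_rejected + draw$n_rejected
      for (sp in species) {
        mat <- matrix_from_index(index, draw, sp, window_minutes, year_days)
        p <- sum(mat) / length(mat)
        pos <- pos + 1L
        out_iter[pos] <- it
        out_sp[pos] <- sp
        out_num[pos, ] <- c(draw$m, draw$season_start, draw$season_length,
                            draw$replicate_length, draw$n_replicates, p,
                            1 - (1 - p)^draw$n_replicates)
      }
    }
  }
  res <- data.frame(iteration_id = out_iter, species_id = out_sp,
                    out_num, stringsAsFactors = FALSE)
  attr(res, "master_seed") <- as.integer(master_seed)
  attr(res, "mode") <- design$mode
  attr(res, "n_rejected_draws") <- n_rejected
  res
}

#' Write / read Monte Carlo results as CSV
#'
#' @param results Result table from [run_monte_carlo()].
#' @param path File path.
#' @param header_comment Optional `# `-prefixed header line(s).
#' @return `write_mc_results_csv()` returns `path` invisibly;
#'   `read_mc_results_csv()` returns the results data.frame.
#' @export
write_mc_results_csv <- function(results, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  write.csv(results, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mc_results_csv
#' @export
read_mc_results_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
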