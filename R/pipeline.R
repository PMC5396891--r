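#' Configuration for a full pipeline run
#'
#' Bundles every knob of the simulate - deduplicate - subsample -
#' estimate - fit - compare pipeline, including the master seed (runs with
#' no seed are refused: no silent nondeterminism).
#'
#' @param out_dir Output directory for the run's CSV files and manifest.
#' @param master_seed Integer master seed for the whole run.
#' @param n_sites,clusters_per_site,cameras_per_cluster Deployment shape
#'   (defaults 4 x 2 x 5 = 40 cameras).
#' @param spacing A [spacing_config()].
#' @param species_models List of [species_model()] objects (default
#'   [default_species_models()]).
#' @param start_date,n_days Simulated year (default 365 days from
#'   2014-11-01).
#' @param window_minutes Deduplication window (default 30).
#' @param design A [design_config()] for the random-mode Monte Carlo.
#' @param n_iterations Monte Carlo iterations per species (default 5000).
#' @param alpha Familywise level for array comparisons.
#' @param comparison_method `"max_t_robust"` or `"permutation"`.
#' @param dedup_attribution `"resample"` or `"first_camera"` (see
#'   [deduplicate_events()]); the choice is echoed in the manifest.
#' @param curve_source `"random"` fits season-detectability curves to the
#'   random-mode draws grouped by array size (one Monte Carlo pass serves
#'   both analyses); `"grid"` runs a second, fixed-grid pass over
#'   `design$m_grid` x `design$season_grid` with `grid_iterations` draws
#'   per cell.
#' @param grid_iterations Draws per grid cell when `curve_source = "grid"`.
#' @param bin_curve_points Fit curves to per-season-length bin means
#'   instead of raw per-iteration points (default `FALSE`).
#' @param min_points_per_fit Minimum points required to attempt a curve
#'   fit for a species x array-size combination.
#' @param target_p_star Target season detectability used by the design
#'   scenario report (default 0.4).
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       master_seed,
                       n_sites = 4,
                       clusters_per_site = 2,
                       cameras_per_cluster = 5,
                       spacing = spacing_config(),
                       species_models = default_species_models(),
                       start_date = as.Date("2014-11-01"),
                       n_days = 365,
                       window_minutes = 30,
                       design = design_config(),
                       n_iterations = 5000,
                       alpha = 0.05,
                       comparison_method = c("max_t_robust", "permutation"),
                       dedup_attribution = c("resample", "first_camera"),
                       curve_source = c("random", "grid"),
                       grid_iterations = 25,
                       bin_curve_points = FALSE,
                       min_points_per_fit = 30,
                       target_p_star = 0.4) {
  if (missing(master_seed) || !is_count(master_seed, min = 0L)) {
    stop_invalid("`master_seed` is required (integer >= 0): runs must be reproducible")
  }
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1L) {
    stop_invalid("`out_dir` must be a single path")
  }
  cfg <- list(
    out_dir = out_dir,
    master_seed = as.integer(master_seed),
    n_sites = n_sites,
    clusters_per_site = clusters_per_site,
    cameras_per_cluster = cameras_per_cluster,
    spacing = if (inherits(spacing, "spacing_config")) spacing else do.call(spacing_config, spacing),
    species_models = species_models,
    start_date = as.Date(start_date),
    n_days = n_days,
    window_minutes = window_minutes,
    design = design,
    n_iterations = n_iterations,
    alpha = alpha,
    comparison_method = match.arg(comparison_method),
    dedup_attribution = match.arg(dedup_attribution),
    curve_source = match.arg(curve_source),
    grid_iterations = grid_iterations,
    bin_curve_points = bin_curve_points,
    min_points_per_fit = min_points_per_fit,
    target_p_star = target_p_star
  )
  if (!is_count(cfg$n_iterations)) stop_invalid("`n_iterations` must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_invalid("`alpha` must lie in (0, 1)")
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tf)
  unname(tools::md5sum(tf))
}

run_stage <- function(name, quiet, expr) {
  tryCatch(expr, error = function(e) {
    stop_invalid("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full study-design evaluation pipeline
#'
#' Orchestrates the whole analysis as one reproducible run: simulate a
#' clustered camera deployment and a yearlong event stream, deduplicate
#' events into independent detections, Monte Carlo subsample hypothetical
#' designs, compute the survey and season detectability estimators,
#' compare array sizes pairwise, and fit the season-detectability curve
#' per species and array size. Every output CSV carries the configuration
#' hash in a `#` header comment, and a JSON manifest records paths, file
#' hashes, the configuration echo and package/R versions, making the run
#' replayable bit for bit under the same master seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage-boundary progress messages.
#'
#' @return Invisibly, an object of class `camarray_run`: `manifest`,
#'   `paths`, plus the in-memory `deployment`, `events` (count only),
#'   `detections`, `mc_results`, `comparisons` (list by species),
#'   `curve_fits` (list by species then array size) and the
#'   `curve_fit_table`.
#' @export
run_full <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) stop_invalid("`config` must come from run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- paste("config_hash:", hash)
  say <- function(...) if (!quiet) message(...)
  paths <- list()

  stage_seeds <- with_seed(config$master_seed, sample.int(.Machine$integer.max, 3))

  dep <- run_stage("deployment", quiet, generate_deployment(
    config$n_sites, config$clusters_per_site, config$cameras_per_cluster,
    spacing = config$spacing, start_date = config$start_date,
    n_days = config$n_days, seed = stage_seeds[1]
  ))
  paths$deployments <- file.path(config$out_dir, "deployments.csv")
  write_deployments_csv(dep, paths$deployments, hdr)
  say("deployment: ", nrow(dep), " cameras at ", config$n_sites, " sites")

  ev <- run_stage("simulate", quiet, simulate_events(
    dep, config$species_models, start_date = config$start_date,
    n_days = config$n_days, seed = stage_seeds[2]
  ))
  paths$events <- file.path(config$out_dir, "events.csv")
  write_events_csv(ev, paths$events, hdr)
  say("simulate: ", nrow(ev), " raw trigger events")

  det <- run_stage("dedup", quiet, deduplicate_events(
    ev, window_minutes = config$window_minutes, deployment = dep,
    attribution = config$dedup_attribution
  ))
  paths$detections <- file.path(config$out_dir, "detections.csv")
  write_detections_csv(det, paths$detections, hdr)
  say("dedup (attribution = ", config$dedup_attribution, "): ", nrow(ev),
      " events -> ", nrow(det), " independent detections")

  mc <- run_stage("subsample", quiet, run_monte_carlo(
    ev, dep, design = config$design, n_iterations = config$n_iterations,
    master_seed = stage_seeds[3], year_start = config$start_date,
    window_minutes = config$window_minutes
  ))
  paths$mc_results <- file.path(config$out_dir, "mc_results.csv")
  write_mc_results_csv(mc, paths$mc_results, hdr)
  say("subsample: ", nrow(mc), " iteration-species rows (",
      attr(mc, "n_rejected_draws"), " rejected draws)")

  species <- sort(unique(mc$species_id))
  comparisons <- list()
  cmp_rows <- list()
  letter_rows <- list()
  for (sp in species) {
    sub <- mc[mc$species_id == sp, ]
    samples <- split(sub$p, sub$array_size)
    samples <- samples[vapply(samples, length, 0L) >= 2L]
    if (length(samples) < 2L) next
    cmp <- run_stage("compare", quiet, compare_array_sizes(
      samples, alpha = config$alpha, method = config$comparison_method,
      seed = config$master_seed, species_id = sp
    ))
    comparisons[[sp]] <- cmp
    cmp_rows[[sp]] <- cbind(species_id = sp, cmp$pairs)
    letter_rows[[sp]] <- data.frame(species_id = sp,
                                    array_size = names(cmp$groups),
                                    letters = unname(cmp$groups),
                                    stringsAsFactors = FALSE)
  }
  paths$comparisons <- file.path(config$out_dir, "comparisons.csv")
  paths$letters <- file.path(config$out_dir, "letters.csv")
  write_csv_hdr(do.call(rbind, cmp_rows), paths$comparisons, hdr)
  write_csv_hdr(do.call(rbind, letter_rows), paths$letters, hdr)
  say("compare: ", length(comparisons), " species compared across array sizes")

  curve_data <- if (config$curve_source == "grid") {
    grid_design <- config$design
    grid_design$mode <- "fixed_grid"
    run_stage("subsample-grid", quiet, run_monte_carlo(
      ev, dep, design = grid_design, n_iterations = config$grid_iterations,
      master_seed = stage_seeds[3] + 1L, year_start = config$start_date,
      window_minutes = config$window_minutes
    ))
  } else {
    mc
  }

  fits <- list()
  fit_rows <- list()
  for (sp in species) {
    fits[[sp]] <- list()
    sub <- curve_data[curve_data$species_id == sp, ]
    for (m in sort(unique(sub$array_size))) {
      pts <- sub[sub$array_size == m, c("season_length", "p_star")]
      if (nrow(pts) < config$min_points_per_fit ||
          length(unique(pts$season_length)) < 3L) next
      f <- suppressWarnings(fit_detcurve(p_star ~ season_length, pts,
                                         bin = config$bin_curve_points))
      f$species_id <- sp
      f$array_size <- m
      fits[[sp]][[as.character(m)]] <- f
      fit_rows[[paste(sp, m)]] <- data.frame(
        species_id = sp, array_size = m,
        A_hat = f$coefficients[["A"]], A_lo = f$ci["A", 1], A_hi = f$ci["A", 2],
        R_hat = f$coefficients[["R"]], R_lo = f$ci["R", 1], R_hi = f$ci["R", 2],
        rss = f$rss, converged = f$converged, n_points = f$n_points,
        stringsAsFactors = FALSE
      )
    }
  }
  fit_table <- do.call(rbind, fit_rows)
  rownames(fit_table) <- NULL
  paths$curve_fits <- file.path(config$out_dir, "curve_fits.csv")
  write_csv_hdr(fit_table, paths$curve_fits, hdr)
  say("fit: ", if (is.null(fit_table)) 0L else sum(fit_table$converged),
      " converged curves of ", if (is.null(fit_table)) 0L else nrow(fit_table))

  manifest <- list(
    config_hash = hash,
    master_seed = config$master_seed,
    package_version = as.character(utils::packageVersion("camarray")),
    r_version = R.version.string,
    files = lapply(paths, function(p) list(path = p,
                                           md5 = unname(tools::md5sum(p)))),
    counts = list(
      cameras = nrow(dep),
      raw_events = nrow(ev),
      independent_detections = nrow(det),
      mc_rows = nrow(mc),
      rejected_draws = attr(mc, "n_rejected_draws")
    ),
    config = deparse(unclass(config))
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(structure(
    list(manifest = manifest, paths = paths, deployment = dep,
         n_events = nrow(ev), detections = det, mc_results = mc,
         comparisons = comparisons, curve_fits = fits,
         curve_fit_table = fit_table, config = config),
    class = "camarray_run"
  ))
}

write_csv_hdr <- function(df, path, header_comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", header_comment), con)
  if (is.null(df)) {
    writeLines("", con)
  } else {
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.camarray_run <- function(x, ...) {
  cat("<camarray_run>\n")
  cat("  seed:", x$manifest$master_seed, " config hash:",
      x$manifest$config_hash, "\n")
  cat("  cameras:", x$manifest$counts$cameras,
      " raw events:", x$manifest$counts$raw_events,
      " detections:", x$manifest$counts$independent_detections, "\n")
  cat("  Monte Carlo rows:", x$manifest$counts$mc_rows, "\n")
  cat("  outputs in:", x$config$out_dir, "\n")
  invisible(x)
}

#' Design-scenario report: cameras vs sites vs season length
#'
#' Given fitted season-detectability curves for a species at several array
#' sizes, a total number of cameras, a field-season budget in days, and a
#' target season detection probability, reports for each array size how
#' many sites one deployment covers (`floor(total_cameras / m)`), the
#' minimum season length that reaches the target (from
#' [invert_detcurve()]), whether that fits the budget, and how many
#' sequential deployments (relocating the arrays) fit: e.g. with 40
#' cameras and a 3-camera array, 13 sites per deployment, and two
#' deployments within the budget doubling the covered sites to 26.
#'
#' @param fits Named list of converged [fit_detcurve()] objects, names =
#'   array size (e.g. the per-species element of a [run_full()] result's
#'   `curve_fits`).
#' @param total_cameras Total cameras available.
#' @param season_budget_days Field-season budget in days.
#' @param target_p_star Required season detection probability.
#' @param max_deployments Cap on sequential deployments per season
#'   (default 2: deploy, retrieve, relocate once).
#'
#' @return A data.frame with one row per array size: `array_size`,
#'   `sites_per_deployment`, `min_season_days`, `feasible`,
#'   `n_deployments`, `sites_covered`; attribute `status` summarises the
#'   outcome (e.g. `"no feasible design"` when every row is infeasible).
#' @export
report_design_scenario <- function(fits, total_cameras, season_budget_days,
                                   target_p_star = 0.4,
                                   max_deployments = 2) {
  if (!is_count(total_cameras) || !is_count(season_budget_days)) {
    stop_invalid("`total_cameras` and `season_budget_days` must be positive integers")
  }
  if (!is.list(fits) || is.null(names(fits))) {
    stop_invalid("`fits` must be a named list of detcurve objects (names = array size)")
  }
  rows <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (!inherits(f, "detcurve") || !isTRUE(f$converged)) next
    m <- as.integer(nm)
    if (m < 1 || m > total_cameras) next
    minS <- invert_detcurve(f, target_p_star)
    feasible <- is.finite(minS) && minS <= season_budget_days
    n_dep <- if (feasible) min(max_deployments, floor(season_budget_days / minS)) else 0L
    rows[[nm]] <- data.frame(
      array_size = m,
      sites_per_deployment = floor(total_cameras / m),
      min_season_days = as.numeric(minS),
      feasible = feasible,
      n_deployments = as.integer(n_dep),
      sites_covered = as.integer(floor(total_cameras / m) * n_dep),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    array_size = integer(), sites_per_deployment = integer(),
    min_season_days = numeric(), feasible = logical(),
    n_deployments = integer(), sites_covered = integer()
  )
  rownames(out) <- NULL
  out <- out[order(out$array_size), , drop = FALSE]
  status <- if (nrow(out) == 0L) {
    "no converged curve fits supplied"
  } else if (!any(out$feasible)) {
    "no feasible design: no array size reaches the target within the season budget"
  } else {
    "ok"
  }
  attr(out, "status") <- status
  out
}
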