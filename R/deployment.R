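#' Spacing configuration for camera deployments
#'
#' Controls the geometry of the simulated deployment: each site holds
#' `clusters_per_site` 1-ha clusters of cameras placed at random
#' coordinates, with cluster centres a fixed distance apart and sites
#' spaced far enough apart to be independent.
#'
#' @param cluster_extent_m Side length in metres of the square area
#'   (default 100 m, i.e. 1 ha) within which a cluster's cameras are
#'   placed at random coordinates.
#' @param intra_mean_m Target mean pairwise distance in metres between
#'   cameras within a cluster (default 65.2 m).
#' @param intra_tol_m Half-width of the accepted band around
#'   `intra_mean_m`; cluster layouts are redrawn until the realised mean
#'   pairwise distance falls within `intra_mean_m` +/- `intra_tol_m`.
#' @param inter_cluster_m Distance in metres between cluster centres
#'   within a site (default 589.3 m).
#' @param site_spacing_m Distance in metres between site origins
#'   (default 10 km, so sites are spatially independent).
#'
#' @return A list of class `spacing_config`.
#' @export
spacing_config <- function(cluster_extent_m = 100,
                           intra_mean_m = 65.2,
                           intra_tol_m = 10,
                           inter_cluster_m = 589.3,
                           site_spacing_m = 10000) {
  vals <- c(cluster_extent_m, intra_mean_m, intra_tol_m, inter_cluster_m,
            site_spacing_m)
  if (!all(is.finite(vals)) || any(vals[-3] <= 0) || intra_tol_m < 0) {
    stop_invalid("spacing distances must be positive finite numbers")
  }
  structure(
    list(cluster_extent_m = cluster_extent_m,
         intra_mean_m = intra_mean_m,
         intra_tol_m = intra_tol_m,
         inter_cluster_m = inter_cluster_m,
         site_spacing_m = site_spacing_m),
    class = "spacing_config"
  )
}

mean_pairwise_dist <- function(x, y) {
  mean(dist(cbind(x, y)))
}

# Draw one cluster of camera coordinates inside a square of side `extent`
# centred on (cx, cy), rejection-sampling until the mean pairwise distance
# lies in [lo, hi]. A single camera has no pairwise constraint.
draw_cluster_coords <- function(n, cx, cy, extent, lo, hi,
                                max_attempts = 10000L) {
  if (n == 1L) {
    return(cbind(x = cx + runif(1, -extent / 2, extent / 2),
                 y = cy + runif(1, -extent / 2, extent / 2)))
  }
  for (i in seq_len(max_attempts)) {
    x <- cx + runif(n, -extent / 2, extent / 2)
    y <- cy + runif(n, -extent / 2, extent / 2)
    d <- mean_pairwise_dist(x, y)
    if (d >= lo && d <= hi) return(cbind(x = x, y = y))
  }
  stop_invalid(
    "could not place a cluster with mean pairwise spacing in [",
    signif(lo, 4), ", ", signif(hi, 4), "] m inside a ",
    extent, " m square; widen `intra_tol_m` or the cluster extent"
  )
}

#' Generate a clustered camera-trap deployment
#'
#' Lays out `n_sites` sites, each containing `clusters_per_site` clusters
#' of `cameras_per_cluster` cameras placed at random coordinates inside a
#' 1-ha area (defaults: 4 sites x 2 clusters x 5 cameras = 40 cameras).
#' Cluster layouts are redrawn until the mean pairwise camera distance
#' within the cluster falls inside the configured band, and cluster centres
#' are separated by the configured inter-cluster distance at a random
#' bearing.
#'
#' @param n_sites,clusters_per_site,cameras_per_cluster Positive integer
#'   counts.
#' @param spacing A [spacing_config()].
#' @param start_date First day of the deployment (a `Date` or something
#'   coercible to one).
#' @param n_days Number of days cameras stay active (default 365; the
#'   simulated year).
#' @param seed Optional integer seed; the deployment is deterministic under
#'   a fixed seed and the caller's RNG stream is left untouched.
#'
#' @return A data.frame with one row per camera and columns `site_id`,
#'   `cluster_id`, `camera_id`, `x_m`, `y_m`, `active_start`, `active_end`.
#' @export
#' @examples
#' dep <- generate_deployment(seed = 1)
#' nrow(dep)  # 40 cameras
generate_deployment <- function(n_sites = 4,
                                clusters_per_site = 2,
                                cameras_per_cluster = 5,
                                spacing = spacing_config(),
                                start_date = as.Date("2014-11-01"),
                                n_days = 365,
                                seed = NULL) {
  if (!is_count(n_sites) || !is_count(clusters_per_site) ||
      !is_count(cameras_per_cluster)) {
    stop_invalid("site, cluster and camera counts must be positive integers")
  }
  if (!inherits(spacing, "spacing_config")) spacing <- do.call(spacing_config, spacing)
  if (!is_count(n_days)) stop_invalid("`n_days` must be a positive integer")
  start_date <- as.Date(start_date)

  with_seed(seed, {
    lo <- spacing$intra_mean_m - spacing$intra_tol_m
    hi <- spacing$intra_mean_m + spacing$intra_tol_m
    rows <- vector("list", n_sites * clusters_per_site)
    idx <- 0L
    for (s in seq_len(n_sites)) {
      site_id <- sprintf("site%02d", s)
      origin <- c((s - 1) * spacing$site_spacing_m, 0)
      # cluster centres: first at the site origin, the rest on a circle of
      # radius inter_cluster_m at random bearings (2 clusters -> one pair
      # exactly inter_cluster_m apart, matching the field layout)
      centres <- matrix(origin, nrow = 1)
      if (clusters_per_site > 1L) {
        theta <- runif(clusters_per_site - 1L, 0, 2 * pi)
        centres <- rbind(
          centres,
          cbind(origin[1] + spacing$inter_cluster_m * cos(theta),
                origin[2] + spacing$inter_cluster_m * sin(theta))
        )
      }
      for (cl in seq_len(clusters_per_site)) {
        xy <- draw_cluster_coords(cameras_per_cluster,
                                  centres[cl, 1], centres[cl, 2],
                                  spacing$cluster_extent_m, lo, hi)
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          site_id = site_id,
          cluster_id = sprintf("%s_c%d", site_id, cl),
          camera_id = sprintf("%s_c%d_cam%d", site_id, cl,
                              seq_len(cameras_per_cluster)),
          x_m = xy[, "x"],
          y_m = xy[, "y"],
          stringsAsFactors = FALSE
        )
      }
    }
    dep <- do.call(rbind, rows)
    dep$active_start <- start_date
    dep$active_end <- start_date + n_days - 1L
    rownames(dep) <- NULL
    dep
  })
}

validate_deployment <- function(deployment) {
  need <- c("site_id", "cluster_id", "camera_id", "x_m", "y_m",
            "active_start", "active_end")
  if (!is.data.frame(deployment) || !all(need %in% names(deployment))) {
    stop_invalid("`deployment` must be a data.frame with columns ",
                 paste(need, collapse = ", "))
  }
  if (anyDuplicated(deployment$camera_id)) {
    stop_invalid("duplicated camera_id in deployment")
  }
  invisible(deployment)
}

#' Write / read a deployment table as CSV
#'
#' Plain-CSV round trip for the deployment table, with ISO-8601 dates.
#' Lines starting with `#` (e.g. a config-hash header written by
#' [run_full()]) are ignored on read.
#'
#' @param deployment Deployment data.frame from [generate_deployment()].
#' @param path File path.
#' @param header_comment Optional comment line(s) written before the CSV
#'   header, each prefixed with `"# "`.
#' @return `write_deployments_csv()` returns `path` invisibly;
#'   `read_deployments_csv()` returns the deployment data.frame.
#' @export
write_deployments_csv <- function(deployment, path, header_comment = NULL) {
  validate_deployment(deployment)
  out <- deployment
  out$active_start <- format(out$active_start, "%Y-%m-%d")
  out$active_end <- format(out$active_end, "%Y-%m-%d")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste("#", header_comment), con)
  }
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_deployments_csv
#' @export
read_deployments_csv <- function(path) {
  dep <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  dep$active_start <- as.Date(dep$active_start)
  dep$active_end <- as.Date(dep$active_end)
  validate_deployment(dep)
  dep
}
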