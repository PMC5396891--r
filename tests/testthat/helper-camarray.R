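# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are written as plain loops, independent of the vectorised code
# paths they check.

test_origin <- as.Date("2015-01-01")

mk_events <- function(minute, camera_id, site_id = "s1", species_id = "sp",
                      start = test_origin) {
  origin <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  n <- length(minute)
  data.frame(site_id = rep_len(site_id, n), camera_id = rep_len(camera_id, n),
             species_id = rep_len(species_id, n),
             timestamp = origin + minute * 60,
             stringsAsFactors = FALSE)
}

mk_deployment <- function(n_sites = 1, cams_per_site = 2,
                          start = test_origin, n_days = 365) {
  rows <- list()
  for (s in seq_len(n_sites)) {
    site <- sprintf("s%d", s)
    rows[[s]] <- data.frame(
      site_id = site,
      cluster_id = paste0(site, "_c1"),
      camera_id = sprintf("%scam%d", site, seq_len(cams_per_site)),
      x_m = (s - 1) * 10000 + seq_len(cams_per_site) * 30,
      y_m = 0,
      stringsAsFactors = FALSE
    )
  }
  dep <- do.call(rbind, rows)
  dep$active_start <- start
  dep$active_end <- start + n_days - 1
  dep
}

mk_draw <- function(selected_cameras, season_start, season_length,
                    replicate_length, iteration_id = 1L) {
  m <- length(selected_cameras[[1]])
  structure(
    list(iteration_id = as.integer(iteration_id), m = as.integer(m),
         season_start = as.integer(season_start),
         season_length = as.integer(season_length),
         replicate_length = as.integer(replicate_length),
         n_replicates = as.integer(season_length %/% replicate_length),
         selected_cameras = selected_cameras, n_rejected = 0L),
    class = "subsample_draw"
  )
}

# Brute-force sliding-window chain construction: explicit event-by-event
# loop over each site x species group in time order.
bf_dedup <- function(events, window_minutes = 30, camera_subset = NULL,
                     start = test_origin) {
  origin <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  df <- data.frame(site_id = events$site_id, camera_id = events$camera_id,
                   species_id = events$species_id,
                   minute = as.numeric(difftime(events$timestamp, origin,
                                                units = "mins")),
                   stringsAsFactors = FALSE)
  if (!is.null(camera_subset)) df <- df[df$camera_id %in% camera_subset, ]
  out <- list()
  for (s in sort(unique(df$site_id))) {
    for (sp in sort(unique(df$species_id[df$site_id == s]))) {
      g <- df[df$site_id == s & df$species_id == sp, ]
      g <- g[order(g$minute, g$camera_id), ]
      cur <- NULL
      flush <- function(cur) {
        data.frame(site_id = s, species_id = sp, first = cur$first,
                   last = cur$last,
                   cams = paste(sort(unique(cur$cams)), collapse = ";"),
                   stringsAsFactors = FALSE)
      }
      for (i in seq_len(nrow(g))) {
        if (is.null(cur) || g$minute[i] - cur$last >= window_minutes) {
          if (!is.null(cur)) out[[length(out) + 1]] <- flush(cur)
          cur <- list(first = g$minute[i], last = g$minute[i],
                      cams = g$camera_id[i])
        } else {
          cur$last <- g$minute[i]
          cur$cams <- c(cur$cams, g$camera_id[i])
        }
      }
      if (!is.null(cur)) out[[length(out) + 1]] <- flush(cur)
    }
  }
  if (!length(out)) {
    return(data.frame(site_id = character(), species_id = character(),
                      first = numeric(), last = numeric(),
                      cams = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$site_id, res$species_id, res$first), ]
}

# Exhaustive replicate-matrix oracle: deduplicate with the loop oracle,
# then scan every (site, replicate, day) cell directly.
bf_replicate_matrix <- function(events, draw, species_id,
                                window_minutes = 30, year_days = 365,
                                start = test_origin) {
  sites <- names(draw$selected_cameras)
  k <- draw$n_replicates
  mat <- matrix(0L, length(sites), k, dimnames = list(sites, NULL))
  ev <- events[events$species_id == species_id, , drop = FALSE]
  for (i in seq_along(sites)) {
    evs <- ev[ev$site_id == sites[i], , drop = FALSE]
    ded <- bf_dedup(evs, window_minutes,
                    camera_subset = draw$selected_cameras[[sites[i]]],
                    start = start)
    det_days <- unique(floor(ded$first / 1440) + 1)
    for (j in seq_len(k)) {
      for (off in ((j - 1) * draw$replicate_length):(j * draw$replicate_length - 1)) {
        day <- ((draw$season_start - 1 + off) %% year_days) + 1
        if (day %in% det_days) mat[i, j] <- 1L
      }
    }
  }
  mat
}

# Exhaustive minimum letter assignment: smallest family of group subsets
# such that no subset contains a significant pair, every non-significant
# pair shares a subset, and every group appears in some subset.
bf_min_letters <- function(groups, sig_pairs) {
  G <- length(groups)
  is_sig <- function(a, b) {
    any((sig_pairs$m_i == a & sig_pairs$m_j == b) |
          (sig_pairs$m_i == b & sig_pairs$m_j == a))
  }
  subsets <- list()
  for (mask in 1:(2^G - 1)) {
    members <- groups[bitwAnd(mask, 2^(seq_len(G) - 1)) > 0]
    ok <- TRUE
    if (length(members) > 1) {
      for (a_i in seq_along(members)) {
        for (b_i in seq_along(members)) {
          if (a_i < b_i && is_sig(members[a_i], members[b_i])) ok <- FALSE
        }
      }
    }
    if (ok) subsets[[length(subsets) + 1]] <- members
  }
  ns_pairs <- list()
  for (a_i in seq_len(G)) {
    for (b_i in seq_len(G)) {
      if (a_i < b_i && !is_sig(groups[a_i], groups[b_i])) {
        ns_pairs[[length(ns_pairs) + 1]] <- c(groups[a_i], groups[b_i])
      }
    }
  }
  covers <- function(cols) {
    for (pr in ns_pairs) {
      if (!any(vapply(cols, function(cl) all(pr %in% cl), TRUE))) return(FALSE)
    }
    all(groups %in% unlist(cols))
  }
  for (r in 1:length(subsets)) {
    combs <- utils::combn(length(subsets), r, simplify = FALSE)
    for (cb in combs) {
      if (covers(subsets[cb])) return(r)
    }
  }
  stop("no valid letter assignment found")
}

letters_consistent <- function(disp, pairs, alpha) {
  for (q in seq_len(nrow(pairs))) {
    share <- any(strsplit(disp[[pairs$m_i[q]]], "")[[1]] %in%
                   strsplit(disp[[pairs$m_j[q]]], "")[[1]])
    if (share != (pairs$p_adj[q] >= alpha)) return(FALSE)
  }
  TRUE
}
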