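#' Define a species detection model for the event simulator
#'
#' A species model specifies how often a species triggers a camera and how
#' that rate varies across cameras and across the year. Rates are raw
#' trigger-event rates, before any deduplication into independent
#' detections.
#'
#' @param species_id Character identifier (e.g. `"deer"`).
#' @param daily_event_rate Expected raw trigger events per camera per day
#'   (>= 0), for an average camera in mid-season.
#' @param camera_heterogeneity_sd Standard deviation of the per-camera
#'   log-rate. Each camera receives a fixed multiplicative log-normal
#'   effect (mean 1 on the natural scale), so some cameras are "hot" and
#'   others rarely record the species — the mechanism by which adding
#'   cameras to an array pays off.
#' @param seasonal_amplitude Amplitude in `[0, 1)` of a sinusoidal
#'   modulation of the daily rate across the year (0 = constant rate).
#' @param within_day_cluster_prob Probability in `[0, 1]` that a trigger
#'   event spawns a companion event 1–29 minutes later, possibly at a
#'   nearby camera in the same cluster. Companion events exercise the
#'   30-minute deduplication rule.
#'
#' @return An object of class `species_model`.
#' @seealso [default_species_models()], [simulate_events()]
#' @export
#' @examples
#' species_model("bobcat", daily_event_rate = 0.03,
#'               camera_heterogeneity_sd = 2.5)
species_model <- function(species_id,
                          daily_event_rate,
                          camera_heterogeneity_sd = 0,
                          seasonal_amplitude = 0,
                          within_day_cluster_prob = 0) {
  if (!is.character(species_id) || length(species_id) != 1L || !nzchar(species_id)) {
    stop_invalid("`species_id` must be a single non-empty string")
  }
  if (!is.numeric(daily_event_rate) || length(daily_event_rate) != 1L ||
      !is.finite(daily_event_rate) || daily_event_rate < 0) {
    stop_invalid("`daily_event_rate` must be a single finite number >= 0")
  }
  if (!is.numeric(camera_heterogeneity_sd) || camera_heterogeneity_sd < 0) {
    stop_invalid("`camera_heterogeneity_sd` must be >= 0")
  }
  if (!is.numeric(seasonal_amplitude) || seasonal_amplitude < 0 ||
      seasonal_amplitude >= 1) {
    stop_invalid("`seasonal_amplitude` must lie in [0, 1)")
  }
  if (!is.numeric(within_day_cluster_prob) || within_day_cluster_prob < 0 ||
      within_day_cluster_prob > 1) {
    stop_invalid("`within_day_cluster_prob` must lie in [0, 1]")
  }
  structure(
    list(
      species_id = species_id,
      daily_event_rate = daily_event_rate,
      camera_heterogeneity_sd = camera_heterogeneity_sd,
      seasonal_amplitude = seasonal_amplitude,
      within_day_cluster_prob = within_day_cluster_prob
    ),
    class = "species_model"
  )
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf(
    "<species_model> %s: rate %.3g events/camera/day, camera sd(log) %.2f, seasonal amp %.2f, cluster prob %.2f\n",
    x$species_id, x$daily_event_rate, x$camera_heterogeneity_sd,
    x$seasonal_amplitude, x$within_day_cluster_prob
  ))
  invisible(x)
}

#' Default four-species community for the synthetic generator
#'
#' Four illustrative species spanning high to low per-camera trigger rates,
#' mirroring a typical temperate-forest camera community: a large frequently
#' detected herbivore (deer), a common mesopredator (raccoon), and two
#' infrequently detected species (opossum, bobcat). The rates are
#' illustrative, not estimates: they are chosen so that frequently detected
#' species approach season detectability quickly even with one camera while
#' infrequently detected species plateau low with a single camera and gain
#' most from multi-camera arrays. Because season detectability saturates
#' roughly as one minus the exponential of the expected number of
#' detections per site and season, the rare species are given well under
#' one trigger event per camera per year, plus camera-to-camera
#' heterogeneity, so single-camera seasons usually record nothing at all.
#'
#' @return A named list of [species_model] objects.
#' @export
#' @examples
#' names(default_species_models())
default_species_models <- function() {
  models <- list(
    species_model("deer", daily_event_rate = 1.0,
                  camera_heterogeneity_sd = 0.5,
                  seasonal_amplitude = 0.3,
                  within_day_cluster_prob = 0.3),
    species_model("raccoon", daily_event_rate = 0.12,
                  camera_heterogeneity_sd = 0.7,
                  seasonal_amplitude = 0.3,
                  within_day_cluster_prob = 0.2),
    species_model("opossum", daily_event_rate = 0.0025,
                  camera_heterogeneity_sd = 1.5,
                  seasonal_amplitude = 0.4,
                  within_day_cluster_prob = 0.1),
    species_model("bobcat", daily_event_rate = 0.0015,
                  camera_heterogeneity_sd = 1.5,
                  seasonal_amplitude = 0.3,
                  within_day_cluster_prob = 0.1)
  )
  setNames(models, vapply(models, `[[`, "", "species_id"))
}
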