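#' Survey detection probability from a replicate detection matrix
#'
#' The survey detection probability is the proportion of site-replicate
#' surveys in which the species was detected at least once, given presence
#' at every site: `p = sum(P) / (N * k)`, where the matrix cell `P` is 1
#' (detection) or 0 (non-detection), `N` is the number of sites (rows) and
#' `k` the number of survey replicates (columns). Presence is assumed
#' (occupancy = 1), so `p` is computed directly from the zeros in the
#' detection/non-detection data rather than estimated jointly with
#' occupancy.
#'
#' @param matrix An `N x k` binary matrix (rows = sites, columns =
#'   replicates), e.g. from [extract_replicate_matrix()].
#'
#' @return An object of class `survey_detection_estimate`: a list with
#'   elements `p`, `N`, `k`, and (when present as matrix attributes)
#'   `m` (array size) and `species_id`.
#' @seealso [season_detection_probability()]
#' @export
#' @examples
#' m <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 2)
#' survey_detection_probability(m)$p  # 4/6
survey_detection_probability <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 1L || ncol(matrix) < 1L) {
    stop_invalid("`matrix` must be a non-empty sites x replicates matrix")
  }
  if (!all(matrix %in% c(0, 1))) {
    stop_invalid("replicate detection matrix cells must be 0 or 1")
  }
  structure(
    list(
      p = sum(matrix) / length(matrix),
      N = nrow(matrix),
      k = ncol(matrix),
      m = attr(matrix, "array_size", exact = TRUE),
      species_id = attr(matrix, "species_id", exact = TRUE)
    ),
    class = "survey_detection_estimate"
  )
}

#' @export
print.survey_detection_estimate <- function(x, ...) {
  cat(sprintf("Survey detection probability p = %.4f  (N = %d sites, k = %d replicates%s)\n",
              x$p, x$N, x$k,
              if (!is.null(x$m)) sprintf(", array size m = %d", x$m) else ""))
  invisible(x)
}

#' Cumulative season detection probability
#'
#' The probability of detecting the species at least once across all `k`
#' independent survey replicates of a season, given per-survey detection
#' probability `p`: `p* = 1 - (1 - p)^k`.
#'
#' Vectorised over `p` and `k` (recycled to a common length).
#'
#' @param p Survey detection probability (or probabilities) in `[0, 1]`.
#' @param k Number of survey replicates (positive integer(s)); replicate
#'   counts are required to be whole numbers — flooring of a season length
#'   by a replicate length happens upstream in the design draw, never here.
#'
#' @return Numeric vector of season detection probabilities.
#' @export
#' @examples
#' season_detection_probability(0.15, 3)  # 0.385875, i.e. 0.39
season_detection_probability <- function(p, k) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_invalid("`p` must be numeric in [0, 1]")
  }
  if (!is.numeric(k) || anyNA(k) || any(k < 1) || any(k != round(k))) {
    stop_invalid("`k` must be integer >= 1 (non-integer replicate counts are rejected, not rounded)")
  }
  1 - (1 - p)^k
}
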