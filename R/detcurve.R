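#' Fit the asymptotic season-detectability curve
#'
#' Fits the saturating curve `p* = A * (1 - exp(-R * S))` to season
#' detection probabilities as a function of season length `S` by bounded
#' nonlinear least squares: `A` in `[0, 1]` is the horizontal asymptote of
#' season detectability and `R > 0` (per day) the rate at which it is
#' approached. The curve passes through the origin by construction (a
#' zero-day season detects nothing).
#'
#' Starting values, unless supplied: `A0` is the largest observed `p*`
#' (clipped into `(0, 1]`) and `R0` comes from log-linearising
#' `1 - p*/A0 = exp(-R S)` at the two smallest season lengths, with
#' `1/mean(S)` as fallback. Optimisation uses bounded Gauss-Newton with an
#' analytic gradient; 95% confidence intervals are profile-likelihood
#' intervals when the profiler succeeds and Wald (t-based) intervals
#' otherwise (`ci_method` records which).
#'
#' @param formula A formula naming the response and the season-length
#'   covariate, e.g. `p_star ~ season_length` (the default when `data` has
#'   those columns).
#' @param data A data.frame containing the variables of `formula`.
#' @param start Optional named list/vector with starting values `A`, `R`.
#' @param bin If `TRUE`, points are first averaged within each distinct
#'   season length and the curve is fitted to the bin means; default
#'   `FALSE` (fit the raw per-iteration points).
#' @param level Confidence level for the reported intervals (default 0.95).
#'
#' @return An object of class `detcurve`: coefficients `A`, `R`, their
#'   covariance and confidence intervals, `rss`, `sigma`, `converged`,
#'   `n_points`, the (possibly binned) data, and the underlying `nls` fit.
#'   If the optimiser fails on degenerate data (for example all `p*` equal
#'   to zero) the object is returned with `converged = FALSE`, `NA`
#'   coefficients and the failure message — never silent defaults — and a
#'   warning is raised.
#' @seealso [invert_detcurve()], [predict.detcurve()], [plot.detcurve()]
#' @export
#' @examples
#' S <- seq(10, 350, by = 20)
#' d <- data.frame(season_length = S,
#'                 p_star = 0.8 * (1 - exp(-0.02 * S)))
#' fit <- fit_detcurve(p_star ~ season_length, d)
#' coef(fit)
fit_detcurve <- function(formula = p_star ~ season_length, data,
                         start = NULL, bin = FALSE, level = 0.95) {
  mf <- model.frame(formula, data = data, na.action = stats::na.omit)
  y <- mf[[1]]
  S <- mf[[2]]
  if (!is.numeric(y) || !is.numeric(S)) stop_invalid("both model variables must be numeric")
  if (any(y < -1e-8 | y > 1 + 1e-8)) stop_invalid("`p*` values must lie in [0, 1]")
  if (any(S < 0)) stop_invalid("season lengths must be >= 0")
  if (bin) {
    agg <- aggregate(y, by = list(S = S), FUN = mean)
    S <- agg$S
    y <- agg$x
  }
  if (length(unique(S)) < 3L) {
    stop_invalid("need at least 3 distinct season lengths to fit the curve")
  }

  if (is.null(start)) {
    A0 <- min(max(max(y), 0.01), 1)
    pos <- which(y > 0 & y < A0 & S > 0)
    R0 <- if (length(pos) >= 1L) {
      two <- pos[order(S[pos])][seq_len(min(2L, length(pos)))]
      mean(-log(1 - y[two] / A0) / S[two])
    } else {
      1 / mean(S[S > 0])
    }
    if (!is.finite(R0) || R0 <= 0) R0 <- 1 / mean(S[S > 0])
    start <- list(A = A0, R = R0)
  } else {
    start <- as.list(start)
  }

  dat <- data.frame(S = S, y = y)
  fit <- if (all(y <= 0)) {
    # a flat-zero response leaves R unidentifiable (any R fits A = 0):
    # signal non-convergence rather than returning a boundary artefact
    simpleError("all p* values are zero; curve parameters are unidentifiable")
  } else tryCatch(
    nls(y ~ detcurve_grad(S, A, R), data = dat, start = start,
        algorithm = "port",
        lower = c(A = 0, R = 1e-10), upper = c(A = 1, R = Inf),
        control = nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) e
  )

  obj <- list(
    call = match.call(),
    formula = formula,
    data = dat,
    n_points = nrow(dat),
    binned = bin,
    level = level,
    species_id = attr(data, "species_id", exact = TRUE),
    array_size = attr(data, "array_size", exact = TRUE)
  )
  if (inherits(fit, "error")) {
    warning("detectability curve fit did not converge: ",
            conditionMessage(fit), call. = FALSE)
    obj <- c(obj, list(
      coefficients = c(A = NA_real_, R = NA_real_),
      vcov = matrix(NA_real_, 2, 2, dimnames = list(c("A", "R"), c("A", "R"))),
      ci = matrix(NA_real_, 2, 2, dimnames = list(c("A", "R"), c("lower", "upper"))),
      rss = NA_real_, sigma = NA_real_, converged = FALSE,
      ci_method = "none", message = conditionMessage(fit), nls = NULL
    ))
    class(obj) <- "detcurve"
    return(obj)
  }

  cf <- coef(fit)
  sm <- summary(fit)
  rss <- sum(residuals(fit)^2)
  dfree <- max(obj$n_points - 2L, 1L)
  converged <- isTRUE(fit$convInfo$isConv)

  ci <- tryCatch(
    suppressWarnings(suppressMessages(confint(fit, level = level))),
    error = function(e) NULL
  )
  ci_method <- "profile"
  if (is.null(ci) || anyNA(ci)) {
    se <- sm$coefficients[, "Std. Error"]
    tq <- qt(1 - (1 - level) / 2, dfree)
    ci <- cbind(lower = cf - tq * se, upper = cf + tq * se)
    ci_method <- "wald"
  }
  ci <- matrix(as.numeric(ci), ncol = 2,
               dimnames = list(c("A", "R"), c("lower", "upper")))

  obj <- c(obj, list(
    coefficients = cf,
    vcov = vcov(fit),
    ci = ci,
    rss = rss,
    sigma = sqrt(rss / dfree),
    converged = converged,
    ci_method = ci_method,
    message = NULL,
    nls = fit
  ))
  class(obj) <- "detcurve"
  obj
}

# Model function with analytic gradient for the bounded optimiser.
detcurve_grad <- deriv(~ A * (1 - exp(-R * S)), c("A", "R"),
                       function(S, A, R) {})

detcurve_eval <- function(S, A, R) A * (1 - exp(-R * S))

#' Invert a fitted detectability curve for design planning
#'
#' Solves `p* = A (1 - exp(-R S))` for the minimum season length `S`
#' reaching a target season detection probability:
#' `S = -log(1 - target / A) / R`. Targets at or above the fitted
#' asymptote `A` are unreachable at any season length and return `NA`
#' with attribute `unreachable = TRUE`.
#'
#' @param fit A converged [fit_detcurve()] object.
#' @param target_p_star Target season detection probability in `(0, 1)`.
#'
#' @return Minimum season length in days (numeric scalar), or `NA_real_`
#'   with attribute `unreachable` when the target exceeds the asymptote.
#' @export
#' @examples
#' S <- seq(10, 350, by = 20)
#' d <- data.frame(season_length = S, p_star = 0.8 * (1 - exp(-0.02 * S)))
#' fit <- fit_detcurve(p_star ~ season_length, d)
#' invert_detcurve(fit, 0.4)  # ~34.66 days
invert_detcurve <- function(fit, target_p_star) {
  if (!inherits(fit, "detcurve")) stop_invalid("`fit` must be a detcurve object")
  if (!isTRUE(fit$converged)) stop_invalid("cannot invert an unconverged curve fit")
  if (!is.numeric(target_p_star) || length(target_p_star) != 1L ||
      target_p_star <= 0 || target_p_star >= 1) {
    stop_invalid("`target_p_star` must lie strictly inside (0, 1)")
  }
  A <- fit$coefficients[["A"]]
  R <- fit$coefficients[["R"]]
  if (target_p_star >= A) {
    return(structure(NA_real_, unreachable = TRUE))
  }
  -log(1 - target_p_star / A) / R
}

#' @export
print.detcurve <- function(x, digits = 4, ...) {
  cat("Season detectability curve  p* = A * (1 - exp(-R * S))\n")
  if (!is.null(x$species_id) || !is.null(x$array_size)) {
    cat(sprintf("  %s%s\n",
                if (!is.null(x$species_id)) paste0("species: ", x$species_id, "  ") else "",
                if (!is.null(x$array_size)) paste0("array size m = ", x$array_size) else ""))
  }
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED", if (!is.null(x$message)) paste0(" (", x$message, ")"), "\n")
    return(invisible(x))
  }
  cat(sprintf("  A (asymptote) = %.*f  [%.*f, %.*f]\n", digits,
              x$coefficients[["A"]], digits, x$ci["A", 1], digits, x$ci["A", 2]))
  cat(sprintf("  R (rate /day) = %.*g  [%.*g, %.*g]\n", digits,
              x$coefficients[["R"]], digits, x$ci["R", 1], digits, x$ci["R", 2]))
  cat(sprintf("  n = %d points, RSS = %.*g, %s%% CI (%s)\n",
              x$n_points, digits, x$rss, format(100 * x$level),
              x$ci_method))
  invisible(x)
}

#' @export
coef.detcurve <- function(object, ...) object$coefficients

#' @export
vcov.detcurve <- function(object, ...) object$vcov

#' @export
confint.detcurve <- function(object, parm = c("A", "R"), level = NULL, ...) {
  if (!is.null(level) && level != object$level) {
    if (!isTRUE(object$converged)) stop_invalid("unconverged fit")
    se <- sqrt(diag(object$vcov))
    tq <- qt(1 - (1 - level) / 2, max(object$n_points - 2L, 1L))
    ci <- cbind(lower = object$coefficients - tq * se,
                upper = object$coefficients + tq * se)
    return(ci[parm, , drop = FALSE])
  }
  object$ci[parm, , drop = FALSE]
}

#' Predict season detectability from a fitted curve
#'
#' @param object A `detcurve` fit.
#' @param newdata Optional data.frame containing the season-length
#'   variable used in the fit (or a column named `S` / `season_length`),
#'   or a numeric vector of season lengths.
#' @param se.fit If `TRUE`, also return pointwise delta-method standard
#'   errors of the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of predicted `p*`, or a list with `fit` and
#'   `se.fit` when `se.fit = TRUE`.
#' @export
predict.detcurve <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (!isTRUE(object$converged)) stop_invalid("cannot predict from an unconverged fit")
  S <- if (is.null(newdata)) {
    object$data$S
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    sv <- all.vars(object$formula)[2]
    cand <- intersect(c(sv, "S", "season_length"), names(newdata))
    if (!length(cand)) stop_invalid("`newdata` lacks a season-length column")
    newdata[[cand[1]]]
  }
  A <- object$coefficients[["A"]]
  R <- object$coefficients[["R"]]
  yhat <- detcurve_eval(S, A, R)
  if (!se.fit) return(yhat)
  g <- cbind(1 - exp(-R * S), A * S * exp(-R * S))
  se <- sqrt(pmax(rowSums((g %*% object$vcov) * g), 0))
  list(fit = yhat, se.fit = se)
}

#' @export
fitted.detcurve <- function(object, ...) predict(object)

#' @export
residuals.detcurve <- function(object, ...) {
  if (!isTRUE(object$converged)) stop_invalid("no residuals for an unconverged fit")
  object$data$y - fitted(object)
}

#' Simulate season-detectability datasets from a fitted curve
#'
#' Draws `nsim` replicate response vectors at the fitted design points,
#' adding Gaussian noise with the fit's residual standard deviation, as in
#' parametric-bootstrap checks of the curve fit.
#'
#' @param object A converged `detcurve` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed (caller's RNG stream is restored).
#' @param ... Unused.
#' @return A data.frame with one column per simulation, `n_points` rows.
#' @export
simulate.detcurve <- function(object, nsim = 1, seed = NULL, ...) {
  if (!isTRUE(object$converged)) stop_invalid("cannot simulate from an unconverged fit")
  mu <- fitted(object)
  with_seed(seed, {
    out <- replicate(nsim, mu + rnorm(length(mu), 0, object$sigma))
    as.data.frame(out)
  })
}

#' @export
summary.detcurve <- function(object, ...) {
  structure(list(fit = object), class = "summary.detcurve")
}

#' @export
print.summary.detcurve <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (isTRUE(f$converged)) {
    se <- sqrt(diag(f$vcov))
    cat("\nCoefficients:\n")
    print(cbind(Estimate = f$coefficients, `Std. Error` = se,
                lower = f$ci[, 1], upper = f$ci[, 2]))
    cat(sprintf("\nResidual sd sigma = %.4g on %d points\n", f$sigma, f$n_points))
    s50 <- invert_detcurve(f, min(0.5, f$coefficients[["A"]] * 0.999))
    if (is.finite(s50)) {
      cat(sprintf("Season length to reach p* = %.2f: %.1f days\n",
                  min(0.5, f$coefficients[["A"]] * 0.999), s50))
    }
  }
  invisible(x)
}

#' Plot a fitted season-detectability curve
#'
#' Draws the observed (season length, p*) points, the fitted curve, and a
#' pointwise delta-method confidence band.
#'
#' @param x A converged `detcurve` fit.
#' @param level Band confidence level (default the fit's level).
#' @param n Number of curve evaluation points.
#' @param ... Passed to `plot()` for the scatter.
#' @return `x`, invisibly.
#' @export
plot.detcurve <- function(x, level = x$level, n = 200, ...) {
  if (!isTRUE(x$converged)) stop_invalid("cannot plot an unconverged fit")
  Sgrid <- seq(0, max(x$data$S), length.out = n)
  pr <- predict(x, Sgrid, se.fit = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  plot(x$data$S, x$data$y, xlab = "Season length (days)",
       ylab = "Season detection probability p*",
       ylim = c(0, 1), col = "grey40", pch = 16, cex = 0.6, ...)
  polygon(c(Sgrid, rev(Sgrid)),
          pmin(pmax(c(pr$fit - z * pr$se.fit, rev(pr$fit + z * pr$se.fit)), 0), 1),
          col = adjustcolor("grey60", 0.4), border = NA)
  lines(Sgrid, pr$fit, lwd = 2)
  invisible(x)
}
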