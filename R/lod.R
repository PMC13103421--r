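## Probit-regression limit of detection from a dilution series of binary
## detection outcomes.
##
## The detection probability is modelled as Phi(a + b * x), where x is the
## fusion-positive DNA fraction (percent, linear scale by default) and Phi
## the standard normal CDF; the LoD at confidence c is the fraction where
## the fitted probability reaches c: x = (Phi^-1(c) - a) / b.

#' Fit a probit limit-of-detection model to dilution observations
#'
#' Maximum-likelihood binomial regression with probit link of
#' `detected / n` on fraction.  Zero-fraction negative-control rows are
#' included by default; on the log10 scale they cannot enter the fit and
#' are dropped with a message.
#'
#' @param data `data.frame` with columns `fraction` (percent
#'   fusion-positive DNA), `n` (replicates) and `detected` (successes,
#'   `0 <= detected <= n`).
#' @param confidence Target detection probability for the reported LoD
#'   (default 0.95).
#' @param scale `"linear"` (default) or `"log10"` fraction scale.
#' @param include_zero Keep zero-fraction negative-control rows
#'   (default `TRUE`; ignored, with a message, on the log scale).
#' @return Object of class `"probit_lod"` with components `coefficients`
#'   (`intercept`, `slope`), `lod`, `confidence`, `scale`, `converged`,
#'   `separation`, `identifiable`, the underlying `glm` fit and the data
#'   used.  Standard methods are available: [coef()], [predict()],
#'   [plot()], [residuals()], [summary()].
#' @examples
#' d <- data.frame(fraction = c(0, 2, 5, 10, 20, 50, 100),
#'                 n = 3, detected = c(0, 1, 2, 3, 3, 3, 3))
#' fit <- probit_lod(d, include_zero = FALSE)
#' fit$lod
#' @export
probit_lod <- function(data, confidence = 0.95,
                       scale = c("linear", "log10"), include_zero = TRUE) {
  scale <- match.arg(scale)
  stop_if_not_prob(confidence, "confidence")
  req <- c("fraction", "n", "detected")
  if (!all(req %in% names(data)))
    stop("'data' needs columns fraction, n, detected", call. = FALSE)
  if (any(data$detected > data$n) || any(data$detected < 0))
    stop("'detected' must lie in [0, n]", call. = FALSE)
  if (any(data$fraction < 0))
    stop("fractions must be non-negative", call. = FALSE)
  d <- data
  if (scale == "log10" || !include_zero) {
    drop <- d$fraction == 0
    if (any(drop) && scale == "log10" && include_zero)
      message("zero-fraction rows cannot enter a log-scale fit; dropped")
    d <- d[!drop, , drop = FALSE]
  }
  if (length(unique(d$fraction)) < 2L)
    stop("need at least two distinct fractions to fit", call. = FALSE)
  if (all(d$detected == 0) || all(d$detected == d$n))
    stop("all-identical outcomes: detection curve is unidentifiable",
         call. = FALSE)
  d$x <- if (scale == "log10") log10(d$fraction) else d$fraction

  warned <- character(0)
  fit <- withCallingHandlers(
    stats::glm(cbind(detected, n - detected) ~ x,
               family = stats::binomial(link = "probit"), data = d),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  separation <- any(grepl("fitted probabilities numerically 0 or 1",
                          warned))
  converged <- fit$converged && !any(grepl("did not converge", warned))
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  identifiable <- is.finite(b) && b > 0
  lod_x <- if (identifiable) (stats::qnorm(confidence) - a) / b else NA_real_
  lod <- if (scale == "log10") 10^lod_x else lod_x
  if (identifiable && !is.na(lod) && lod < 0) {
    identifiable <- FALSE
  }
  structure(list(coefficients = c(intercept = a, slope = b),
                 lod = if (identifiable) lod else NA_real_,
                 confidence = confidence, scale = scale,
                 include_zero = include_zero && scale == "linear",
                 converged = converged, separation = separation,
                 identifiable = identifiable,
                 glm = fit, data = d), class = "probit_lod")
}

#' LoD at a different confidence level from a fitted probit model
#'
#' @param fit A `"probit_lod"`.
#' @param confidence Target detection probability.
#' @return The fraction at which the fitted detection probability equals
#'   `confidence`, on the original (percent) scale.
#' @examples
#' # a = -2, b = 0.4: LoD at 95% = (1.6449 + 2) / 0.4 = 9.11
#' @export
lod_at <- function(fit, confidence = 0.95) {
  stopifnot(inherits(fit, "probit_lod"))
  stop_if_not_prob(confidence, "confidence")
  b <- fit$coefficients[["slope"]]
  if (!is.finite(b) || b <= 0)
    stop("non-identifiable LoD: fitted slope is not positive", call. = FALSE)
  x <- (stats::qnorm(confidence) - fit$coefficients[["intercept"]]) / b
  if (fit$scale == "log10") 10^x else x
}

#' @export
coef.probit_lod <- function(object, ...) object$coefficients

#' @export
vcov.probit_lod <- function(object, ...) stats::vcov(object$glm)

#' Predicted detection probability at given fractions
#' @param object A `"probit_lod"`.
#' @param fraction Numeric vector of fractions (percent).
#' @param ... Unused.
#' @export
predict.probit_lod <- function(object, fraction, ...) {
  if (missing(fraction)) fraction <- object$data$fraction
  x <- if (object$scale == "log10") log10(fraction) else fraction
  stats::pnorm(object$coefficients[["intercept"]] +
                 object$coefficients[["slope"]] * x)
}

#' @export
residuals.probit_lod <- function(object, ...) stats::residuals(object$glm, ...)

#' @export
print.probit_lod <- function(x, ...) {
  cat(sprintf("Probit limit-of-detection fit (%s fraction scale%s)\n",
              x$scale,
              if (x$include_zero) ", zero-fraction controls included" else ""))
  cat(sprintf("  intercept %.4f, slope %.4f%s\n",
              x$coefficients[["intercept"]], x$coefficients[["slope"]],
              if (!x$converged) "  [not converged]"
              else if (x$separation) "  [quasi-separation]" else ""))
  if (x$identifiable)
    cat(sprintf("  LoD at %.0f%% detection probability: %.2f%%\n",
                100 * x$confidence, x$lod))
  else cat("  LoD not identifiable (non-positive slope)\n")
  invisible(x)
}

#' @export
summary.probit_lod <- function(object, ...) {
  print(object)
  cat("\nGLM coefficients:\n")
  stats::printCoefmat(stats::coef(summary(object$glm)))
  if (object$identifiable && object$scale == "linear") {
    ## delta-method standard error of the LoD
    a <- object$coefficients[["intercept"]]
    b <- object$coefficients[["slope"]]
    z <- stats::qnorm(object$confidence)
    gr <- c(-1 / b, -(z - a) / b^2)
    se <- sqrt(drop(t(gr) %*% stats::vcov(object$glm) %*% gr))
    cat(sprintf("\nLoD %.2f%% (delta-method s.e. %.2f)\n", object$lod, se))
  }
  invisible(object)
}

#' @export
plot.probit_lod <- function(x, ...) {
  d <- x$data
  xs <- seq(min(d$fraction), max(d$fraction), length.out = 200)
  graphics::plot(d$fraction, d$detected / d$n, pch = 16,
                 xlab = "fusion-positive fraction (%)",
                 ylab = "detection probability",
                 ylim = c(0, 1), ...)
  graphics::lines(xs, predict(x, xs))
  if (x$identifiable) {
    graphics::abline(v = x$lod, lty = 2)
    graphics::abline(h = x$confidence, lty = 3)
  }
  invisible(x)
}

#' LoD under all exposed fit configurations
#'
#' Fits the probit model on the linear and log10 fraction scales, each
#' with and without the zero-fraction negative-control rows, and reports
#' the LoD of every configuration (on the log scale the zero rows can
#' never enter, so those two configurations coincide).
#'
#' @inheritParams probit_lod
#' @return `data.frame` with columns `scale`, `include_zero`, `lod`,
#'   `converged`, `separation`.
#' @export
lod_configurations <- function(data, confidence = 0.95) {
  grid <- expand.grid(scale = c("linear", "log10"),
                      include_zero = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- suppressMessages(
      probit_lod(data, confidence, grid$scale[i], grid$include_zero[i]))
    data.frame(scale = grid$scale[i], include_zero = grid$include_zero[i],
               lod = fit$lod, converged = fit$converged,
               separation = fit$separation, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate dilution-series detection outcomes from a known probit curve
#'
#' Validation harness for [probit_lod()]: draws binomial detection counts
#' at probability `pnorm(a + b * x)` for each fraction.
#'
#' @param a,b Generating intercept and slope (linear fraction scale).
#' @param fractions Numeric vector of fractions (percent).
#' @param n Replicates per fraction.
#' @param seed Integer seed.
#' @return `data.frame` with `fraction`, `n`, `detected`.
#' @export
simulate_detection_curve <- function(a, b, fractions, n, seed = 1L) {
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  withr::with_seed(seed, {
    p <- stats::pnorm(a + b * fractions)
    data.frame(fraction = fractions, n = n,
               detected = stats::rbinom(length(fractions), n, p))
  })
}
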