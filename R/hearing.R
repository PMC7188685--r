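#' Scale and log-transform an inner-ear duct length
#'
#' The pars inferior (or endocochlear duct) length is scaled to the
#' basicranium length to remove skull size, then log10-transformed:
#' x = log10(pars_inferior / basicranium). The ratio is dimensionless, so
#' doubling both measurements leaves x unchanged. (Base 10 is the
#' convention of the extant hearing dataset this regression follows; a
#' natural-log variant is available via `base`.)
#'
#' @param pars_inferior_length duct length, mm (> 0).
#' @param basicranium_length basicranium length, mm (> 0).
#' @param base logarithm base (default 10).
#' @return the scaled log length x.
#' @export
scale_and_transform <- function(pars_inferior_length, basicranium_length,
                                base = 10) {
  if (any(pars_inferior_length <= 0) || any(basicranium_length <= 0))
    stop("scale_and_transform: lengths must be positive")
  log(pars_inferior_length / basicranium_length, base = base)
}

#' Fit an OLS hearing model
#'
#' Ordinary least squares of a hearing capability (mean best frequency or
#' best range, Hz) on scaled log duct length. Rows with a missing
#' predictor or response are dropped before fitting (species lacking duct
#' length measurements are excluded).
#'
#' @param x scaled log duct lengths.
#' @param y hearing capability values, Hz.
#' @param response `"mean_best_frequency"` or `"best_range"`.
#' @return object of class `hearing_model`: `slope` (Hz per log unit),
#'   `intercept` (Hz), `r_squared`, `p_value` (slope F-test), `n`.
#' @export
fit_hearing_model <- function(x, y,
                              response = c("mean_best_frequency", "best_range")) {
  response <- match.arg(response)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fit_hearing_model: need at least 3 complete rows")
  if (stats::sd(x) == 0) stop("fit_hearing_model: constant predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  hearing_model(slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                response = response,
                r_squared = sm$r.squared,
                p_value = unname(sm$coefficients[2L, 4L]),
                n = length(x))
}

#' Construct a hearing model directly from coefficients
#'
#' Used to evaluate a published regression equation without refitting.
#'
#' @param slope,intercept regression coefficients (Hz per log unit, Hz).
#' @param response which capability the model predicts.
#' @param r_squared,p_value,n optional fit statistics.
#' @return object of class `hearing_model`.
#' @export
hearing_model <- function(slope, intercept,
                          response = c("mean_best_frequency", "best_range"),
                          r_squared = NA_real_, p_value = NA_real_,
                          n = NA_integer_) {
  response <- match.arg(response)
  structure(list(slope = slope, intercept = intercept, response = response,
                 r_squared = r_squared, p_value = p_value, n = n),
            class = "hearing_model")
}

#' @export
print.hearing_model <- function(x, ...) {
  cat(sprintf("<hearing_model> %s: y = %.4gx + %.4g", x$response,
              x$slope, x$intercept))
  if (!is.na(x$r_squared))
    cat(sprintf(" (r^2 = %.4f, p = %.3g, n = %d)", x$r_squared, x$p_value, x$n))
  cat("\n")
  invisible(x)
}

#' Predict hearing capability at a scaled log duct length
#'
#' @param object a `hearing_model`.
#' @param x scaled log duct length(s).
#' @param ... unused.
#' @return predicted value(s), Hz.
#' @export
predict.hearing_model <- function(object, x, ...) {
  object$slope * x + object$intercept
}

#' Summarize a best-frequency / best-range pair as a hearing interval
#'
#' The overall best hearing range is the symmetric interval of the given
#' width centered on the best frequency.
#'
#' @param best_frequency predicted mean best hearing frequency, Hz.
#' @param best_range_width predicted best hearing range width, Hz (>= 0).
#' @return object of class `hearing_prediction`: `best_frequency`,
#'   `best_range_width`, `range_low`, `range_high` (Hz).
#' @export
summarize_hearing <- function(best_frequency, best_range_width) {
  if (best_range_width < 0)
    stop("summarize_hearing: negative range width")
  structure(list(best_frequency = best_frequency,
                 best_range_width = best_range_width,
                 range_low = best_frequency - best_range_width / 2,
                 range_high = best_frequency + best_range_width / 2),
            class = "hearing_prediction")
}

#' @export
print.hearing_prediction <- function(x, ...) {
  cat(sprintf("best hearing frequency %.1f Hz, range %.1f Hz (%.1f-%.1f Hz)\n",
              x$best_frequency, x$best_range_width, x$range_low, x$range_high))
  invisible(x)
}
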