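#' Development rates from stage durations
#'
#' A stage completed in d days proceeds at rate 1/d per day; applied to
#' per-temperature mean durations this gives the points of the classic
#' rate-versus-temperature plot.
#'
#' @param durations named numeric vector of mean stage durations (days);
#'   names are temperature labels
#' @return named numeric vector of rates (1/day)
#' @examples
#' development_rates(c("21" = 20.79, "33" = 8.47))
#' @export
development_rates <- function(durations) {
  stopifnot(is.numeric(durations), all(durations > 0))
  1 / durations
}

#' Fit development rate against log temperature
#'
#' Ordinary least squares of rate on log(temperature):
#' \code{rate = a + b log(T)}. The default log base is natural; the
#' coefficient of determination is invariant to the base and the slope
#' scales by \code{ln(base)}, so the base only matters for quoting
#' coefficients.
#'
#' @param temperature numeric vector of temperatures (same unit
#'   throughout, conventionally degrees C)
#' @param rate numeric vector of development rates (1/day)
#' @param base log base (default \code{exp(1)}; use 10 for common log)
#' @return a \code{thermal_fit}: list with \code{a} (intercept), \code{b}
#'   (slope per log-unit), \code{r_squared}, \code{base}, \code{points}
#'   (data frame temperature, rate, log_temp, fitted, residual) and the
#'   underlying \code{lm} fit
#' @export
fit_log_model <- function(temperature, rate, base = exp(1)) {
  stopifnot(length(temperature) == length(rate))
  if (length(unique(temperature)) < 3L)
    stop("need at least 3 distinct temperatures")
  lt <- log(temperature, base = base)
  if (stats::var(lt) == 0) stop("no variance in log temperature")
  fit <- stats::lm(rate ~ lt)
  points <- data.frame(
    temperature = temperature, rate = rate, log_temp = lt,
    fitted = unname(stats::fitted(fit)),
    residual = unname(stats::residuals(fit))
  )
  # direct R^2 avoids summary.lm's perfect-fit warning on collinear input
  r2 <- 1 - sum(points$residual^2) / sum((rate - mean(rate))^2)
  structure(
    list(a = unname(stats::coef(fit)[1L]), b = unname(stats::coef(fit)[2L]),
         r_squared = r2, base = base, points = points, fit = fit),
    class = "thermal_fit"
  )
}

#' @export
print.thermal_fit <- function(x, ...) {
  basetxt <- if (isTRUE(all.equal(x$base, exp(1)))) "ln"
             else sprintf("log%g", x$base)
  cat(sprintf("rate = %.4g + %.4g %s(T),  R^2 = %.4f  (n = %d)\n",
              x$a, x$b, basetxt, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Predicted development rate at new temperatures
#'
#' @param object a \code{thermal_fit}
#' @param temperature temperatures to predict at
#' @param ... unused
#' @return numeric vector of fitted rates (1/day)
#' @export
predict.thermal_fit <- function(object, temperature, ...) {
  object$a + object$b * log(temperature, base = object$base)
}
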