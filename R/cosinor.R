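#' Single-component cosinor model
#'
#' Fits the fixed-period sinusoid
#' \deqn{y = M + A\cos(\omega (t - \phi)) + \epsilon, \quad \omega = 2\pi/period}
#' by its linearisation \eqn{y = M + \beta_1\cos(\omega t) +
#' \beta_2\sin(\omega t)}, solved by QR least squares. The amplitude is
#' \eqn{A = \sqrt{\beta_1^2+\beta_2^2}} and the acrophase — the time of day
#' at which the fitted rhythm peaks — is
#' \eqn{\phi = \mathrm{atan2}(\beta_2, \beta_1)/\omega}, wrapped onto
#' \[0, 24). The acrophase confidence interval comes from the delta method
#' on \eqn{(\beta_1, \beta_2)} with t critical values; the zero-amplitude
#' test is the 2-df F test of \eqn{\beta_1 = \beta_2 = 0}.
#'
#' @param t time of day (or internal time) in fractional hours.
#' @param y numeric response (e.g. relative response time in percent).
#' @param period rhythm period in hours (default 24, fixed).
#' @param conf_level confidence level for the acrophase interval.
#' @return an object of class `"cosinor"`: list with `mesor`, `amplitude`,
#'   `acrophase` (hours in \[0, 24)), `acrophase_ci`, `amplitude_p`
#'   (zero-amplitude F-test p-value), `period`, `residual_sd`,
#'   `coefficients` (`mesor`, `beta_cos`, `beta_sin`), `fitted.values`,
#'   `residuals`, `n`, `df.residual`, `call`.
#' @examples
#' t <- rep(0:23, 3)
#' y <- 5 + 2 * cos(2 * pi * (t - 10) / 24) + rnorm(length(t), sd = 0.3)
#' fit <- cosinor(t, y)
#' summary(fit)
#' format_acrophase(fit)
#' @export
cosinor <- function(t, y, period = 24, conf_level = 0.95) {
  cl <- match.call()
  ok <- !is.na(t) & !is.na(y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  if (length(unique(round(t, 10))) < 4L) {
    stop("rhythm unidentifiable: need at least 4 distinct time points")
  }
  w <- 2 * pi / period
  X <- cbind(mesor = 1, beta_cos = cos(w * t), beta_sin = sin(w * t))
  qrx <- qr(X)
  if (qrx$rank < 3L) stop("rhythm unidentifiable: design is rank deficient")
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  dfres <- n - 3L
  s2 <- rss / dfres
  amplitude <- sqrt(beta[["beta_cos"]]^2 + beta[["beta_sin"]]^2)
  acrophase <- wrap24(atan2(beta[["beta_sin"]], beta[["beta_cos"]]) / w)
  # delta method on (beta_cos, beta_sin) for the acrophase
  xtx_inv <- chol2inv(qr.R(qrx))
  vc <- s2 * xtx_inv
  ci <- c(NA_real_, NA_real_)
  se_phi <- NA_real_
  if (amplitude > 0 && dfres > 0) {
    g <- c(-beta[["beta_sin"]], beta[["beta_cos"]]) / (amplitude^2 * w)
    se_phi <- sqrt(drop(t(g) %*% vc[2:3, 2:3] %*% g))
    q <- stats::qt(1 - (1 - conf_level) / 2, dfres)
    ci <- c(acrophase - q * se_phi, acrophase + q * se_phi)
  }
  rss0 <- sum((y - mean(y))^2)
  fstat <- ((rss0 - rss) / 2) / s2
  amplitude_p <- if (s2 == 0) {
    if (amplitude > 0) 0 else 1
  } else stats::pf(fstat, 2, dfres, lower.tail = FALSE)
  structure(list(mesor = beta[["mesor"]], amplitude = amplitude,
                 acrophase = acrophase, acrophase_ci = ci,
                 acrophase_se = se_phi, amplitude_p = amplitude_p,
                 period = period, residual_sd = sqrt(s2),
                 coefficients = beta, vcov = vc,
                 fitted.values = fitted, residuals = resid,
                 t = t, n = n, df.residual = dfres,
                 conf_level = conf_level, call = cl),
            class = "cosinor")
}

#' Format an acrophase with its confidence interval
#'
#' Renders the fitted acrophase as `"hh:mm (hh:mm to hh:mm)"`, flooring
#' fractional hours to the minute (an acrophase of 10.4 h becomes
#' `"10:24"`).
#'
#' @param fit a `"cosinor"` fit.
#' @return a single character string.
#' @export
format_acrophase <- function(fit) {
  stopifnot(inherits(fit, "cosinor"))
  if (anyNA(fit$acrophase_ci)) return(format_hhmm(fit$acrophase))
  sprintf("%s (%s to %s)", format_hhmm(fit$acrophase),
          format_hhmm(fit$acrophase_ci[1]), format_hhmm(fit$acrophase_ci[2]))
}

#' @export
print.cosinor <- function(x, digits = 4, ...) {
  cat(sprintf("Cosinor fit (period %g h)\n", x$period))
  cat(sprintf("  mesor     %.*g\n", digits, x$mesor))
  cat(sprintf("  amplitude %.*g  (zero-amplitude p = %s)\n", digits,
              x$amplitude, format.pval(x$amplitude_p, digits = 3)))
  cat(sprintf("  acrophase %s\n", format_acrophase(x)))
  cat(sprintf("  n = %d, residual SD = %.*g\n", x$n, digits, x$residual_sd))
  invisible(x)
}

#' @export
summary.cosinor <- function(object, ...) {
  data.frame(mesor = object$mesor, amplitude = object$amplitude,
             acrophase = object$acrophase,
             acro_ci_low = object$acrophase_ci[1],
             acro_ci_high = object$acrophase_ci[2],
             amplitude_p = object$amplitude_p,
             residual_sd = object$residual_sd, n = object$n)
}

#' @export
coef.cosinor <- function(object, ...) object$coefficients

#' @export
fitted.cosinor <- function(object, ...) object$fitted.values

#' @export
residuals.cosinor <- function(object, ...) object$residuals

#' Predict from a cosinor fit
#' @param object a `"cosinor"` fit.
#' @param newdata optional numeric vector of times (hours); defaults to the
#'   fitting times.
#' @param ... unused.
#' @return fitted rhythm values.
#' @export
predict.cosinor <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t else newdata
  w <- 2 * pi / object$period
  object$mesor + object$amplitude * cos(w * (t - object$acrophase))
}

#' Plot a cosinor fit
#' @param x a `"cosinor"` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cosinor <- function(x, ...) {
  graphics::plot(x$t, x$fitted.values + x$residuals,
                 xlab = "time (h)", ylab = "response", ...)
  tt <- seq(0, x$period, length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  graphics::abline(v = x$acrophase, lty = 2, col = "grey40")
  invisible(x)
}
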