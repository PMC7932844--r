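#' Repeated-measures correlation
#'
#' Estimates the common within-subject association between two repeatedly
#' measured variables by the ANCOVA formulation: `y` is modelled with one
#' intercept per subject and a single shared slope on `x`. Writing
#' \eqn{\tilde x, \tilde y} for the within-subject centered variables, the
#' common slope is \eqn{b = \sum \tilde x \tilde y / \sum \tilde x^2}, the
#' effect size is
#' \deqn{r_{rm} = \mathrm{sign}(b)\sqrt{SS_{slope}/(SS_{slope}+SS_{error})}}
#' with \eqn{SS_{slope} = b^2 \sum \tilde x^2}, the degrees of freedom are
#' \eqn{N - k - 1} for `N` observations on `k` subjects, and the p-value
#' comes from the F statistic with `(1, df)` degrees of freedom. The
#' confidence interval uses the Fisher z transform with standard error
#' \eqn{1/\sqrt{df - 1}}.
#'
#' Missing pairs are removed listwise; subjects with fewer than two
#' complete pairs are dropped. Subjects whose `x` is constant contribute
#' nothing to the slope (their centered `x` is zero) but keep their `y`
#' deviations in the error term, exactly as the explicit dummy-coded
#' regression would. Aggregating repeated measures across subjects with a
#' plain Pearson correlation can reverse the within-subject association
#' (Simpson's paradox); the ANCOVA formulation is immune to per-subject
#' constant shifts of either variable.
#'
#' @param x,y numeric vectors of paired measurements.
#' @param subject subject identifier vector, same length.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return an object of class `"rmcorr"`: a list with elements `r` (the
#'   repeated-measures correlation), `df`, `p.value`, `conf.int`, `slope`,
#'   `n_obs`, `n_subjects`, `conf_level` and `call`.
#' @seealso [rmcorr_oracle()] for the independent design-matrix route.
#' @examples
#' set.seed(1)
#' subj <- rep(1:5, each = 8)
#' x <- rnorm(40)
#' y <- 0.5 * x + rnorm(5)[subj] + rnorm(40)
#' fit <- rmcorr(x, y, subj)
#' print(fit)
#' confint(fit)
#' @export
rmcorr <- function(x, y, subject, conf_level = 0.95) {
  cl <- match.call()
  d <- rmcorr_prepare(x, y, subject)
  xc <- d$x - stats::ave(d$x, d$subject)
  yc <- d$y - stats::ave(d$y, d$subject)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("no within-subject variation in x")
  slope <- sum(xc * yc) / sxx
  ss_slope <- slope^2 * sxx
  ss_error <- sum((yc - slope * xc)^2)
  rmcorr_result(slope, ss_slope, ss_error,
                n_obs = nrow(d), n_subjects = length(unique(d$subject)),
                conf_level = conf_level, call = cl)
}

# listwise deletion + minimum-pairs rule shared by both routes
rmcorr_prepare <- function(x, y, subject) {
  ok <- !is.na(x) & !is.na(y) & !is.na(subject)
  d <- data.frame(x = x[ok], y = y[ok], subject = as.character(subject[ok]),
                  stringsAsFactors = FALSE)
  counts <- table(d$subject)
  d <- d[d$subject %in% names(counts)[counts >= 2], , drop = FALSE]
  if (length(unique(d$subject)) < 2L) {
    if (length(unique(d$subject)) == 1L) return(d)
    stop("need at least one subject with >= 2 complete pairs")
  }
  d
}

rmcorr_result <- function(slope, ss_slope, ss_error, n_obs, n_subjects,
                          conf_level, call) {
  df <- n_obs - n_subjects - 1L
  if (df < 1L) stop("not enough observations for the repeated-measures correlation")
  r <- sign(slope) * sqrt(ss_slope / (ss_slope + ss_error))
  f <- ss_slope / (ss_error / df)
  p <- stats::pf(f, 1, df, lower.tail = FALSE)
  ci <- if (df > 1L) {
    z <- atanh(r)
    se <- 1 / sqrt(df - 1)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    tanh(c(z - q * se, z + q * se))
  } else c(NA_real_, NA_real_)
  structure(list(r = r, df = df, p.value = p, conf.int = ci, slope = slope,
                 statistic = f, n_obs = n_obs, n_subjects = n_subjects,
                 conf_level = conf_level, call = call),
            class = "rmcorr")
}

#' Repeated-measures correlation by explicit design matrix
#'
#' Independent verification route for [rmcorr()]: fits
#' `y ~ subject indicators + x` by ordinary least squares on the explicit
#' dummy-coded design matrix and derives the same quantities from the
#' sum-of-squares decomposition against the intercepts-only model. Meant
#' for small inputs and cross-checks.
#'
#' @inheritParams rmcorr
#' @return an object of class `"rmcorr"` (see [rmcorr()]).
#' @export
rmcorr_oracle <- function(x, y, subject, conf_level = 0.95) {
  cl <- match.call()
  d <- rmcorr_prepare(x, y, subject)
  subj <- factor(d$subject)
  dummies <- stats::model.matrix(~ subj - 1)
  full <- stats::lm.fit(cbind(dummies, x = d$x), d$y)
  reduced <- stats::lm.fit(dummies, d$y)
  ss_error <- sum(full$residuals^2)
  ss_slope <- sum(reduced$residuals^2) - ss_error
  slope <- full$coefficients[["x"]]
  if (is.na(slope)) stop("no within-subject variation in x")
  rmcorr_result(slope, max(ss_slope, 0), ss_error,
                n_obs = nrow(d), n_subjects = nlevels(subj),
                conf_level = conf_level, call = cl)
}

#' @export
print.rmcorr <- function(x, digits = 4, ...) {
  cat("Repeated-measures correlation\n")
  cat(sprintf("  r_rm = %.*f, df = %d, p = %s\n", digits, x$r, x$df,
              format.pval(x$p.value, digits = 3)))
  cat(sprintf("  %d%% CI: (%.*f, %.*f)   slope = %.*g\n",
              round(100 * x$conf_level), digits, x$conf.int[1],
              digits, x$conf.int[2], digits, x$slope))
  cat(sprintf("  %d observations, %d subjects\n", x$n_obs, x$n_subjects))
  invisible(x)
}

#' @export
summary.rmcorr <- function(object, ...) {
  out <- data.frame(r_rm = object$r, df = object$df,
                    statistic = object$statistic, p.value = object$p.value,
                    ci_low = object$conf.int[1], ci_high = object$conf.int[2],
                    slope = object$slope, n_obs = object$n_obs,
                    n_subjects = object$n_subjects)
  rownames(out) <- NULL
  out
}

#' @export
coef.rmcorr <- function(object, ...) {
  c(slope = object$slope)
}

#' @export
confint.rmcorr <- function(object, parm, level, ...) {
  out <- matrix(object$conf.int, nrow = 1,
                dimnames = list("r_rm",
                                paste0(100 * c((1 - object$conf_level) / 2,
                                               1 - (1 - object$conf_level) / 2),
                                       " %")))
  out
}
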