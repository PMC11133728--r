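# Exposure-response statistics of the bioassay: the saturating dose-response
# curve y = m x / (h + x) + b, pink-cell appearance rates, backward sliding
# window (BSW) averaging of daily particulate-matter series, and
# origin-constrained linear regression with Pearson correlation.

#' Evaluate the saturating dose-response curve
#'
#' y = m x / (h + x) + b: `m` is the saturation level approached as the dose
#' grows, `h` the half-saturation dose at which the response reaches
#' m/2 + b, and `b` a small baseline.
#'
#' @param x dose (mg/kg), non-negative.
#' @param m saturation level.
#' @param h half-saturation dose, strictly positive.
#' @param b baseline.
#' @return The response at each dose.
#' @export
eval_saturating <- function(x, m, h, b = 0) {
  if (h <= 0) stop("h must be positive")
  if (any(x < 0)) stop("doses must be non-negative")
  m * x / (h + x) + b
}

#' Fit the saturating dose-response curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of y = m x / (h + x) + b with m, h constrained
#' non-negative. By default responses are aggregated to the per-dose median
#' before fitting, matching how the dose-response relation is summarized per
#' sample; `aggregate = "none"` fits every replicate. Doses whose responses
#' are all missing (e.g. the lethal top dose with no surviving
#' inflorescences) are dropped and recorded in the result.
#'
#' @param doses numeric doses (mg/kg).
#' @param responses numeric responses, same length.
#' @param aggregate `"median"` (default) or `"none"`.
#' @param start optional named list with starting values `m`, `h`, `b`. By
#'   default the half-saturation dose is profiled over a logarithmic grid
#'   (the curve is linear in `m` and `b` given `h`), and the grid point with
#'   the smallest residual sum of squares seeds the optimizer; this avoids
#'   the degenerate local optimum at `h -> 0`.
#' @return A `dose_response_fit` list with `m`, `h`, `b`, standard errors
#'   `se_m`, `se_h`, `se_b`, `residual_sd`, `converged`, the dropped doses,
#'   and the fitted-curve `equation` string.
#' @export
fit_dose_response <- function(doses, responses, aggregate = c("median", "none"),
                              start = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(doses) == length(responses))
  keep <- !is.na(responses)
  dropped <- sort(unique(doses[!doses %in% doses[keep]]))
  doses <- doses[keep]
  responses <- responses[keep]
  if (any(doses < 0)) stop("doses must be non-negative")
  if (aggregate == "median") {
    med <- tapply(responses, doses, stats::median)
    doses <- as.numeric(names(med))
    responses <- as.numeric(med)
  }
  if (length(unique(doses)) < 3) {
    stop("at least 3 distinct doses are required to fit the 3-parameter curve")
  }
  x <- doses
  y <- responses
  if (is.null(start)) start <- profile_start(x, y)
  fit <- minpack.lm::nls.lm(
    par = start, lower = c(0, 1e-9, -Inf),
    fn = function(p) y - (p$m * x / (p$h + x) + p$b),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4) {
    stop("dose-response fit did not converge: ", fit$message)
  }
  p <- fit$par
  dof <- max(length(y) - 3, 1)
  sigma <- sqrt(fit$deviance / dof)
  ses <- tryCatch(sigma * sqrt(diag(chol2inv(chol(fit$hessian)))),
                  error = function(e) rep(NA_real_, 3))
  structure(list(
    m = p$m, h = p$h, b = p$b,
    se_m = ses[1], se_h = ses[2], se_b = ses[3],
    residual_sd = sigma,
    converged = TRUE,
    dropped_doses = dropped,
    n = length(y),
    equation = sprintf("y = %.2fx/(%.2f+x)+%.2f", p$m, p$h, p$b)
  ), class = "dose_response_fit")
}

# Starting values by profiling h: for each h on a log grid over the positive
# dose range, (m, b) solve a 2-parameter linear least-squares problem; the
# grid minimum seeds the full nonlinear fit.
profile_start <- function(x, y) {
  pos <- x[x > 0]
  grid <- exp(seq(log(min(pos) / 10), log(max(pos) * 10), length.out = 60))
  best <- NULL
  for (h in grid) {
    z <- x / (h + x)
    cf <- stats::lm.fit(cbind(z, 1), y)$coefficients
    if (cf[1] < 0) next
    rss <- sum((y - cf[1] * z - cf[2])^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(m = max(cf[[1]], 1e-6), h = h, b = cf[[2]], rss = rss)
    }
  }
  if (is.null(best)) {
    best <- list(m = max(max(y) - min(y), 1e-6), h = stats::median(pos),
                 b = min(y))
  }
  list(m = best$m, h = best$h, b = best$b)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> ", x$equation, "\n", sep = "")
  cat(sprintf("  m = %.4f (SE %.4f), h = %.4f (SE %.4f), b = %.4f (SE %.4f)\n",
              x$m, x$se_m, x$h, x$se_h, x$b, x$se_b))
  if (length(x$dropped_doses)) {
    cat("  dropped doses with no observations:",
        paste(x$dropped_doses, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pink-cell appearance rate per 1000 stamen hairs
#'
#' @param events number of pink-cell events observed.
#' @param hairs number of stamen hairs scored, positive.
#' @return `1000 * events / hairs`.
#' @export
pink_appearance_rate <- function(events, hairs) {
  if (any(hairs <= 0)) stop("hairs must be positive")
  if (any(events < 0)) stop("events must be non-negative")
  1000 * events / hairs
}

#' An exposure record: dated daily PM series plus a sampling date
#'
#' @param dates `Date` vector, strictly increasing.
#' @param values daily PM concentrations (ug/m3), non-negative.
#' @param sampling_date `Date` of inflorescence sampling.
#' @param pollutant `"PM2.5"` or `"PM10"`.
#' @return An `exposure_record` list.
#' @export
exposure_record <- function(dates, values, sampling_date,
                            pollutant = c("PM10", "PM2.5")) {
  pollutant <- match.arg(pollutant)
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(values))
  if (any(diff(as.numeric(dates)) <= 0)) {
    stop("dates must be strictly increasing")
  }
  if (any(values < 0, na.rm = TRUE)) stop("PM values must be non-negative")
  structure(list(dates = dates, values = values,
                 sampling_date = as.Date(sampling_date),
                 pollutant = pollutant),
            class = "exposure_record")
}

#' Backward-sliding-window average of daily PM values
#'
#' Averages the daily concentrations over a window of `window_days`
#' consecutive days ending `lag_days` before the sampling date (inclusive) --
#' the exposure proxy used for relating PM to pink-cell appearance (6-day
#' window, 2-day lag by default). Values outside the window never enter the
#' mean.
#'
#' @param rec an [exposure_record()].
#' @param window_days length of the exposure window in days.
#' @param lag_days gap between the window end and the sampling date.
#' @return The window mean concentration.
#' @export
bsw_average <- function(rec, window_days = 6L, lag_days = 2L) {
  stopifnot(inherits(rec, "exposure_record"))
  end <- rec$sampling_date - lag_days
  window <- seq(end - window_days + 1L, end, by = "day")
  pos <- match(window, rec$dates)
  missing <- window[is.na(pos) | is.na(rec$values[pos])]
  if (length(missing) > 0) {
    stop("missing daily values in the exposure window: ",
         paste(format(missing), collapse = ", "))
  }
  mean(rec$values[pos])
}

#' Least-squares regression through the origin with Pearson correlation
#'
#' Fits y = s x with slope s = sum(xy) / sum(x^2) and reports the ordinary
#' product-moment correlation of (x, y) alongside, the form in which the
#' PM / pink-cell relations are summarized.
#'
#' @param x predictor (windowed PM average, ug/m3).
#' @param y response (pink cells per 1000 hairs).
#' @return A `regression_result` list with `slope`, `se_slope`, `pearson_r`
#'   and `n`.
#' @export
fit_origin_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("at least 2 points are required")
  sxx <- sum(x^2)
  if (sxx == 0) stop("all x values are zero; the slope is undefined")
  slope <- sum(x * y) / sxx
  resid <- y - slope * x
  se <- if (length(x) > 1) {
    sqrt(sum(resid^2) / (length(x) - 1) / sxx)
  } else {
    NA_real_
  }
  structure(list(slope = slope, se_slope = se,
                 pearson_r = stats::cor(x, y), n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.2fx (SE %.3f), r = %.3f, n = %d\n",
              x$slope, x$se_slope, x$pearson_r, x$n))
  invisible(x)
}
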