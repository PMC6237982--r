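#' Fit first-order removal kinetics to a concentration series
#'
#' Fits C(t) = c0 * exp(-k t).  The default log-linear method regresses
#' ln C on t by ordinary least squares, excluding samples at or below the
#' detection floor (log of a near-zero reading is dominated by analytical
#' noise).  The nonlinear method minimizes squared error on the
#' concentration scale itself via \code{\link[stats]{nls}}, seeded by the
#' log-linear estimates; prefer it when many samples sit near zero.
#'
#' @param time_h Sample times (h).
#' @param conc_mg_l Concentrations (mg/L), >= 0.
#' @param method \code{"log-linear"} (default) or \code{"nonlinear"}.
#' @param detection_floor Concentration (mg/L) at or below which samples
#'   are excluded from the log-linear fit.
#' @return Object of class \code{first_order_fit} with components
#'   \code{k} (1/h), \code{c0} (mg/L), \code{r_squared} and
#'   \code{method}; supports \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{print} and \code{plot}.
#' @examples
#' t <- 0:10
#' fit <- fit_first_order(t, 50 * exp(-0.3 * t))
#' coef(fit)  # k = 0.3, c0 = 50
#' @export
fit_first_order <- function(time_h, conc_mg_l,
                            method = c("log-linear", "nonlinear"),
                            detection_floor = 0.1) {
  method <- match.arg(method)
  if (length(time_h) != length(conc_mg_l))
    stop("time_h and conc_mg_l must have the same length")
  ok <- is.finite(time_h) & is.finite(conc_mg_l)
  time_h <- time_h[ok]; conc_mg_l <- conc_mg_l[ok]
  if (length(time_h) < 3)
    stop("first-order fit needs at least 3 finite samples")
  if (any(conc_mg_l < 0)) stop("concentrations must be >= 0")
  if (all(conc_mg_l == 0))
    stop("degenerate data: all concentrations are zero")

  if (method == "log-linear") {
    use <- conc_mg_l > detection_floor
    if (sum(use) < 2)
      stop("log-linear fit needs >= 2 samples above the detection floor (",
           detection_floor, " mg/L); try method = \"nonlinear\"")
    t <- time_h[use]; y <- log(conc_mg_l[use])
    fit <- stats::lm(y ~ t)
    k <- max(0, -unname(stats::coef(fit)[2]))
    c0 <- exp(unname(stats::coef(fit)[1]))
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  } else {
    # seed from a rough log-linear pass (floor-protected)
    y0 <- log(pmax(conc_mg_l, detection_floor))
    sl <- stats::coef(stats::lm(y0 ~ time_h))
    start <- list(c0 = max(conc_mg_l), k = max(1e-6, -unname(sl[2])))
    nfit <- try(stats::nls(conc_mg_l ~ c0 * exp(-k * time_h), start = start,
                           control = stats::nls.control(warnOnly = TRUE)),
                silent = TRUE)
    if (inherits(nfit, "try-error"))
      stop("nonlinear first-order fit failed to converge")
    p <- stats::coef(nfit)
    k <- max(0, unname(p["k"])); c0 <- unname(p["c0"])
    res <- conc_mg_l - c0 * exp(-k * time_h)
    sst <- sum((conc_mg_l - mean(conc_mg_l))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  }
  structure(list(k = k, c0 = c0, r_squared = r2, method = method,
                 detection_floor = detection_floor,
                 data = data.frame(time_h = time_h, conc_mg_l = conc_mg_l)),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("First-order removal fit (%s):\n", x$method))
  cat(sprintf("  k  = %.4g 1/h   (half-life %.3g h)\n", x$k,
              if (x$k > 0) log(2) / x$k else Inf))
  cat(sprintf("  c0 = %.4g mg/L   R2 = %.4f\n", x$c0, x$r_squared))
  invisible(x)
}

#' @export
coef.first_order_fit <- function(object, ...) {
  c(k = object$k, c0 = object$c0)
}

#' @export
predict.first_order_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_h
       else if (is.data.frame(newdata)) newdata$time_h else newdata
  object$c0 * exp(-object$k * t)
}

#' @export
fitted.first_order_fit <- function(object, ...) predict(object)

#' @export
residuals.first_order_fit <- function(object, ...) {
  object$data$conc_mg_l - fitted(object)
}

#' @export
plot.first_order_fit <- function(x, ...) {
  d <- x$data
  plot(d$time_h, d$conc_mg_l, xlab = "time (h)",
       ylab = "concentration (mg/L)", ...)
  tt <- seq(min(d$time_h), max(d$time_h), length.out = 200)
  graphics::lines(tt, x$c0 * exp(-x$k * tt), col = "steelblue")
  invisible(x)
}

#' Volumetric nitrate removal rate
#'
#' The endpoint-average removal rate in the two unit systems used for
#' denitrifying reactors: mg N per litre per hour, and kg N per cubic
#' metre per day (= mg/L/h x 0.024).
#'
#' @param initial_mg_l Initial nitrate-N concentration (mg/L).
#' @param fraction_removed Fraction of the initial concentration removed
#'   over the interval, in [0, 1].
#' @param duration_h Interval length (h), > 0.
#' @return Named vector with \code{mg_n_l_h} and \code{kg_n_m3_d}.
#' @examples
#' volumetric_removal_rate(200, 0.828, 6)  # ~27.6 mg/L/h, 0.66 kg/m3/d
#' @export
volumetric_removal_rate <- function(initial_mg_l, fraction_removed,
                                    duration_h) {
  if (!is.finite(duration_h) || duration_h <= 0)
    stop("duration_h must be positive")
  if (!is.finite(fraction_removed) || fraction_removed < 0 ||
      fraction_removed > 1)
    stop("fraction_removed must lie in [0, 1]")
  if (!is.finite(initial_mg_l) || initial_mg_l < 0)
    stop("initial_mg_l must be >= 0")
  mg_l_h <- initial_mg_l * fraction_removed / duration_h
  c(mg_n_l_h = mg_l_h, kg_n_m3_d = mg_l_h * 24 / 1000)
}
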