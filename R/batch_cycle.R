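#' Reactor configuration
#'
#' Physical constants of the two-chamber reactor: anolyte volume,
#' external resistance in the circuit, and cathode area used to
#' normalize current and power densities.  Defaults match a bench-scale
#' cell: 15 mL chambers, 1 kOhm external resistor, 7 cm2 cathode.
#'
#' @param anolyte_volume_l Anolyte volume (L).
#' @param external_resistance_ohm External resistance (Ohm).
#' @param cathode_area_m2 Cathode projected area (m2).
#' @return Object of class \code{reactor_config}.
#' @export
reactor_config <- function(anolyte_volume_l = 0.015,
                           external_resistance_ohm = 1000,
                           cathode_area_m2 = 7e-4) {
  vals <- list(anolyte_volume_l = anolyte_volume_l,
               external_resistance_ohm = external_resistance_ohm,
               cathode_area_m2 = cathode_area_m2)
  bad <- vapply(vals, function(x) !is.numeric(x) || length(x) != 1 ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    stop("reactor parameters must be single positive numbers; bad: ",
         paste(names(vals)[bad], collapse = ", "))
  structure(vals, class = "reactor_config")
}

#' One batch cycle of a microbial fuel cell
#'
#' The unit of analysis: a multichannel time series covering one
#' feed-to-depletion cycle.  Voltage is sampled densely (typically every
#' 5 min); chemistry (COD, nitrogen species) may be sampled sparsely but
#' COD and nitrate-N must be present at least at the first and last
#' sample.  Missing chemistry samples are \code{NA}.
#'
#' @param time_h Sample times (h), strictly increasing.
#' @param voltage_v Cell voltage across the external resistor (V), >= 0.
#' @param cod_mg_l Chemical oxygen demand (mg/L), \code{NA} where not
#'   measured.
#' @param no3n_mg_l,no2n_mg_l,nh4n_mg_l Nitrogen species as N (mg/L).
#' @param reactor A \code{\link{reactor_config}}.
#' @return Object of class \code{batch_cycle}.
#' @export
batch_cycle <- function(time_h, voltage_v, cod_mg_l, no3n_mg_l,
                        no2n_mg_l = NULL, nh4n_mg_l = NULL,
                        reactor = reactor_config()) {
  n <- length(time_h)
  if (n < 2) stop("a batch cycle needs at least 2 samples")
  if (length(voltage_v) != n) stop("voltage_v length must match time_h")
  if (any(diff(time_h) <= 0)) {
    i <- which(diff(time_h) <= 0)[1]
    stop("time_h must be strictly increasing (violated at row ", i + 1, ")")
  }
  if (any(voltage_v < 0, na.rm = TRUE)) stop("voltage_v must be >= 0")
  pad <- function(x, nm) {
    if (is.null(x)) return(rep(NA_real_, n))
    if (length(x) != n) stop(nm, " length must match time_h")
    if (any(x < 0, na.rm = TRUE)) stop(nm, " must be >= 0")
    as.numeric(x)
  }
  cod_mg_l <- pad(cod_mg_l, "cod_mg_l")
  no3n_mg_l <- pad(no3n_mg_l, "no3n_mg_l")
  no2n_mg_l <- pad(no2n_mg_l, "no2n_mg_l")
  nh4n_mg_l <- pad(nh4n_mg_l, "nh4n_mg_l")
  for (nm in c("cod_mg_l", "no3n_mg_l")) {
    x <- get(nm)
    if (is.na(x[1]) || is.na(x[n]))
      stop(nm, " must be measured at the first and last sample")
  }
  if (!inherits(reactor, "reactor_config"))
    reactor <- do.call(reactor_config, as.list(reactor))
  structure(list(
    data = data.frame(time_h = as.numeric(time_h),
                      voltage_v = as.numeric(voltage_v),
                      cod_mg_l = cod_mg_l, no3n_mg_l = no3n_mg_l,
                      no2n_mg_l = no2n_mg_l, nh4n_mg_l = nh4n_mg_l),
    reactor = reactor), class = "batch_cycle")
}

#' @export
print.batch_cycle <- function(x, ...) {
  d <- x$data
  n <- nrow(d)
  cat(sprintf("Batch cycle: %d samples over %.2f h\n", n,
              d$time_h[n] - d$time_h[1]))
  cat(sprintf("  voltage    %.3f -> %.3f V (max %.3f)\n",
              d$voltage_v[1], d$voltage_v[n], max(d$voltage_v)))
  cat(sprintf("  COD        %.1f -> %.1f mg/L\n", d$cod_mg_l[1],
              d$cod_mg_l[n]))
  cat(sprintf("  NO3-N      %.1f -> %.1f mg/L\n", d$no3n_mg_l[1],
              d$no3n_mg_l[n]))
  cat(sprintf("  reactor    %.0f mL, %g Ohm, %.1f cm2 cathode\n",
              x$reactor$anolyte_volume_l * 1000,
              x$reactor$external_resistance_ohm,
              x$reactor$cathode_area_m2 * 1e4))
  invisible(x)
}

#' @export
plot.batch_cycle <- function(x, ...) {
  d <- x$data
  op <- graphics::par(mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  plot(d$time_h, d$voltage_v, type = "l", xlab = "time (h)",
       ylab = "voltage (V)", ...)
  ok <- !is.na(d$no3n_mg_l)
  if (any(ok)) {
    graphics::par(new = TRUE)
    plot(d$time_h[ok], d$no3n_mg_l[ok], type = "b", col = "firebrick",
         axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "firebrick")
    graphics::mtext("NO3-N (mg/L)", side = 4, line = 2.5,
                    col = "firebrick")
  }
  invisible(x)
}
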