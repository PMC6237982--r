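#' Charge delivered to the circuit over a batch cycle
#'
#' Integrates the circuit current I(t) = V(t)/R over the cycle by the
#' trapezoidal rule (time converted from hours to seconds).  This is the
#' anode-respiration term of the electron balance.
#'
#' @param cycle A \code{\link{batch_cycle}}.
#' @return Charge in Coulombs.
#' @examples
#' # 0.45 V across 1 kOhm for 10 h is 4.5e-4 A * 36000 s = 16.2 C
#' @export
integrate_current <- function(cycle) {
  stopifnot(inherits(cycle, "batch_cycle"))
  d <- cycle$data
  if (nrow(d) < 2)
    stop("insufficient data: current integration needs >= 2 samples")
  R <- cycle$reactor$external_resistance_ohm
  pracma::trapz(d$time_h * 3600, d$voltage_v / R)
}

#' Total electrons liberated from the substrate in one cycle
#'
#' The COD consumed between the first and last sample, scaled by the
#' anolyte volume and converted to charge (4 e- per O2 equivalent).
#' A COD *increase* beyond a small noise tolerance triggers a
#' data-quality warning and is treated as zero consumption.
#'
#' @param cycle A \code{\link{batch_cycle}}.
#' @param constants A \code{stoich_constants} object.
#' @param increase_tolerance Fractional COD increase tolerated as
#'   measurement noise before warning.
#' @return Charge in Coulombs.
#' @export
total_electrons <- function(cycle, constants = stoich_constants(),
                            increase_tolerance = 0.02) {
  stopifnot(inherits(cycle, "batch_cycle"))
  d <- cycle$data
  delta <- d$cod_mg_l[1] - d$cod_mg_l[nrow(d)]
  if (delta < 0) {
    if (-delta > increase_tolerance * max(d$cod_mg_l[1], 1))
      warning("COD increased over the cycle by ",
              format(-delta, digits = 3),
              " mg/L; check influent/effluent samples", call. = FALSE)
    delta <- 0
  }
  electrons_from_cod(delta * cycle$reactor$anolyte_volume_l,
                     constants = constants)
}

#' Partition a batch cycle's electron fluxes
#'
#' Splits the electrons liberated by substrate oxidation (\code{c_t},
#' from the COD drop) into three sinks: anode respiration (\code{c_an},
#' the time integral of circuit current), anodic denitrification
#' (\code{c_de}, from nitrate-N removed assuming reduction to N2), and
#' a residual (\code{c_ot = c_t - c_an - c_de}) covering biomass
#' synthesis and losses.  Also computes the coulombic efficiency
#' CE = 100 c_an / c_t and the denitrification-corrected coulombic
#' efficiency CCE = 100 c_an / (c_t - c_de).
#'
#' A negative residual is reported, never clamped: it flags inconsistent
#' measurements.  A nonzero final ammonium triggers a warning, since
#' dissimilatory nitrate reduction to ammonium would consume 8 e- per N
#' and bias \code{c_de}.
#'
#' @param cycle A \code{\link{batch_cycle}}.
#' @param constants A \code{stoich_constants} object.
#' @param nitrite_correction Deduct electrons for nitrate stalled at
#'   residual nitrite (see \code{\link{electrons_from_nitrate}}).
#' @return Object of class \code{electron_balance}: charges \code{c_t},
#'   \code{c_an}, \code{c_de}, \code{c_ot} (C), \code{ce_pct},
#'   \code{cce_pct}, and \code{fractions}.
#' @examples
#' sim <- simulate_batch_cycle(sim_config(initial_no3n_mg_l = 50), seed = 1)
#' electron_balance(sim$cycle)
#' @export
electron_balance <- function(cycle, constants = stoich_constants(),
                             nitrite_correction = FALSE) {
  stopifnot(inherits(cycle, "batch_cycle"))
  d <- cycle$data
  n <- nrow(d)
  c_t <- total_electrons(cycle, constants = constants)
  c_an <- integrate_current(cycle)
  delta_n <- (d$no3n_mg_l[1] - d$no3n_mg_l[n]) *
    cycle$reactor$anolyte_volume_l
  if (delta_n < 0) {
    warning("nitrate-N increased over the cycle; treating removal as 0",
            call. = FALSE)
    delta_n <- 0
  }
  resid_no2 <- if (is.na(d$no2n_mg_l[n])) 0 else
    d$no2n_mg_l[n] * cycle$reactor$anolyte_volume_l
  c_de <- electrons_from_nitrate(delta_n, resid_no2,
                                 nitrite_correction = nitrite_correction,
                                 constants = constants)
  if (!is.na(d$nh4n_mg_l[n]) && d$nh4n_mg_l[n] > 0.1)
    warning("final NH4-N ", d$nh4n_mg_l[n], " mg/L > 0.1: dissimilatory ",
            "reduction to ammonium (8 e-/N) would bias the balance",
            call. = FALSE)
  if (c_t == 0 && c_an > 1e-9)
    stop("no COD was consumed but circuit charge is nonzero: ",
         "coulombic efficiency undefined")
  c_ot <- c_t - c_an - c_de
  if (c_ot < -1e-9 * max(c_t, 1))
    warning("negative residual electron flux (", format(c_ot, digits = 3),
            " C): sinks exceed the COD-derived total", call. = FALSE)
  ce <- if (c_t > 0) 100 * c_an / c_t else NA_real_
  denom <- c_t - c_de
  cce_flag <- NULL
  if (denom <= 0) {
    cce <- NA_real_
    cce_flag <- "c_de >= c_t: corrected coulombic efficiency undefined"
    warning(cce_flag, call. = FALSE)
  } else cce <- 100 * c_an / denom
  fr <- if (c_t > 0)
    c(anode_respiration = c_an / c_t,
      anodic_denitrification = c_de / c_t,
      others = c_ot / c_t)
  else c(anode_respiration = NA_real_, anodic_denitrification = NA_real_,
         others = NA_real_)
  structure(list(c_t = c_t, c_an = c_an, c_de = c_de, c_ot = c_ot,
                 ce_pct = ce, cce_pct = cce, fractions = fr,
                 nitrate_removed_mg = delta_n, flag = cce_flag),
            class = "electron_balance")
}

#' @export
print.electron_balance <- function(x, digits = 4, ...) {
  cat("Electron balance (Coulombs):\n")
  cat(sprintf("  c_t  total (COD)        %s\n", format(x$c_t, digits = digits)))
  cat(sprintf("  c_an anode respiration  %s\n", format(x$c_an, digits = digits)))
  cat(sprintf("  c_de denitrification    %s\n", format(x$c_de, digits = digits)))
  cat(sprintf("  c_ot others (residual)  %s\n", format(x$c_ot, digits = digits)))
  cat(sprintf("  CE  %.1f %%   CCE  %s %%\n", x$ce_pct,
              if (is.na(x$cce_pct)) "NA" else sprintf("%.1f", x$cce_pct)))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
summary.electron_balance <- function(object, ...) {
  fr <- electron_fractions(object)
  cat("Electron fractions of c_t:\n")
  for (nm in names(fr))
    cat(sprintf("  %-24s %.3f\n", nm, fr[[nm]]))
  invisible(fr)
}

#' Electron fractions of the three sinks
#'
#' @param balance An \code{\link{electron_balance}} with \code{c_t > 0}.
#' @return Named vector (anode_respiration, anodic_denitrification,
#'   others) summing to 1 exactly.
#' @export
electron_fractions <- function(balance) {
  stopifnot(inherits(balance, "electron_balance"))
  if (!is.finite(balance$c_t) || balance$c_t <= 0)
    stop("electron fractions require c_t > 0")
  c(anode_respiration = balance$c_an / balance$c_t,
    anodic_denitrification = balance$c_de / balance$c_t,
    others = balance$c_ot / balance$c_t)
}

#' Net COD/N ratio of a batch cycle
#'
#' Mass of COD consumed per mass of nitrate-N removed, under two
#' accountings.  \code{"residual"} charges denitrification with all COD
#' not recovered as circuit current (c_t - c_an), i.e. denitrification
#' plus biomass and losses.  \code{"dissimilatory"} counts only the
#' stoichiometric electrons of nitrate reduction (c_de), which is the
#' constant 40/14 = 2.857 g COD per g N regardless of the data.
#'
#' @param cycle A \code{\link{batch_cycle}}.
#' @param mode \code{"residual"} or \code{"dissimilatory"}.
#' @param constants A \code{stoich_constants} object.
#' @param balance Optionally a precomputed \code{electron_balance} for
#'   this cycle.
#' @return The ratio, g COD per g N.
#' @export
net_cod_n_ratio <- function(cycle, mode = c("residual", "dissimilatory"),
                            constants = stoich_constants(),
                            balance = NULL) {
  mode <- match.arg(mode)
  if (is.null(balance))
    balance <- suppressWarnings(electron_balance(cycle, constants = constants))
  stopifnot(inherits(balance, "electron_balance"))
  n_mg <- balance$nitrate_removed_mg
  if (!is.finite(n_mg) || n_mg <= 0)
    stop("net COD/N requires positive nitrate-N removal")
  charge <- switch(mode, residual = balance$c_t - balance$c_an,
                   dissimilatory = balance$c_de)
  cod_equivalent_of_charge(charge, constants = constants) / n_mg
}
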