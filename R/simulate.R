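#' Configuration for the synthetic batch-cycle generator
#'
#' Defaults reproduce the bench-scale operating regime the analysis
#' targets: 1 g/L sodium acetate feed (780.5 mg/L COD), nitrate-N from 0
#' to 200 mg/L, a ~0.45 V plateau across a 1 kOhm resistor, 15 mL
#' anolyte, 7 cm2 cathode, voltage logged every 5 min, and 2%
#' multiplicative measurement noise.
#'
#' @param initial_cod_mg_l Starting COD (mg/L).
#' @param initial_no3n_mg_l Starting nitrate-N (mg/L), 0 for a
#'   nitrate-free control.
#' @param k_no3_h First-order nitrate removal constant (1/h).
#' @param plateau_voltage_v Cell voltage during the substrate-replete
#'   plateau (V).
#' @param external_resistance_ohm,anolyte_volume_l,cathode_area_m2
#'   Reactor constants, see \code{\link{reactor_config}}.
#' @param others_fraction Fraction of the total electron flux diverted
#'   to biomass synthesis and losses, in [0, 1).
#' @param sample_interval_min Logging interval (min).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 = noise-free).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(initial_cod_mg_l = 780.5,
                       initial_no3n_mg_l = 0,
                       k_no3_h = 0.3,
                       plateau_voltage_v = 0.45,
                       external_resistance_ohm = 1000,
                       anolyte_volume_l = 0.015,
                       cathode_area_m2 = 7e-4,
                       others_fraction = 0.10,
                       sample_interval_min = 5,
                       noise_cv = 0.02) {
  cfg <- list(initial_cod_mg_l = initial_cod_mg_l,
              initial_no3n_mg_l = initial_no3n_mg_l,
              k_no3_h = k_no3_h,
              plateau_voltage_v = plateau_voltage_v,
              external_resistance_ohm = external_resistance_ohm,
              anolyte_volume_l = anolyte_volume_l,
              cathode_area_m2 = cathode_area_m2,
              others_fraction = others_fraction,
              sample_interval_min = sample_interval_min,
              noise_cv = noise_cv)
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1))
  if (!all(num)) stop("all sim_config fields must be single finite numbers")
  if (cfg$others_fraction < 0 || cfg$others_fraction >= 1)
    stop("others_fraction must lie in [0, 1)")
  if (cfg$initial_cod_mg_l <= 0) stop("initial_cod_mg_l must be > 0")
  if (cfg$initial_no3n_mg_l < 0 || cfg$k_no3_h < 0 || cfg$noise_cv < 0)
    stop("concentrations, rates and noise must be >= 0")
  structure(cfg, class = "sim_config")
}

# multiplicative log-normal noise with unit mean
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate one batch cycle with a known electron partition
#'
#' Generates a feed-to-depletion cycle in which anode respiration and
#' denitrification draw concurrently on the same electron-donor (COD)
#' pool: nitrate declines first-order at \code{k_no3_h}; the cell holds
#' \code{plateau_voltage_v} while donor remains, then decays
#' exponentially (0.5 h time constant) to below the 20 mV cycle-end
#' threshold.  The COD trajectory is constructed so that the electrons
#' consumed equal c_an + c_de + c_ot with c_ot exactly
#' \code{others_fraction} of the total before noise; the cycle is timed
#' to leave ~0.5% of the COD budget as residual so the endpoint stays
#' positive under noise.  Ground truth is returned alongside, so
#' pipeline recovery can be checked exactly.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed; the output is a deterministic function of
#'   (config, seed).
#' @return List with \code{cycle} (a \code{\link{batch_cycle}}, noisy if
#'   \code{noise_cv > 0}) and \code{truth} (an \code{electron_balance}
#'   computed from the noise-free series).
#' @examples
#' sim <- simulate_batch_cycle(sim_config(initial_no3n_mg_l = 100), seed = 7)
#' sim$truth$ce_pct
#' @export
simulate_batch_cycle <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  F <- 96485
  V_l <- config$anolyte_volume_l
  R <- config$external_resistance_ohm
  f <- config$others_fraction
  vp <- config$plateau_voltage_v
  tau_h <- 0.5                      # post-depletion voltage decay constant
  end_v <- 0.02                     # medium-replacement threshold
  dt_h <- config$sample_interval_min / 60

  budget_c <- electrons_from_cod(config$initial_cod_mg_l * V_l)
  # charge (C) per mg/L of nitrate-N removed
  q_n <- V_l * 5 * F / (14 * 1000)
  n0 <- config$initial_no3n_mg_l
  k <- config$k_no3_h
  i_p <- vp / R                      # plateau current (A)
  # decay-phase charge down to the cutoff voltage
  decay_c <- i_p * 3600 * tau_h * (1 - end_v / vp)
  # donor-depletion time: plateau + decay charge and nitrate electrons
  # consume 99.5% of the budget (the rest stays as residual COD)
  usable_c <- 0.995 * budget_c
  consumed <- function(t) {
    c_de_t <- if (k > 0) q_n * n0 * (1 - exp(-k * t)) else 0
    (i_p * 3600 * t + decay_c + c_de_t) / (1 - f)
  }
  if (consumed(dt_h) >= usable_c)
    stop("infeasible config: COD budget exhausted before the first sample")
  t_up <- usable_c * (1 - f) / (i_p * 3600) + dt_h
  t_dep <- stats::uniroot(function(t) consumed(t) - usable_c,
                          c(dt_h, t_up), tol = 1e-10)$root

  t_end <- t_dep + tau_h * log(vp / end_v) + 3 * dt_h  # debounce margin
  time_h <- seq(0, ceiling(t_end / dt_h) * dt_h, by = dt_h)
  volts <- ifelse(time_h <= t_dep, vp,
                  vp * exp(-(time_h - t_dep) / tau_h))
  no3 <- ifelse(time_h <= t_dep, n0 * exp(-k * time_h),
                n0 * exp(-k * t_dep))

  c_an_cum <- pracma::cumtrapz(time_h * 3600, volts / R)[, 1]
  c_de_cum <- q_n * (n0 - no3)
  cum_total <- (c_an_cum + c_de_cum) / (1 - f)
  cod <- config$initial_cod_mg_l - cum_total * 8000 / F / V_l
  if (cod[length(cod)] < 0)
    stop("infeasible config: COD trajectory went negative")

  c_an <- c_an_cum[length(c_an_cum)]
  c_de <- c_de_cum[length(c_de_cum)]
  c_t <- (c_an + c_de) / (1 - f)
  truth <- structure(list(
    c_t = c_t, c_an = c_an, c_de = c_de, c_ot = f * c_t,
    ce_pct = 100 * c_an / c_t,
    cce_pct = if (c_t - c_de > 0) 100 * c_an / (c_t - c_de) else NA_real_,
    fractions = c(anode_respiration = c_an / c_t,
                  anodic_denitrification = c_de / c_t,
                  others = f),
    nitrate_removed_mg = (n0 - no3[length(no3)]) * V_l,
    flag = NULL), class = "electron_balance")

  cv <- config$noise_cv
  cycle <- batch_cycle(
    time_h = time_h,
    voltage_v = mult_noise(volts, cv),
    cod_mg_l = mult_noise(cod, cv),
    no3n_mg_l = mult_noise(no3, cv),
    no2n_mg_l = rep(0, length(time_h)),
    nh4n_mg_l = rep(0, length(time_h)),
    reactor = reactor_config(anolyte_volume_l = V_l,
                             external_resistance_ohm = R,
                             cathode_area_m2 = config$cathode_area_m2))
  list(cycle = cycle, truth = truth)
}

#' Simulate a polarization sweep of a linear cell
#'
#' Equivalent-circuit generator: V = OCV R / (R + R_int) at each
#' external resistance, optionally with multiplicative noise.  For this
#' model the maximum power density falls at R = R_int (maximum power
#' transfer), which anchors the tests of
#' \code{\link{polarization_analysis}}.
#'
#' @param ocv_v Open-circuit voltage (V), > 0.
#' @param r_int_ohm Internal resistance (Ohm), >= 0.
#' @param cathode_area_m2 Cathode area (m2).
#' @param resistances External resistances to sweep (Ohm), > 0.
#' @param noise_cv Voltage noise CV (0 = exact).
#' @param seed Integer seed.
#' @return A \code{\link{polarization_curve}}.
#' @export
simulate_polarization <- function(ocv_v, r_int_ohm,
                                  cathode_area_m2 = 7e-4,
                                  resistances = c(100, 150, 200, 300, 500,
                                                  800, 1000, 2000, 5000),
                                  noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(ocv_v) || ocv_v <= 0) stop("ocv_v must be > 0")
  if (!is.finite(r_int_ohm) || r_int_ohm < 0) stop("r_int_ohm must be >= 0")
  if (any(resistances <= 0)) stop("resistances must be > 0")
  v <- ocv_v * resistances / (resistances + r_int_ohm)
  polarization_curve(resistances, mult_noise(v, noise_cv),
                     cathode_area_m2 = cathode_area_m2)
}

#' Simulate a cyclic voltammogram with Gaussian redox peaks
#'
#' Builds a two-segment (anodic then cathodic) sweep over the potential
#' window as a sum of Gaussian peaks on a signed capacitive baseline:
#' anodic peaks add positive current to the anodic sweep, cathodic
#' (reduction) peaks add negative current to the cathodic sweep.
#'
#' @param peaks Data frame with columns \code{center_v},
#'   \code{height_a} (> 0), \code{width_v} (Gaussian sigma, V) and
#'   \code{kind} ("anodic" or "cathodic").  May have zero rows.
#' @param baseline_capacitive_a Magnitude of the capacitive current
#'   offset (A): + on the anodic sweep, - on the cathodic.
#' @param window Potential window \code{c(min, max)} (V vs. reference).
#' @param step_v Potential step (V).
#' @param scan_rate_v_s Scan rate recorded in the output (V/s).
#' @param noise_a Additive Gaussian current noise sd (A).
#' @param seed Integer seed.
#' @return A \code{\link{voltammogram}}.
#' @export
simulate_cv <- function(peaks = data.frame(center_v = numeric(),
                                           height_a = numeric(),
                                           width_v = numeric(),
                                           kind = character()),
                        baseline_capacitive_a = 5e-5,
                        window = c(-0.6, 0.2), step_v = 0.001,
                        scan_rate_v_s = 0.001, noise_a = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (step_v <= 0) stop("step_v must be > 0")
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be c(min, max) with min < max")
  need <- c("center_v", "height_a", "width_v", "kind")
  if (!all(need %in% names(peaks)))
    stop("peaks must have columns ", paste(need, collapse = ", "))
  out <- which(peaks$center_v < window[1] | peaks$center_v > window[2])
  if (length(out))
    warning("peak centre(s) outside the sweep window: ",
            paste(format(peaks$center_v[out]), collapse = ", "),
            call. = FALSE)
  e_up <- seq(window[1], window[2], by = step_v)
  e_dn <- rev(e_up)[-1]
  gaussians <- function(e, kind) {
    tot <- numeric(length(e))
    sel <- peaks$kind == kind
    for (i in which(sel))
      tot <- tot + peaks$height_a[i] *
        exp(-0.5 * ((e - peaks$center_v[i]) / peaks$width_v[i])^2)
    tot
  }
  i_up <- baseline_capacitive_a + gaussians(e_up, "anodic")
  i_dn <- -baseline_capacitive_a - gaussians(e_dn, "cathodic")
  cur <- c(i_up, i_dn)
  if (noise_a > 0) cur <- cur + stats::rnorm(length(cur), sd = noise_a)
  voltammogram(c(e_up, e_dn), cur, scan_rate_v_s = scan_rate_v_s,
               segment = c(rep("anodic", length(e_up)),
                           rep("cathodic", length(e_dn))))
}
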