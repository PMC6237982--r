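# shared fixtures, generated in code

# a cycle with constant voltage and linear chemistry, for closed-form checks
constant_voltage_cycle <- function(v = 0.45, hours = 10, n = 121,
                                   cod0 = 780.5, cod_end = 100,
                                   no3_0 = 50, no3_end = 0,
                                   reactor = reactor_config()) {
  t <- seq(0, hours, length.out = n)
  batch_cycle(time_h = t,
              voltage_v = rep(v, n),
              cod_mg_l = seq(cod0, cod_end, length.out = n),
              no3n_mg_l = seq(no3_0, no3_end, length.out = n),
              no2n_mg_l = rep(0, n), nh4n_mg_l = rep(0, n),
              reactor = reactor)
}

# initial nitrate-N (mg/L) that makes c_de approximately a target fraction
# of c_t, assuming full depletion; from the simulator's electron budget
nitrate_for_de_fraction <- function(cfg, frac) {
  budget <- electrons_from_cod(cfg$initial_cod_mg_l * cfg$anolyte_volume_l)
  c_de <- frac * 0.995 * budget
  c_de * 14 * 1000 / (cfg$anolyte_volume_l * 5 * 96485)
}

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%g within %g of %g", object, tol, expected))
}
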