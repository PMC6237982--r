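test_that("polarization analysis finds MPD and internal resistance of a linear cell", {
  # V = 0.7 - 200 I: with the sweep bracketing 200 Ohm, max power
  # transfer puts the MPD point at R_ext = 200 Ohm
  pc <- simulate_polarization(0.7, 200,
                              resistances = c(100, 150, 200, 300, 500,
                                              1000, 5000))
  res <- polarization_analysis(pc)
  expect_equal(res$mpd_resistance_ohm, 200)
  expect_within(res$mpd_w_m2, 0.875, 1e-6)   # (0.35^2/200)/7e-4
  expect_within(res$current_density_at_mpd_a_m2, 2.5, 1e-6)
  expect_within(res$internal_resistance_ohm, 200, 1e-6)
  expect_within(res$ocv_v, 0.7, 1e-6)
  expect_length(res$flags, 0)
})

test_that("degenerate polarization inputs are flagged or rejected", {
  one <- polarization_curve(1000, 0.45)
  res <- polarization_analysis(one)
  expect_within(res$mpd_w_m2, 0.45^2 / 1000 / 7e-4, 1e-9)  # 0.289 W/m2
  expect_match(res$flags, "fewer than 3", all = FALSE)
  zero <- polarization_curve(c(100, 500, 1000), c(0, 0, 0))
  expect_equal(polarization_analysis(zero)$mpd_w_m2, 0)
  expect_error(polarization_curve(c(100, 100), c(0.2, 0.5)), "conflicting")
  expect_error(polarization_curve(-5, 0.3), "positive")
})

test_that("power density equals voltage times current density at every point", {
  set.seed(31)
  pc <- simulate_polarization(runif(1, 0.4, 0.9), runif(1, 50, 800),
                              noise_cv = 0.02, seed = 99)
  p <- pc$points
  expect_equal(p$power_density_w_m2,
               p$voltage_v * p$current_density_a_m2, tolerance = 1e-12)
})

test_that("MPD falls at R_ext == R_int across a random linear-cell grid", {
  set.seed(12)
  sweep <- c(50, 100, 150, 200, 300, 500, 800, 1000, 2000, 5000)
  for (i in 1:20) {
    r_int <- sample(sweep[2:(length(sweep) - 1)], 1)
    ocv <- runif(1, 0.3, 1.0)
    pc <- simulate_polarization(ocv, r_int, resistances = sweep)
    expect_equal(polarization_analysis(pc)$mpd_resistance_ohm, r_int)
  }
})

test_that("CV first derivative matches calculus on known signals", {
  # linear I(E): constant derivative
  e <- seq(-0.6, 0.2, by = 0.001)
  lin <- voltammogram(e, 3e-4 * e + 1e-5, segment = rep("anodic", length(e)))
  d <- cv_first_derivative(lin)
  expect_equal(d$didE_a_v, rep(3e-4, length(e)), tolerance = 1e-6)
  # single Gaussian: derivative crosses zero at the centre
  cv <- simulate_cv(data.frame(center_v = -0.21, height_a = 2e-4,
                               width_v = 0.04, kind = "anodic"),
                    baseline_capacitive_a = 0)
  d <- cv_first_derivative(cv)
  da <- d[d$segment == "anodic", ]
  sgn <- sign(da$didE_a_v)
  cross <- which(diff(sgn) < 0 & abs(da$didE_a_v[-1]) < 1e-3)[1]
  expect_within(da$potential_v[cross], -0.21, 0.002)
  # window must fit the segment
  short <- voltammogram(seq(0, 0.01, 0.001), rnorm(11))
  expect_error(cv_first_derivative(short, smooth_window = 11), "shorter")
  expect_error(cv_first_derivative(lin, smooth_window = 10), "odd")
})

test_that("overlapping oxidation centres appear as two inflection structures", {
  cv <- simulate_cv(data.frame(center_v = c(-0.21, -0.05),
                               height_a = c(2e-4, 1.2e-4),
                               width_v = c(0.04, 0.04),
                               kind = c("anodic", "anodic")),
                    baseline_capacitive_a = 2e-5)
  rep <- detect_redox_peaks(cv, prominence_fraction = 0.05)
  infl_anodic <- rep$inflections[rep$inflections$segment == "anodic", ]
  # each Gaussian contributes a +max and a -min in dI/dE
  expect_gte(nrow(infl_anodic), 4)
  d <- cv_first_derivative(cv)
  expect_true(any(d$didE_a_v > 0) && any(d$didE_a_v < 0))
})

test_that("redox peak detection recovers placed peaks and respects invariances", {
  peaks <- data.frame(center_v = c(-0.21, -0.185),
                      height_a = c(2e-4, 1.5e-4),
                      width_v = c(0.03, 0.03),
                      kind = c("anodic", "cathodic"))
  cv <- simulate_cv(peaks, baseline_capacitive_a = 0)
  rep <- detect_redox_peaks(cv, prominence_fraction = 0.1)
  expect_equal(nrow(rep$oxidation_peaks), 1)
  expect_equal(nrow(rep$reduction_peaks), 1)
  expect_within(rep$oxidation_peaks$potential_v, -0.21, 0.005)
  expect_within(rep$reduction_peaks$potential_v, -0.185, 0.005)
  # scale equivariance: doubled height, same potential
  cv2 <- simulate_cv(transform(peaks, height_a = 2 * height_a),
                     baseline_capacitive_a = 0)
  rep2 <- detect_redox_peaks(cv2, prominence_fraction = 0.1)
  expect_equal(rep2$oxidation_peaks$potential_v,
               rep$oxidation_peaks$potential_v)
  expect_within(rep2$oxidation_peaks$height_a,
                2 * rep$oxidation_peaks$height_a, 1e-8)
  # offset invariance: a constant capacitive current moves nothing
  cv3 <- simulate_cv(peaks, baseline_capacitive_a = 5e-5)
  rep3 <- detect_redox_peaks(cv3, prominence_fraction = 0.1)
  expect_equal(rep3$oxidation_peaks$potential_v,
               rep$oxidation_peaks$potential_v)
  # null case: flat baseline plus 1% white noise yields no peaks
  set.seed(4)
  flat <- simulate_cv(baseline_capacitive_a = 1e-4, noise_a = 1e-6,
                      seed = 4)
  rep0 <- detect_redox_peaks(flat, prominence_fraction = 0.1)
  expect_equal(nrow(rep0$oxidation_peaks), 0)
  expect_equal(nrow(rep0$reduction_peaks), 0)
})

test_that("batch staging for CV segments a trapezoidal cycle in order", {
  t <- seq(0, 30, by = 1 / 12)
  v <- ifelse(t < 2, t / 2 * 0.45,
              ifelse(t < 20, 0.45, pmax(0.45 * exp(-(t - 20) / 0.5), 0)))
  st <- stage_batch_for_cv(t, v)
  expect_true(all(is.finite(st)))
  expect_true(st["stage1"] < st["stage2"])
  expect_true(st["stage2"] < st["stage3"])
  expect_true(st["stage3"] < st["stage4"])
  expect_true(st["stage4"] < st["stage5"])
  # monotone rise: decline and end stages undefined, flagged
  st2 <- stage_batch_for_cv(t, t / max(t) * 0.4)
  expect_true(is.na(st2["stage4"]) && is.na(st2["stage5"]))
  expect_gte(length(attr(st2, "flags")), 1)
  # constant voltage: degenerate, stages 1 and 2 coincide
  st3 <- stage_batch_for_cv(t, rep(0.3, length(t)))
  expect_equal(unname(st3["stage1"]), unname(st3["stage2"]))
  expect_match(attr(st3, "flags"), "coincide", all = FALSE)
})

test_that("staging also works on a simulated cycle", {
  sim <- simulate_batch_cycle(sim_config(initial_no3n_mg_l = 100,
                                         noise_cv = 0), seed = 2)
  d <- sim$cycle$data
  st <- stage_batch_for_cv(d$time_h, d$voltage_v)
  expect_true(all(is.finite(st[c("stage1", "stage2", "stage4", "stage5")])))
  expect_true(st["stage5"] <= max(d$time_h))
})
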