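test_that("COD equivalent of sodium acetate is linear and matches theory", {
  # theoretical conversion: 2 mol O2 per mol acetate, 82 g/mol salt
  expect_equal(cod_of_sodium_acetate(1.0), 1000 * 2 * 32 / 82,
               tolerance = 1e-12)
  expect_within(cod_of_sodium_acetate(1.0), 780.5, 0.1)
  expect_identical(cod_of_sodium_acetate(0), 0)
  expect_equal(cod_of_sodium_acetate(2.0), 2 * cod_of_sodium_acetate(1.0))
  expect_error(cod_of_sodium_acetate(-1), "non-negative")
})

test_that("COD route and acetate route count the same electrons", {
  st <- stoich_constants()
  # 1 g/L sodium acetate in 15 mL: 11.71 mg COD consumed
  mass_g <- 1.0 * 0.015
  via_cod <- electrons_from_cod(cod_of_sodium_acetate(1.0) * 0.015)
  via_acetate <- mass_g / st$mw_sodium_acetate * st$e_per_acetate * st$faraday
  expect_equal(via_cod, via_acetate, tolerance = 1e-9)
  expect_within(electrons_from_cod(11.71), 141.2, 0.1)
  expect_identical(electrons_from_cod(0), 0)
  expect_within(electrons_from_cod(780.5), 9413, 1)
  # linearity under random masses
  set.seed(42)
  m <- runif(20, 0, 5000)
  expect_equal(electrons_from_cod(2 * m), 2 * electrons_from_cod(m))
  expect_error(electrons_from_cod(-0.1), "non-negative")
})

test_that("nitrate electron equivalents follow the 5 e- route with optional nitrite deduction", {
  # 50 mg/L N in 15 mL = 0.75 mg N; 0.75/1000/14 * 5 * 96485
  expect_within(electrons_from_nitrate(0.75), 25.85, 0.01)
  expect_identical(electrons_from_nitrate(0), 0)
  # all removed nitrate stuck at nitrite: only 2 of 5 electrons used
  expect_equal(electrons_from_nitrate(0.75, 0.75, nitrite_correction = TRUE),
               electrons_from_nitrate(0.75) * 2 / 5, tolerance = 1e-12)
  # correction off ignores residual nitrite
  expect_equal(electrons_from_nitrate(0.75, 0.5), electrons_from_nitrate(0.75))
  expect_error(electrons_from_nitrate(0.5, 0.75), "inconsistent")
  expect_error(electrons_from_nitrate(-1), "non-negative")
})

test_that("critical COD/N ratio reproduces the stoichiometric 3.75 and scales correctly", {
  expect_within(critical_cod_n_ratio(denitrifier_stoichiometry()), 3.75, 0.01)
  # plug-in with unit coefficients: 82 * 0.7805 / 14
  unit <- half_reaction(c("CH3COO-" = 1, "NO3-" = 1), c("N2" = 0.5))
  expect_within(critical_cod_n_ratio(unit), 82 * 0.78049 / 14, 0.01)
  # doubling the nitrate coefficient halves the ratio
  dbl <- half_reaction(c("CH3COO-" = 1, "NO3-" = 2), c("N2" = 1))
  expect_equal(critical_cod_n_ratio(dbl), critical_cod_n_ratio(unit) / 2)
  no_nitrate <- half_reaction(c("CH3COO-" = 1, "H2O" = 2), c("CO2" = 2))
  expect_error(critical_cod_n_ratio(no_nitrate), "NO3-")
})

test_that("element balance tallies printed coefficients, flagging the known H/charge misbalance", {
  eq3 <- check_element_balance(denitrifier_stoichiometry(),
                               c("C", "N", "O", "H", "charge"))
  get <- function(el) eq3[eq3$element == el, ]
  # hand tallies: C 14.06 both sides, N 8.58 both sides, O 39.80 both sides
  expect_equal(get("C")$discrepancy, 0, tolerance = 1e-9)
  expect_equal(get("C")$left, 14.06)
  expect_equal(get("N")$discrepancy, 0, tolerance = 1e-9)
  expect_equal(get("O")$discrepancy, 0, tolerance = 1e-9)
  # the printed equation is not balanced in H (21.09 vs 28.12) or charge
  expect_equal(get("H")$left, 21.09)
  expect_equal(get("H")$right, 28.12)
  expect_false(get("H")$balanced)
  expect_equal(get("charge")$left, -15.61)
  expect_equal(get("charge")$right, -8.58)
  # the acetate half reaction balances in everything, electrons included
  eq1 <- check_element_balance(acetate_oxidation(),
                               c("C", "H", "O", "charge"))
  expect_true(all(eq1$balanced))
  eq2 <- check_element_balance(nitrate_reduction(),
                               c("N", "H", "O", "charge"))
  expect_true(all(eq2$balanced))
  expect_error(parse_species("??"), "parse")
})

test_that("species parser handles ionic formulas", {
  p <- parse_species("CH3COO-")
  expect_equal(p$elements[["C"]], 2)
  expect_equal(p$elements[["H"]], 3)
  expect_equal(p$elements[["O"]], 2)
  expect_equal(p$charge, -1)
  expect_equal(parse_species("NO3-")$elements[["O"]], 3)
  expect_equal(parse_species("Fe^3+")$charge, 3)
  expect_equal(parse_species("C5H7O2N")$elements,
               c(C = 5, H = 7, O = 2, N = 1))
})

test_that("constants are overridable from a config file and validated", {
  st <- stoich_constants()
  expect_within(st$cod_per_g_sodium_acetate,
                1000 * 2 * st$mw_o2 / st$mw_sodium_acetate, 1e-9)
  expect_error(stoich_constants(mw_n = -1), "positive")
  cfgfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(mw_n = 14.007), cfgfile, auto_unbox = TRUE)
  st2 <- load_stoich_config(cfgfile)
  expect_equal(st2$mw_n, 14.007)
  # finer molar mass moves the critical ratio only in the third decimal
  r <- critical_cod_n_ratio(denitrifier_stoichiometry(), constants = st2)
  expect_within(r, critical_cod_n_ratio(denitrifier_stoichiometry()), 0.005)
  jsonlite::write_json(list(bogus = 1), cfgfile, auto_unbox = TRUE)
  expect_error(load_stoich_config(cfgfile), "unknown")
})
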