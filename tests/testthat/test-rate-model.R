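test_that("pure water gives pH 7 at pKw 14", {
  st <- solve_speciation(tibble::tibble(id = "w", pka = 9, conc_amine = 0),
                         thermo_constants())
  expect_equal(st$h, 1e-7, tolerance = 1e-6)
  expect_equal(st$oh, 1e-7, tolerance = 1e-6)
})

test_that("carbon-free weak base matches the closed-form OH concentration", {
  # Kb = 1e-5, C = 1 M: [OH-] ~ sqrt(Kb C) when Kb << C
  st <- solve_speciation(tibble::tibble(id = "b", pka = 9, conc_amine = 1),
                         thermo_constants())
  expect_equal(st$oh, sqrt(1e-5), tolerance = 0.01)
})

test_that("speciation satisfies all balances on 1000 random inputs", {
  set.seed(101)
  n <- 1000
  solvents <- tibble::tibble(id = as.character(seq_len(n)),
                             pka = runif(n, 6, 11),
                             conc_amine = runif(n, 0.01, 5))
  loads <- runif(n, 0, 1)
  constants <- thermo_constants()
  st <- solve_speciation(solvents, constants, carbon_load = loads)
  maxc <- pmax(st$h, st$oh, st$co2_aq, st$hco3, st$co3, st$amine_free,
               st$ammonium)
  expect_true(all(abs(st$charge_residual) <= 1e-10 * maxc))
  expect_true(all(abs(st$amine_free + st$ammonium - solvents$conc_amine) <=
                    1e-10 * solvents$conc_amine))
  expect_true(all(abs(st$co2_aq + st$hco3 + st$co3 -
                        loads * solvents$conc_amine) <=
                    1e-10 * pmax(loads * solvents$conc_amine, 1e-30)))
  expect_true(all(abs(st$h * st$oh - 1e-14) <= 1e-8 * 1e-14))
  expect_true(all(st$h >= 0 & st$oh >= 0 & st$co2_aq >= 0 & st$hco3 >= 0 &
                    st$co3 >= 0 & st$amine_free >= -1e-15 & st$ammonium >= 0))
})

test_that("bisection agrees with a uniroot oracle on the same residual", {
  constants <- thermo_constants()
  solv <- tibble::tibble(id = "x", pka = 9.7, conc_amine = 2.1)
  st <- solve_speciation(solv, constants, carbon_load = 0.4)
  kw <- 1e-14; ka <- 10^-9.7; k1 <- 10^-6.35; k2 <- 10^-10.33
  ct <- 0.4 * 2.1
  f <- function(ph) {
    h <- 10^-ph; oh <- kw / h
    amm <- 2.1 * h / (ka + h)
    co2 <- ct / (1 + k1 / h + k1 * k2 / h^2)
    hco3 <- co2 * k1 / h; co3 <- hco3 * k2 / h
    h + amm - oh - hco3 - 2 * co3
  }
  oracle <- stats::uniroot(f, c(0, 14), tol = 1e-14)$root
  expect_equal(st$ph, oracle, tolerance = 1e-9)
})

test_that("Henry mode fixes dissolved CO2 at H * pCO2", {
  constants <- thermo_constants()
  st <- solve_speciation(tibble::tibble(id = "x", pka = 9, conc_amine = 1),
                         constants, p_co2 = 1)
  expect_equal(st$co2_aq, 0.034)
})

test_that("zero-barrier rate reduces exactly to A [CO2][OH-]", {
  constants <- thermo_constants()
  solv <- tibble::tibble(id = "x", pka = 9.3, conc_amine = 1.5, dg3 = -40)
  st <- solve_speciation(solv, constants, p_co2 = 1)
  params <- rate_model_params(a = 0, b = 0, A_of_T = c("298.15" = 123.4))
  r <- absorption_rate(solv, st, params, constants)
  expect_identical(r$rate, 123.4 * st$co2_aq * st$oh)
})

test_that("a RT ln10 shift in dG3 changes the rate by exactly 10x", {
  constants <- thermo_constants()
  solv <- tibble::tibble(id = "x", pka = 9.3, conc_amine = 1.5, dg3 = -40)
  st <- solve_speciation(solv, constants, p_co2 = 1)
  params <- rate_model_params(a = 1, b = 5, A_of_T = c("298.15" = 1e6))
  shift <- constants$r_gas * constants$T_K * log(10) / 1000
  r1 <- absorption_rate(solv, st, params, constants)$rate
  solv2 <- dplyr::mutate(solv, dg3 = dg3 + shift)
  r2 <- absorption_rate(solv2, st, params, constants)$rate
  expect_equal(r1 / r2, 10, tolerance = 1e-12)
})

test_that("rate decreases strictly monotonically in dG3", {
  constants <- thermo_constants()
  dg3 <- seq(-60, 0, length.out = 25)
  solv <- tibble::tibble(id = as.character(seq_along(dg3)), pka = 9,
                         conc_amine = 1, dg3 = dg3)
  st <- solve_speciation(solv, constants, p_co2 = 1)
  params <- rate_model_params(a = 0.5, b = 2, A_of_T = c("298.15" = 1e6))
  r <- absorption_rate(solv, st, params, constants)$rate
  expect_true(all(diff(r) < 0))
})

test_that("rates at 313 K and 323 K are perfectly rank-correlated", {
  # temperature only rescales the barrier term, so ranks are preserved
  # exactly whenever the speciation and free-energy orderings are aligned:
  # (a) a dG3 sweep at fixed basicity, (b) an ensemble where dG3 decreases
  # with pKa (the structure of real amine sets)
  rate_at <- function(solv, Tk) {
    constants <- thermo_constants(T_K = Tk)
    st <- solve_speciation(solv, constants, p_co2 = 1)
    absorption_rate(solv, st,
                    rate_model_params(a = 0.5, b = 0,
                                      A_of_T = setNames(1e6, format(Tk))),
                    constants)$rate
  }
  sweep <- tibble::tibble(id = as.character(1:40), pka = 9, conc_amine = 1.5,
                          dg3 = seq(-70, -30, length.out = 40))
  r1 <- rate_at(sweep, 313.15); r2 <- rate_at(sweep, 323.15)
  expect_identical(rank(r1), rank(r2))
  expect_equal(cor(r1, r2, method = "spearman"), 1, tolerance = 1e-12)
  pka <- seq(6.5, 10.8, length.out = 40)
  ens <- tibble::tibble(id = as.character(1:40), pka = pka,
                        conc_amine = 1.5, dg3 = -45 - 2.6 * pka)
  e1 <- rate_at(ens, 313.15); e2 <- rate_at(ens, 323.15)
  expect_identical(rank(e1), rank(e2))
  expect_equal(cor(e1, e2, method = "spearman"), 1, tolerance = 1e-12)
})

test_that("dG5 closed form matches hand evaluation", {
  constants <- thermo_constants()  # 298.15 K, pKw 14
  fe <- absorption_free_energy(
    tibble::tibble(id = c("a", "b"), pka = c(9, 14), dg3 = c(-40, -40)),
    constants)
  expect_equal(fe$dg5[1], 8.314 * 298.15 * log(10) * 5 / 1000,
               tolerance = 1e-12)
  expect_equal(signif(fe$dg5[1], 4), 28.54)
  expect_equal(fe$dg5[2], 0)
  expect_equal(fe$dg4, fe$dg3 + fe$dg5)
  expect_equal(fe$dg4[1], -11.46, tolerance = 1e-3)
})

test_that("calibration inverts noiseless simulation to 1e-6 relative", {
  constants <- thermo_constants(T_K = 323.15)
  params <- rate_model_params(a = 0.5, b = 10, A_of_T = c("323.15" = 1e5))
  set.seed(11)
  solv <- tibble::tibble(id = as.character(1:8), pka = runif(8, 7, 10.5),
                         conc_amine = runif(8, 0.5, 3),
                         dg3 = seq(-70, -35, length.out = 8))
  st <- solve_speciation(solv, constants, p_co2 = 1)
  solv$rate <- absorption_rate(solv, st, params, constants)$rate
  cal <- calibrate_rate_model(solv, constants, A = 1e5, p_co2 = 1)
  expect_equal(cal$a, 0.5, tolerance = 1e-6)
  expect_equal(cal$b, 10, tolerance = 1e-6)
})

test_that("calibration tolerates 5% multiplicative noise within 10%", {
  constants <- thermo_constants(T_K = 323.15)
  params <- rate_model_params(a = 0.5, b = 10, A_of_T = c("323.15" = 1e5))
  set.seed(23)
  solv <- tibble::tibble(id = as.character(1:10), pka = runif(10, 7, 10.5),
                         conc_amine = runif(10, 0.5, 3),
                         dg3 = runif(10, -70, -35))
  st <- solve_speciation(solv, constants, p_co2 = 1)
  clean <- absorption_rate(solv, st, params, constants)$rate
  solv$rate <- clean * exp(rnorm(10, 0, 0.05))
  cal <- calibrate_rate_model(solv, constants, p_co2 = 1)
  expect_equal(cal$a, 0.5, tolerance = 0.1)
})

test_that("degenerate calibration designs are rejected", {
  solv <- tibble::tibble(id = as.character(1:4), pka = 9, conc_amine = 1,
                         dg3 = -40, rate = 1)
  expect_error(calibrate_rate_model(solv, thermo_constants()), "singular")
  expect_error(calibrate_rate_model(solv[1:2, ], thermo_constants()), ">= 3")
})

test_that("missing pre-exponential temperature errors unless interpolation on", {
  params <- rate_model_params(A_of_T = c("298.15" = 1e5, "323.15" = 1e6))
  expect_error(aminescreen:::preexponential_at(
    rate_model_params(A_of_T = c("298.15" = 1e5)), 310),
    "interpolation")
  # ln A linear in 1/T between the tabulated points
  A310 <- aminescreen:::preexponential_at(
    rate_model_params(A_of_T = c("298.15" = 1e5, "323.15" = 1e6),
                      interpolate_A = TRUE), 310.15)
  expect_gt(A310, 1e5); expect_lt(A310, 1e6)
})

test_that("rate_model_table reports endpoint transforms consistently", {
  out <- rate_model_table(
    tibble::tibble(id = "x", pka = 10, conc_amine = 1, dg3 = -60),
    rate_model_params(a = 0.5, A_of_T = c("298.15" = 1e6)),
    thermo_constants(), p_co2 = 1)
  expect_equal(out$neglog_rate, -log10(out$rate))
  expect_equal(out$neglog_dg4, -log10(-out$dg4))
})
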