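#' Thermodynamic constants for the aqueous CO2/amine system
#'
#' Defaults are the 298 K literature-standard values; every entry is
#' overridable to move the operating point (e.g. to 323 K). `pkw` is the
#' water autoionization constant, `pka1_co2`/`pka2_co2` the carbonic-acid
#' steps (CO2(aq) -> HCO3- -> CO3^2-) and `henry_co2` the Henry solubility
#' of CO2 in water.
#'
#' @param T_K absolute temperature, K.
#' @param pkw water autoionization pK.
#' @param pka1_co2,pka2_co2 carbonate pK values.
#' @param henry_co2 Henry constant, mol L^-1 bar^-1.
#' @return a `thermo_constants` list; `r_gas` is fixed at 8.314 J mol^-1 K^-1.
#' @export
thermo_constants <- function(T_K = 298.15, pkw = 14.0, pka1_co2 = 6.35,
                             pka2_co2 = 10.33, henry_co2 = 0.034) {
  stopifnot(T_K > 0, is.finite(pkw), is.finite(pka1_co2), is.finite(pka2_co2),
            henry_co2 > 0)
  structure(list(T_K = T_K, r_gas = 8.314, pkw = pkw, pka1_co2 = pka1_co2,
                 pka2_co2 = pka2_co2, henry_co2 = henry_co2),
            class = "thermo_constants")
}

#' Operating-point preset: 13 mol% amine
#'
#' Converts an amine mole fraction to mol L^-1 assuming a configurable
#' solution density and that the balance of the solution is water. The
#' industrial-absorption operating point used throughout the package is
#' 13 mol% amine at 323 K.
#'
#' @param mol_pct amine mole percent.
#' @param mw_amine amine molar mass, g/mol.
#' @param density_kg_L solution density, kg/L.
#' @return amine concentration, mol L^-1.
#' @export
amine_conc_from_molpct <- function(mol_pct, mw_amine, density_kg_L = 1.0) {
  x <- mol_pct / 100
  mass_per_mol <- x * mw_amine + (1 - x) * 18.015   # g per mole of solution
  1000 * density_kg_L * x / mass_per_mol
}

#' Solve aqueous speciation for amine solvents
#'
#' For each amine solvent, solves the coupled acid-base equilibria (water
#' autoionization, amine protonation, CO2/HCO3-/CO3^2-) together with the
#' amine mass balance, a carbon constraint and charge balance, by bracketed
#' bisection on pH of the monotone charge-balance residual.
#'
#' Two carbon modes are supported: `p_co2` fixes dissolved CO2 via Henry's
#' law (initial-rate regime, the default when `p_co2` is given), while
#' `carbon_load` imposes total dissolved carbon as mol CO2 per mol amine.
#'
#' @param solvents data frame with columns `id`, `pka`, `conc_amine`
#'   (mol L^-1).
#' @param constants a [thermo_constants()].
#' @param carbon_load mol CO2 per mol amine (total-carbon mode).
#' @param p_co2 CO2 partial pressure, bar (Henry mode); overrides
#'   `carbon_load` when non-NULL.
#' @param tol_ph pH half-interval at which bisection stops.
#' @return a tibble: `id`, `ph`, `h`, `oh`, `co2_aq`, `hco3`, `co3`,
#'   `amine_free`, `ammonium`, `charge_residual` (all concentrations
#'   mol L^-1).
#' @examples
#' solve_speciation(tibble::tibble(id = "w", pka = 9, conc_amine = 0),
#'                  thermo_constants())
#' @export
solve_speciation <- function(solvents, constants = thermo_constants(),
                             carbon_load = 0, p_co2 = NULL, tol_ph = 1e-13) {
  stopifnot(is.data.frame(solvents),
            all(c("id", "pka", "conc_amine") %in% names(solvents)))
  if (any(solvents$conc_amine < 0)) abort("`conc_amine` must be >= 0")
  if (any(solvents$pka <= 0 | solvents$pka >= constants$pkw)) {
    abort("`pka` must lie in (0, pkw)")
  }
  if (is.null(p_co2) && any(carbon_load < 0)) abort("`carbon_load` must be >= 0")
  n <- nrow(solvents)
  load <- if (length(carbon_load) == 1L) rep(carbon_load, n) else carbon_load
  rows <- purrr::map(seq_len(n), function(i) {
    speciate_one(solvents$id[i], solvents$pka[i], solvents$conc_amine[i],
                 constants, load[i], p_co2, tol_ph)
  })
  dplyr::bind_rows(rows)
}

speciate_one <- function(id, pka, conc_amine, constants, carbon_load, p_co2,
                         tol_ph) {
  kw <- 10^(-constants$pkw)
  ka <- 10^(-pka)
  k1 <- 10^(-constants$pka1_co2)
  k2 <- 10^(-constants$pka2_co2)
  co2_fixed <- if (!is.null(p_co2)) constants$henry_co2 * p_co2 else NULL
  ct <- carbon_load * conc_amine

  species <- function(ph) {
    h <- 10^(-ph)
    oh <- kw / h
    ammonium <- conc_amine * h / (ka + h)
    if (!is.null(co2_fixed)) {
      co2 <- co2_fixed
      hco3 <- co2 * k1 / h
      co3 <- hco3 * k2 / h
    } else {
      denom <- 1 + k1 / h + k1 * k2 / h^2
      co2 <- ct / denom
      hco3 <- co2 * k1 / h
      co3 <- hco3 * k2 / h
    }
    list(h = h, oh = oh, co2 = co2, hco3 = hco3, co3 = co3,
         ammonium = ammonium, amine_free = conc_amine - ammonium)
  }
  residual <- function(ph) {
    s <- species(ph)
    s$h + s$ammonium - s$oh - s$hco3 - 2 * s$co3
  }

  lo <- 0; hi <- constants$pkw
  flo <- residual(lo); fhi <- residual(hi)
  if (!(flo > 0 && fhi < 0)) {
    abort(paste0("no sign change of the charge-balance residual on pH [0, ",
                 constants$pkw, "] for id '", id, "': f(0) = ",
                 signif(flo, 4), ", f(pkw) = ", signif(fhi, 4)))
  }
  while ((hi - lo) / 2 > tol_ph) {
    mid <- (lo + hi) / 2
    if (residual(mid) > 0) lo <- mid else hi <- mid
  }
  ph <- (lo + hi) / 2
  s <- species(ph)
  tibble::tibble(
    id = id, ph = ph, h = s$h, oh = s$oh, co2_aq = s$co2, hco3 = s$hco3,
    co3 = s$co3, amine_free = s$amine_free, ammonium = s$ammonium,
    charge_residual = residual(ph)
  )
}

#' Rate-model parameters
#'
#' The linear free-energy (Polanyi-Evans) barrier slope `a` and intercept
#' `b` (kJ mol^-1), plus the temperature-tabulated pre-exponential factor
#' `A(T)`. The numeric values used in production runs come from calibration
#' against measured rates ([calibrate_rate_model()]); the defaults
#' (`a = 0.5`, `b = 0`, `A = 1`) are placeholders that preserve ordering,
#' not fitted constants.
#'
#' @param a unitless barrier slope.
#' @param b barrier intercept, kJ mol^-1.
#' @param A_of_T named numeric vector of pre-exponential factors keyed by
#'   temperature ("298.15" etc.), rate units x L^2 mol^-2.
#' @param interpolate_A allow ln A vs 1/T linear interpolation between
#'   tabulated temperatures?
#' @return a `rate_model_params` list.
#' @export
rate_model_params <- function(a = 0.5, b = 0, A_of_T = c("298.15" = 1),
                              interpolate_A = FALSE) {
  stopifnot(is.finite(a), is.finite(b), all(A_of_T > 0))
  structure(list(a = a, b = b, A_of_T = A_of_T,
                 interpolate_A = interpolate_A),
            class = "rate_model_params")
}

preexponential_at <- function(params, T_K) {
  key <- format(T_K)
  temps <- as.numeric(names(params$A_of_T))
  hit <- which(abs(temps - T_K) < 1e-9)
  if (length(hit) >= 1L) return(unname(params$A_of_T[hit[1]]))
  if (!params$interpolate_A) {
    abort(paste0("no pre-exponential factor tabulated at T = ", key,
                 " K and interpolation is disabled"))
  }
  if (length(temps) < 2L) abort("interpolation needs >= 2 tabulated temperatures")
  ln_A <- stats::approx(1 / temps, log(params$A_of_T), xout = 1 / T_K,
                        rule = 2)$y
  exp(ln_A)
}

#' Absorption rate from the speciation-coupled rate law
#'
#' rate = A(T) exp(-(a dG3 + b) / RT) [CO2][OH-], with the barrier from the
#' Polanyi-Evans relation on the solvation free-energy difference `dg3`
#' (OH- + CO2 vs HCO3-, kJ mol^-1).
#'
#' @param solvents data frame with columns `id`, `dg3` (kJ mol^-1).
#' @param state speciation tibble from [solve_speciation()], matched by `id`.
#' @param params a [rate_model_params()].
#' @param constants a [thermo_constants()].
#' @return input tibble plus `dg_barrier` (kJ mol^-1) and `rate`.
#' @export
absorption_rate <- function(solvents, state, params = rate_model_params(),
                            constants = thermo_constants()) {
  stopifnot(all(c("id", "dg3") %in% names(solvents)))
  joined <- dplyr::left_join(tibble::as_tibble(solvents)[, c("id", "dg3")],
                             state[, c("id", "co2_aq", "oh")], by = "id")
  if (anyNA(joined$co2_aq)) abort("speciation state missing for some ids")
  A <- preexponential_at(params, constants$T_K)
  rt <- constants$r_gas * constants$T_K
  dg_barrier <- params$a * joined$dg3 + params$b
  joined$dg_barrier <- dg_barrier
  joined$rate <- A * exp(-dg_barrier * 1000 / rt) * joined$co2_aq * joined$oh
  joined
}

#' Free energy of absorption from pKa and the solvation difference
#'
#' The overall absorption reaction (amine + H2O + CO2 -> ammonium + HCO3-)
#' decomposes into OH- + CO2 -> HCO3- (free energy `dg3`, supplied, e.g.
#' from solvation simulations) and amine + H2O -> ammonium + OH- (free
#' energy `dg5`, fixed by the amine pKa):
#' dG5 = RT ln(10) (pKw - pKa) / 1000 kJ mol^-1, and dG4 = dG3 + dG5.
#'
#' @param solvents data frame with columns `id`, `pka`, `dg3`.
#' @param constants a [thermo_constants()].
#' @return tibble: `id`, `dg3`, `dg5`, `dg4` (kJ mol^-1).
#' @export
absorption_free_energy <- function(solvents, constants = thermo_constants()) {
  stopifnot(all(c("id", "pka", "dg3") %in% names(solvents)))
  rt <- constants$r_gas * constants$T_K
  dg5 <- rt * log(10) * (constants$pkw - solvents$pka) / 1000
  tibble::tibble(id = solvents$id, dg3 = solvents$dg3, dg5 = dg5,
                 dg4 = solvents$dg3 + dg5)
}

#' Calibrate the Polanyi-Evans slope against observed rates
#'
#' Fits ln(rate) - ln([CO2][OH-]) = ln A - (a dG3 + b) 1000 / RT by least
#' squares in dG3. At a single temperature only the slope `a` and the
#' combined intercept c(T) = ln A - b 1000 / RT are identifiable; `b` is
#' resolved when `A` is supplied.
#'
#' @param reference data frame with columns `id`, `pka`, `conc_amine`,
#'   `dg3`, `rate` (> 0), all at the temperature of `constants`.
#' @param constants a [thermo_constants()].
#' @param A known pre-exponential factor, or NULL.
#' @param ... passed to [solve_speciation()] (carbon mode).
#' @return object of class `rate_calibration`: `a`, `intercept` (= ln A -
#'   b 1000/RT), `b` (NA unless `A` given), `A`, `fit` (the lm), `n`.
#' @export
calibrate_rate_model <- function(reference, constants = thermo_constants(),
                                 A = NULL, ...) {
  stopifnot(all(c("id", "pka", "conc_amine", "dg3", "rate") %in% names(reference)))
  if (nrow(reference) < 3L) abort("calibration needs >= 3 reference solvents")
  if (any(reference$rate <= 0)) abort("reference rates must be > 0")
  if (stats::sd(reference$dg3) == 0) {
    abort("singular calibration: all dG3 values are identical")
  }
  state <- solve_speciation(reference, constants, ...)
  y <- log(reference$rate) - log(state$co2_aq * state$oh)
  fit <- stats::lm(y ~ dg3, data = data.frame(y = y, dg3 = reference$dg3))
  rt <- constants$r_gas * constants$T_K
  a <- -unname(coef(fit)[2]) * rt / 1000
  intercept <- unname(coef(fit)[1])
  b <- if (!is.null(A)) (log(A) - intercept) * rt / 1000 else NA_real_
  structure(list(a = a, intercept = intercept, b = b, A = A, fit = fit,
                 n = nrow(reference), T_K = constants$T_K),
            class = "rate_calibration")
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat("Polanyi-Evans calibration (", x$n, " solvents, T = ", x$T_K, " K)\n",
      "  a = ", signif(x$a, 6), "\n",
      "  intercept ln A - 1000 b/RT = ", signif(x$intercept, 6), "\n", sep = "")
  if (!is.na(x$b)) cat("  b = ", signif(x$b, 6), " kJ/mol (A supplied)\n", sep = "")
  invisible(x)
}

#' Run the full rate model over a solvent table
#'
#' Convenience wrapper: speciation, rate and free energies in one call,
#' including the QSPR endpoint transforms -log10(rate) and -log10(-dG4)
#' (the latter NA when dG4 >= 0).
#'
#' @param solvents data frame with `id`, `pka`, `conc_amine`, `dg3`.
#' @param params a [rate_model_params()].
#' @param constants a [thermo_constants()].
#' @param ... carbon mode, passed to [solve_speciation()].
#' @return tibble with speciation, `rate`, `dg3`, `dg5`, `dg4`,
#'   `neglog_rate`, `neglog_dg4`.
#' @export
rate_model_table <- function(solvents, params = rate_model_params(),
                             constants = thermo_constants(), ...) {
  state <- solve_speciation(solvents, constants, ...)
  rates <- absorption_rate(solvents, state, params, constants)
  fe <- absorption_free_energy(solvents, constants)
  out <- dplyr::left_join(state, rates[, c("id", "dg_barrier", "rate")], by = "id")
  out <- dplyr::left_join(out, fe, by = "id")
  out$neglog_rate <- -log10(out$rate)
  out$neglog_dg4 <- ifelse(out$dg4 < 0, -log10(-out$dg4), NA_real_)
  out
}
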