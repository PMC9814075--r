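#' Extract r(CO2) from a pressure-decay trace
#'
#' The absorption rate metric of a constant-interfacial-area (Lewis cell)
#' experiment: the slope of the CO2 partial-pressure curve at the time at
#' which half of the absorbable CO2 (relative to the equilibrium plateau)
#' has transferred to the liquid. The initial pressure is the first sample,
#' the equilibrium pressure the mean of the final `k_tail` samples; the 50%
#' crossing is located by linear interpolation and the slope estimated by a
#' symmetric least-squares window around it (noise-robust compared to a raw
#' finite difference).
#'
#' @param trace data frame with columns `time_s` (strictly increasing) and
#'   `p_co2_bar`.
#' @param window half-width of the regression window in samples.
#' @param k_tail number of tail samples averaged into the plateau.
#' @param noise_tol relative tolerance for the monotonicity / plateau-drift
#'   checks.
#' @param p_eq known equilibrium pressure, bar; when NULL (default) it is
#'   estimated as the tail plateau mean.
#' @return object of class `rco2_fit`: `rate_bar_s` (|dP/dt|, positive),
#'   `t50`, `p0`, `p_eq`, `window_fit` (the lm), `trace`.
#' @export
rco2_slope <- function(trace, window = 5L, k_tail = 10L, noise_tol = 0.01,
                       p_eq = NULL) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "p_co2_bar") %in% names(trace)))
  t <- trace$time_s
  p <- trace$p_co2_bar
  if (length(t) < 5L) abort("trace needs at least 5 samples")
  if (any(diff(t) <= 0)) abort("`time_s` must be strictly increasing")
  k_tail <- min(k_tail, length(p))
  p0 <- p[1]
  if (is.null(p_eq)) {
    tail_p <- p[seq.int(length(p) - k_tail + 1L, length(p))]
    p_eq <- mean(tail_p)
    if (p0 <= p_eq) abort("trace does not decay: p0 <= p_eq")
    drift <- (max(tail_p) - min(tail_p)) / (p0 - p_eq)
    if (drift > 10 * noise_tol) {
      warn(paste0("tail of the trace is not a plateau (relative drift ",
                  signif(drift, 3), "); p_eq may be unreliable"))
    }
  }
  if (p0 <= p_eq) abort("trace does not decay: p0 <= p_eq")
  rises <- diff(p) > noise_tol * (p0 - p_eq)
  if (any(rises)) {
    warn("trace is non-monotone beyond noise tolerance; proceeding best-effort")
  }
  frac <- (p0 - p) / (p0 - p_eq)
  cross <- which(frac >= 0.5)
  if (length(cross) == 0L) abort("trace never reaches 50% absorption")
  j <- cross[1]
  if (j <= 2L) {
    abort("50% absorption is crossed between the first two samples; sampling too sparse")
  }
  t50 <- t[j - 1L] + (0.5 - frac[j - 1L]) / (frac[j] - frac[j - 1L]) *
    (t[j] - t[j - 1L])
  center <- which.min(abs(t - t50))
  idx <- seq.int(max(1L, center - window), min(length(t), center + window))
  fit <- stats::lm(p ~ t, data = data.frame(t = t[idx], p = p[idx]))
  structure(list(rate_bar_s = abs(unname(coef(fit)[2])), t50 = t50, p0 = p0,
                 p_eq = p_eq, window_fit = fit, trace = tibble::as_tibble(trace)),
            class = "rco2_fit")
}

#' @export
print.rco2_fit <- function(x, ...) {
  cat("r(CO2) = ", signif(x$rate_bar_s, 6), " bar/s at t50 = ",
      signif(x$t50, 6), " s (p0 = ", x$p0, ", p_eq = ", signif(x$p_eq, 6),
      " bar)\n", sep = "")
  invisible(x)
}

#' Lewis-cell configuration
#'
#' Geometry, operating conditions and the vapor-phase equation of state of
#' a constant-interfacial-area absorption cell. The EOS is pluggable: any
#' `function(T_K, P_bar)` returning a molar density in mol/L. The default
#' is the ideal gas; a compressibility correction can be layered on top.
#'
#' @param v_total_L total cell volume, L.
#' @param t_cell_K cell temperature, K.
#' @param solvent_moles moles of solvent introduced.
#' @param solvent_molar_density_molL solvent molar density at `t_cell_K`,
#'   mol/L.
#' @param p_sat_solvent_bar solvent saturation pressure, bar.
#' @param r_cell_m cell radius, m (optional; enables interface height).
#' @param eos vapor-density model, mol/L.
#' @return a `cell_config` list.
#' @export
cell_config <- function(v_total_L, t_cell_K, solvent_moles,
                        solvent_molar_density_molL, p_sat_solvent_bar = 0,
                        r_cell_m = NULL, eos = eos_ideal_gas) {
  stopifnot(v_total_L > 0, t_cell_K > 0, solvent_moles >= 0,
            solvent_molar_density_molL > 0)
  v_liq <- solvent_moles / solvent_molar_density_molL
  if (v_liq >= v_total_L) abort("liquid volume exceeds the cell volume")
  structure(list(v_total_L = v_total_L, t_cell_K = t_cell_K,
                 solvent_moles = solvent_moles,
                 solvent_molar_density_molL = solvent_molar_density_molL,
                 p_sat_solvent_bar = p_sat_solvent_bar, r_cell_m = r_cell_m,
                 eos = eos),
            class = "cell_config")
}

#' Ideal-gas vapor density
#'
#' rho = P / (R T), returned in mol/L.
#'
#' @param T_K temperature, K.
#' @param P_bar pressure, bar.
#' @return molar density, mol/L.
#' @export
eos_ideal_gas <- function(T_K, P_bar) {
  (P_bar * 1e5) / (8.314 * T_K) / 1000
}

#' Compressibility-corrected EOS from a Z table
#'
#' Wraps the ideal gas with an interpolated compressibility factor
#' Z(P): rho = P / (Z R T).
#'
#' @param p_bar,z aligned vectors tabulating Z against pressure.
#' @return an EOS function for [cell_config()].
#' @export
eos_z_table <- function(p_bar, z) {
  stopifnot(length(p_bar) == length(z), all(z > 0))
  function(T_K, P_bar) {
    zz <- stats::approx(p_bar, z, xout = P_bar, rule = 2)$y
    eos_ideal_gas(T_K, P_bar) / zz
  }
}

#' Solubility from the cell mass balance
#'
#' Liquid volume from the solvent moles and molar density, vapor volume by
#' difference, vapor-phase solute moles from the EOS density at the solute
#' partial pressure (cell pressure minus solvent saturation pressure), and
#' liquid-phase moles by conservation. For gas mixtures, per-species liquid
#' moles follow from the global composition `z` and vapor composition `y`.
#'
#' @param cell a [cell_config()].
#' @param n_total_solute total solute moles introduced.
#' @param p_cell_bar cell pressure, bar.
#' @param z,y optional named numeric vectors (summing to 1) of global and
#'   vapor compositions for mixtures.
#' @return tibble: `v_liq_L`, `v_vap_L`, `n_vapor`, `n_liquid`, `n_total`,
#'   `x_solute` (liquid mole fraction over solvent + solute), `h_liq_m`
#'   (when the cell radius is set), plus a `species` list-column for
#'   mixtures.
#' @export
solubility_from_balance <- function(cell, n_total_solute, p_cell_bar,
                                    z = NULL, y = NULL) {
  stopifnot(inherits(cell, "cell_config"), n_total_solute >= 0)
  p_solute <- p_cell_bar - cell$p_sat_solvent_bar
  if (p_solute <= 0) abort("solute partial pressure is <= 0")
  v_liq <- cell$solvent_moles / cell$solvent_molar_density_molL
  v_vap <- cell$v_total_L - v_liq
  rho_v <- cell$eos(cell$t_cell_K, p_solute)
  n_vapor <- v_vap * rho_v
  if (n_vapor > n_total_solute) {
    abort(paste0("vapor phase alone holds ", signif(n_vapor, 6),
                 " mol > n_total = ", n_total_solute,
                 " mol: inconsistent inputs"))
  }
  n_liquid <- n_total_solute - n_vapor
  species <- NULL
  if (!is.null(z)) {
    if (is.null(y)) abort("mixture mode needs both `z` and `y`")
    stopifnot(abs(sum(z) - 1) < 1e-8, abs(sum(y) - 1) < 1e-8,
              identical(sort(names(z)), sort(names(y))))
    n_l_i <- z[names(z)] * n_total_solute - y[names(z)] * n_vapor
    liq_moles <- c(n_l_i, solvent = cell$solvent_moles)
    species <- tibble::tibble(species = names(liq_moles),
                              n_liquid = unname(liq_moles),
                              x = unname(liq_moles) / sum(liq_moles))
  }
  out <- tibble::tibble(
    v_liq_L = v_liq, v_vap_L = v_vap, n_vapor = n_vapor,
    n_liquid = n_liquid, n_total = n_total_solute,
    x_solute = n_liquid / (cell$solvent_moles + n_liquid),
    h_liq_m = if (!is.null(cell$r_cell_m)) interface_height(cell) else NA_real_
  )
  if (!is.null(species)) out$species <- list(species)
  out
}

#' Liquid interface height of a cylindrical cell
#'
#' h = V_L / (pi r^2), with the liquid volume from the solvent moles and
#' molar density (liters converted to cubic meters).
#'
#' @param cell a [cell_config()] with `r_cell_m` set.
#' @return interface height, m.
#' @export
interface_height <- function(cell) {
  stopifnot(inherits(cell, "cell_config"))
  if (is.null(cell$r_cell_m) || cell$r_cell_m <= 0) {
    abort("`r_cell_m` must be set and positive")
  }
  v_liq_m3 <- cell$solvent_moles / cell$solvent_molar_density_molL / 1000
  v_liq_m3 / (pi * cell$r_cell_m^2)
}
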