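# Scaffold-and-substituent assembly of tertiary amines. Every template
# places exactly one tertiary nitrogen; substituents are drawn from an
# alphabet of saturated chains, hydroxylated chains and one thioether, so
# the emitted molecules satisfy the structural screening rules (no double
# bonds, aromatics, 1/2-amines, ketones or forbidden sulfur) by
# construction.
synthetic_scaffolds <- list(
  acyclic = list(template = "N(%s)(%s)%s", n_sub = 3L, pka_base = 9.8),
  piperidine = list(template = "N1(%s)CCCCC1", n_sub = 1L, pka_base = 10.2),
  piperidinol = list(template = "N1(%s)CCC(O)CC1", n_sub = 1L, pka_base = 9.7),
  pyrrolidine = list(template = "N1(%s)CCCC1", n_sub = 1L, pka_base = 10.4),
  pyrrolidinol = list(template = "N1(%s)CCC(O)C1", n_sub = 1L, pka_base = 9.9)
)

synthetic_substituents <- tibble::tibble(
  smiles = c("C", "CC", "CCC", "CCCC", "CCO", "CCCO", "CCCCO", "CC(C)O",
             "CC(O)CO", "CCOC", "CCSC", "CCSCC"),
  n_carbon = c(1, 2, 3, 4, 2, 3, 4, 3, 3, 3, 3, 4),
  n_oh = c(0, 0, 0, 0, 1, 1, 1, 1, 2, 0, 0, 0),
  thioether = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE, TRUE, TRUE)
)

#' Generate a synthetic tertiary-amine library with mechanistic truth
#'
#' Assembles amines from ring/chain scaffolds and a substituent alphabet,
#' then attaches a mechanistically consistent truth table: pKa from
#' scaffold base values plus substituent increments (hydroxyls and the
#' thioether lower basicity) with Gaussian noise, clipped to [6, 11]; the
#' solvation free-energy difference dG3 as an affine decreasing function of
#' pKa plus small structural terms and noise (so dG3 rises as pKa falls);
#' and the true absorption rate and absorption free energy dG4 computed
#' through the package's own rate model at the 13 mol% / 323 K operating
#' point. On the generated ensemble Spearman(rate, dG4) <= -0.9 is
#' asserted at generation time (slow absorbers have high absorption free
#' energy).
#'
#' @param n_compounds library size.
#' @param seed integer seed; output is deterministic given the seed.
#' @param mw_max molecular-weight cap, g/mol.
#' @param pka_noise_sd,dg3_noise_sd Gaussian noise levels of the property
#'   model.
#' @param params rate-model parameters used for the truth rates.
#' @param constants thermodynamic constants of the operating point.
#' @param scaffold_weights named sampling weights over the scaffold set.
#' @return list: `library` (tibble id, smiles), `truth` (tibble id, smiles,
#'   scaffold, pka, dg3, rate, dg4, neglog_rate, neglog_dg4),
#'   `spearman_rate_dg4`.
#' @export
generate_library <- function(n_compounds = 150L, seed = 7L, mw_max = 250,
                             pka_noise_sd = 0.15, dg3_noise_sd = 0.35,
                             params = rate_model_params(A_of_T = c("323.15" = 1e6)),
                             constants = thermo_constants(T_K = 323.15),
                             scaffold_weights = c(acyclic = 0.4,
                                                  piperidine = 0.15,
                                                  piperidinol = 0.15,
                                                  pyrrolidine = 0.15,
                                                  pyrrolidinol = 0.15)) {
  stopifnot(n_compounds >= 1L)
  scaffold_weights <- scaffold_weights[names(synthetic_scaffolds)]
  set.seed(seed)
  seen <- character()
  rows <- list()
  attempts <- 0L
  while (length(rows) < n_compounds) {
    attempts <- attempts + 1L
    if (attempts > 60L * n_compounds) {
      abort("library generation did not converge; constraints too tight")
    }
    scaf_name <- sample(names(synthetic_scaffolds), 1L,
                        prob = scaffold_weights)
    scaf <- synthetic_scaffolds[[scaf_name]]
    subs <- synthetic_substituents[
      sample(nrow(synthetic_substituents), scaf$n_sub, replace = TRUE), ]
    smiles <- do.call(sprintf, c(list(scaf$template), as.list(subs$smiles)))
    can <- ob_canonical_smiles(smiles)
    if (is.na(can) || can %in% seen) next
    props <- ob_properties(can)
    if (props$mw > mw_max) next
    # at most one thioether arm keeps the chemistry plausible
    if (sum(subs$thioether) > 1L) next
    seen <- c(seen, can)
    ring <- scaf_name != "acyclic"
    ring_oh <- scaf_name %in% c("piperidinol", "pyrrolidinol")
    n_oh <- sum(subs$n_oh) + as.integer(ring_oh)
    pka <- scaf$pka_base - 0.55 * n_oh - 0.35 * sum(subs$thioether) +
      0.05 * sum(subs$n_carbon) + rnorm(1L, 0, pka_noise_sd)
    pka <- min(max(pka, 6), 11)
    # offset keeps dG4 = dG3 + dG5 < 0 over the whole pKa range (absorption
    # exergonic), since dG5 ~= 6.19 (14 - pKa) kJ/mol at 323 K
    dg3 <- -45 - 2.6 * pka + 0.6 * ring + 0.4 * n_oh +
      rnorm(1L, 0, dg3_noise_sd)
    rows <- c(rows, list(tibble::tibble(
      id = sprintf("syn%03d", length(rows) + 1L), smiles = can,
      scaffold = scaf_name, pka = pka, dg3 = dg3, mw = props$mw
    )))
  }
  truth <- dplyr::bind_rows(rows)
  truth$conc_amine <- amine_conc_from_molpct(13, truth$mw)
  model <- rate_model_table(truth, params, constants, p_co2 = 1)
  truth <- dplyr::left_join(
    truth, model[, c("id", "rate", "dg4", "neglog_rate", "neglog_dg4")],
    by = "id"
  )
  rho <- stats::cor(truth$rate, truth$dg4, method = "spearman")
  if (rho > -0.9) {
    abort(paste0("generated ensemble violates the rate/dG4 anticorrelation: ",
                 "Spearman ", signif(rho, 3)))
  }
  list(library = truth[, c("id", "smiles")], truth = truth,
       spearman_rate_dg4 = rho)
}

#' Generate a synthetic kinetic pressure trace
#'
#' Exponential relaxation p(t) = p_eq + (p0 - p_eq) exp(-k t) with optional
#' seeded Gaussian noise, emulating the pressure decay of a Lewis-cell
#' absorption run. The analytic slope at 50% absorption,
#' r(CO2) = k (p0 - p_eq) / 2, is returned as truth.
#'
#' @param p0,p_eq initial and equilibrium CO2 partial pressures, bar
#'   (`p0 > p_eq`).
#' @param k relaxation constant, 1/s.
#' @param t_max trace duration, s (default: 10 relaxation times).
#' @param n_points number of samples.
#' @param noise_sd Gaussian noise standard deviation, bar.
#' @param seed integer seed for the noise.
#' @return list: `trace` (tibble time_s, p_co2_bar), `rate_true` (bar/s),
#'   `t50_true` (s).
#' @export
generate_trace <- function(p0 = 2, p_eq = 1, k = 0.01, t_max = 10 / k,
                           n_points = 500L, noise_sd = 0, seed = 1L) {
  stopifnot(p0 > p_eq, k > 0, n_points >= 5L)
  t <- seq(0, t_max, length.out = n_points)
  p <- p_eq + (p0 - p_eq) * exp(-k * t)
  if (noise_sd > 0) {
    set.seed(seed)
    p <- p + rnorm(n_points, 0, noise_sd)
  }
  list(trace = tibble::tibble(time_s = t, p_co2_bar = p),
       rate_true = k * (p0 - p_eq) / 2, t50_true = log(2) / k)
}
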