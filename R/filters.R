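#' Screening filter configuration
#'
#' The structural and physicochemical rules used to build a tertiary-amine
#' screening library: molecular weight cap, calculated logP window, a
#' required tertiary-amine center, and bans on double bonds, aromatic rings,
#' primary/secondary amines, ketones and sulfur other than thiols/thioethers.
#'
#' Substructure rules are SMARTS patterns and can be edited. The tertiary
#' amine is a trivalent non-aromatic nitrogen with three carbon neighbors,
#' no attached hydrogen and not part of an amide; amide/ester carbonyls do
#' not count as ketones; the "double bond" rule covers non-aromatic C=C,
#' C=N and N=N only, so carbonyls are handled solely by the ketone rule.
#'
#' @param mw_max maximum molecular weight, g/mol.
#' @param clogp_min,clogp_max allowed calculated logP window.
#' @param clogp_enabled apply the logP rule? Disable to make verdicts
#'   independent of the logP estimator.
#' @param patterns named list of SMARTS patterns overriding the defaults.
#' @return a `filter_config` list.
#' @export
filter_config <- function(mw_max = 250, clogp_min = -1, clogp_max = 1,
                          clogp_enabled = TRUE, patterns = list()) {
  default_patterns <- list(
    tertiary_amine = "[NX3;H0;!$([N]=*);!$(N[CX3]=[OX1])]([#6])([#6])[#6]",
    double_bond = c("C=C", "C=N", "N=N"),
    aromatic_ring = "a",
    primary_secondary_amine = c(
      "[NX3;H2;!$([NX3][CX3]=[OX1])]",
      "[NX3;H1;!$([NX3][CX3]=[OX1]);!$([NX3]=*)]"
    ),
    ketone = "[#6][CX3](=[OX1])[#6]",
    forbidden_sulfur = "[#16;!$([SX2H1]);!$([SX2]([#6])[#6])]"
  )
  structure(
    list(
      mw_max = mw_max, clogp_min = clogp_min, clogp_max = clogp_max,
      clogp_enabled = clogp_enabled,
      patterns = utils::modifyList(default_patterns, patterns)
    ),
    class = "filter_config"
  )
}

filter_rule_names <- c(
  "mw", "clogp", "no_tertiary_amine", "double_bond", "aromatic_ring",
  "primary_secondary_amine", "ketone", "forbidden_sulfur"
)

#' Apply the screening filters to standardized molecules
#'
#' Every rule is evaluated for every molecule (no short-circuiting), so the
#' report lists the complete set of violations.
#'
#' @param standardized a data frame as returned by [standardize_library()]
#'   (columns `id`, `smiles_std`, `mw`, `clogp`).
#' @param rules a [filter_config()].
#' @return a tibble with columns `id`, `passed` and `failed_rules`
#'   (list-column of rule names drawn from the fixed vocabulary).
#' @export
screen_filters <- function(standardized, rules = filter_config()) {
  stopifnot(is.data.frame(standardized),
            all(c("id", "smiles_std", "mw", "clogp") %in% names(standardized)))
  rows <- purrr::pmap(
    list(standardized$id, standardized$smiles_std,
         standardized$mw, standardized$clogp),
    function(id, smi, mw, clogp) {
      failed <- character()
      if (mw > rules$mw_max) failed <- c(failed, "mw")
      if (rules$clogp_enabled && (clogp < rules$clogp_min || clogp > rules$clogp_max)) {
        failed <- c(failed, "clogp")
      }
      match_any <- function(pats) any(vapply(pats, function(p)
        ob_smarts_count(smi, p) > 0, logical(1)))
      if (!match_any(rules$patterns$tertiary_amine)) {
        failed <- c(failed, "no_tertiary_amine")
      }
      if (match_any(rules$patterns$double_bond)) failed <- c(failed, "double_bond")
      if (match_any(rules$patterns$aromatic_ring)) failed <- c(failed, "aromatic_ring")
      if (match_any(rules$patterns$primary_secondary_amine)) {
        failed <- c(failed, "primary_secondary_amine")
      }
      if (match_any(rules$patterns$ketone)) failed <- c(failed, "ketone")
      if (match_any(rules$patterns$forbidden_sulfur)) {
        failed <- c(failed, "forbidden_sulfur")
      }
      tibble::tibble(id = id, passed = length(failed) == 0L,
                     failed_rules = list(failed))
    }
  )
  dplyr::bind_rows(rows)
}

#' Standardize and filter a raw molecule library
#'
#' Runs [standardize_library()] then [screen_filters()], keeping unparseable
#' entries in the report (counted separately, never silently dropped).
#'
#' @inheritParams standardize_library
#' @param rules a [filter_config()].
#' @return a list with `standardized` (parseable molecules), `reports`
#'   (filter verdicts joined with standardization columns) and `summary`
#'   (tibble: n_input, n_unparseable, n_passed, n_failed).
#' @export
filter_library <- function(library, rules = filter_config()) {
  check_library_frame(library)
  std <- standardize_library(library)
  ok <- std[is.na(std$parse_error), ]
  if (nrow(ok) > 0L) {
    verdicts <- screen_filters(ok, rules)
    reports <- dplyr::left_join(
      dplyr::select(std, "id", "smiles_std", "mw", "clogp", "parse_error"),
      verdicts, by = "id"
    )
  } else {
    reports <- dplyr::mutate(
      dplyr::select(std, "id", "smiles_std", "mw", "clogp", "parse_error"),
      passed = NA, failed_rules = list(character())
    )
  }
  summary <- tibble::tibble(
    n_input = nrow(std),
    n_unparseable = sum(!is.na(std$parse_error)),
    n_passed = sum(reports$passed, na.rm = TRUE),
    n_failed = sum(!reports$passed, na.rm = TRUE)
  )
  list(standardized = ok, reports = reports, summary = summary)
}
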