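#' Descriptor configuration for a screening run
#'
#' The fragment schemes and property provider used to featurize a library.
#' A trained pool records this configuration; [screen()] refuses to apply a
#' pool to descriptors built from a different configuration, since a silent
#' mismatch would corrupt the ranking.
#'
#' @param schemes named list of [fragment_scheme()]s.
#' @param provider a [property_provider()] or NULL.
#' @return a `descriptor_config` list.
#' @export
descriptor_config <- function(schemes = list(seq24 = fragment_scheme("sequence", 2, 4)),
                              provider = NULL) {
  stopifnot(is.list(schemes))
  structure(list(schemes = schemes, provider = provider),
            class = "descriptor_config")
}

#' Featurize a standardized library under a descriptor configuration
#'
#' Builds every descriptor space of the configuration. At training time
#' constant columns are pruned (`prune = TRUE`); for prediction they are
#' kept and later aligned to each pool entry's feature list.
#'
#' @param standardized a [standardize_library()] result.
#' @param config a [descriptor_config()].
#' @param prune drop constant columns?
#' @return named list of descriptor matrices.
#' @export
featurize <- function(standardized, config, prune = TRUE) {
  spaces <- purrr::imap(config$schemes, function(scheme, nm) {
    m <- build_matrix(standardized, scheme, prune = prune)
    attr(m, "space_name") <- nm
    m
  })
  if (!is.null(config$provider)) {
    m <- build_matrix(standardized, config$provider, prune = prune)
    spaces[[config$provider$name]] <- m
  }
  spaces
}

descriptor_fingerprint <- function(config) {
  parts <- purrr::imap_chr(config$schemes, function(s, nm) {
    paste(nm, s$family, s$min_length, s$max_length, s$coloration, sep = ":")
  })
  if (!is.null(config$provider)) {
    parts <- c(parts, paste0("provider:", config$provider$name, ":",
                             paste(config$provider$property_names, collapse = ",")))
  }
  paste(sort(parts), collapse = "|")
}

#' Train consensus pools for both screening endpoints
#'
#' Standardizes the training library, featurizes it under one descriptor
#' configuration and builds one consensus pool per endpoint
#' (-log10 rate and -log10(-dG4)). The descriptor fingerprint is stamped
#' onto each pool.
#'
#' @param training data frame with columns `id`, `smiles`, `rate`
#'   (raw, > 0) and `dg4` (raw, < 0).
#' @param config a [descriptor_config()].
#' @param grids hyperparameter grids ([default_grids()]).
#' @param q2_rate,q2_dg admission thresholds for the two endpoints.
#' @param seed integer master seed.
#' @param n_repeats CV repeats used in grid search.
#' @return object of class `screen_model`: `pool_rate`, `pool_dg`,
#'   `config`, `standardized`.
#' @export
train_screening_model <- function(training, config = descriptor_config(),
                                  grids = default_grids(reduced = TRUE),
                                  q2_rate = 0.6, q2_dg = 0.7, seed = 1L,
                                  n_repeats = 5L) {
  stopifnot(all(c("id", "smiles", "rate", "dg4") %in% names(training)))
  std <- standardize_library(training)
  if (any(!is.na(std$parse_error))) {
    abort(paste0("unparseable training structure(s): ",
                 paste(std$id[!is.na(std$parse_error)], collapse = ", ")))
  }
  spaces <- featurize(std, config, prune = TRUE)
  y_rate <- endpoint_transform(training$rate, "rate")
  y_dg <- endpoint_transform(training$dg4, "dG_abs")
  pool_rate <- build_pool(spaces, y_rate, grids, q2_threshold = q2_rate,
                          seed = seed, n_repeats = n_repeats)
  pool_dg <- build_pool(spaces, y_dg, grids, q2_threshold = q2_dg,
                        seed = seed + 1L, n_repeats = n_repeats)
  structure(list(pool_rate = pool_rate, pool_dg = pool_dg, config = config,
                 fingerprint = descriptor_fingerprint(config),
                 standardized = std),
            class = "screen_model")
}

#' @export
print.screen_model <- function(x, ...) {
  cat("Screening model (descriptors: ", x$fingerprint, ")\n", sep = "")
  cat("rate endpoint pool:\n"); print(x$pool_rate)
  cat("dG endpoint pool:\n"); print(x$pool_dg)
  invisible(x)
}

#' Screen a candidate library against a reference compound
#'
#' Full virtual-screening pass: standardize, apply the structural filters,
#' featurize, predict both endpoints with the consensus pools, and rank
#' the filter-passing, in-domain candidates on the chosen endpoint
#' (-log10 rate by default; lower = faster absorption). The reference
#' compound (MDEA unless overridden) runs through the same prediction
#' pipeline regardless of its own filter verdict, and `beats_reference`
#' marks candidates predicted faster than it.
#'
#' @param model a [train_screening_model()] result.
#' @param library data frame with columns `id`, `smiles` plus whatever
#'   extra columns the descriptor configuration needs (e.g. `pka`).
#' @param reference_smiles reference compound SMILES (default MDEA).
#' @param reference_extra named list of extra column values for the
#'   reference compound (e.g. `list(pka = 8.52)`, MDEA's conjugate-acid
#'   pKa, when the pKa passthrough is active).
#' @param rules a [filter_config()].
#' @param ranking_endpoint `"rate"` or `"dG_abs"`.
#' @param require_in_ad rank only in-domain candidates?
#' @return object of class `screen_result`: `records` (one row per library
#'   member), `reference` (its consensus predictions), `summary` (stage
#'   counts).
#' @export
screen <- function(model, library, reference_smiles = "CN(CCO)CCO",
                   reference_extra = list(),
                   rules = filter_config(), ranking_endpoint = c("rate", "dG_abs"),
                   require_in_ad = TRUE) {
  stopifnot(inherits(model, "screen_model"))
  ranking_endpoint <- match.arg(ranking_endpoint)
  check_library_frame(library)
  if (descriptor_fingerprint(model$config) != model$fingerprint) {
    abort("descriptor configuration mismatch between pool and request")
  }
  filt <- filter_library(library, rules)
  reports <- filt$reports

  predictable <- filt$standardized
  preds_rate <- preds_dg <- NULL
  if (nrow(predictable) > 0L) {
    spaces <- featurize(predictable, model$config, prune = FALSE)
    preds_rate <- consensus_predict(model$pool_rate, spaces)
    preds_dg <- consensus_predict(model$pool_dg, spaces)
  }
  ref_input <- dplyr::bind_cols(
    tibble::tibble(id = ".reference", smiles = reference_smiles),
    tibble::as_tibble(reference_extra)
  )
  ref_std <- standardize_library(ref_input)
  if (any(!is.na(ref_std$parse_error))) abort("unparseable reference SMILES")
  ref_spaces <- featurize(ref_std, model$config, prune = FALSE)
  ref_rate <- consensus_predict(model$pool_rate, ref_spaces)
  ref_dg <- consensus_predict(model$pool_dg, ref_spaces)

  records <- dplyr::select(reports, "id", "smiles_std", "passed", "failed_rules")
  names(records)[names(records) == "passed"] <- "passed_filters"
  join_pred <- function(records, preds, prefix) {
    cols <- setNames(c("mean", "sd", "in_ad"),
                     paste0(prefix, c("_mean", "_sd", "_in_ad")))
    if (is.null(preds)) {
      for (nm in names(cols)) records[[nm]] <- if (grepl("in_ad", nm)) NA else NA_real_
      return(records)
    }
    p <- preds[, c("id", "mean", "sd", "in_ad")]
    names(p) <- c("id", names(cols))
    dplyr::left_join(records, p, by = "id")
  }
  records <- join_pred(records, preds_rate, "pred_rate")
  records <- join_pred(records, preds_dg, "pred_dg")
  records$in_ad <- records$pred_rate_in_ad & records$pred_dg_in_ad

  key_mean <- if (ranking_endpoint == "rate") "pred_rate_mean" else "pred_dg_mean"
  key_sd <- if (ranking_endpoint == "rate") "pred_rate_sd" else "pred_dg_sd"
  ref_key <- if (ranking_endpoint == "rate") ref_rate$mean else ref_dg$mean
  eligible <- !is.na(records$passed_filters) & records$passed_filters &
    (!require_in_ad | (!is.na(records$in_ad) & records$in_ad))
  ord <- order(records[[key_mean]][eligible], records[[key_sd]][eligible],
               records$id[eligible])
  records$rank <- NA_integer_
  records$rank[which(eligible)[ord]] <- seq_len(sum(eligible))
  records$beats_reference <- !is.na(records[[key_mean]]) &
    records[[key_mean]] < ref_key

  reference <- tibble::tibble(
    smiles = reference_smiles, smiles_std = ref_std$smiles_std,
    pred_rate_mean = ref_rate$mean, pred_rate_sd = ref_rate$sd,
    pred_dg_mean = ref_dg$mean, pred_dg_sd = ref_dg$sd
  )
  summary <- dplyr::mutate(filt$summary,
                           n_ranked = sum(eligible),
                           n_beats_reference = sum(records$beats_reference &
                                                     eligible, na.rm = TRUE))
  structure(list(records = tibble::as_tibble(records), reference = reference,
                 summary = summary, ranking_endpoint = ranking_endpoint),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Virtual screen (", x$summary$n_input, " candidates, ranked on the ",
      x$ranking_endpoint, " endpoint)\n", sep = "")
  cat("  passed filters: ", x$summary$n_passed, "; ranked: ",
      x$summary$n_ranked, "; predicted faster than reference: ",
      x$summary$n_beats_reference, "\n", sep = "")
  cat("reference -log10(rate) prediction: ",
      signif(x$reference$pred_rate_mean, 4), " +/- ",
      signif(x$reference$pred_rate_sd, 4), "\n", sep = "")
  invisible(x)
}

#' Top-ranked screening candidates
#'
#' @param result a [screen()] result.
#' @param n number of candidates.
#' @param require_in_ad restrict to in-domain candidates (ranks already
#'   respect this if the screen was run with `require_in_ad = TRUE`).
#' @return tibble of the first `n` records by rank (fewer if fewer are
#'   eligible); prefix-stable in `n`.
#' @export
top_candidates <- function(result, n, require_in_ad = TRUE) {
  stopifnot(inherits(result, "screen_result"), n >= 0)
  rec <- result$records
  rec <- rec[!is.na(rec$rank), ]
  if (require_in_ad) rec <- rec[rec$in_ad, ]
  rec <- rec[order(rec$rank), ]
  head(rec, n)
}
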