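#' Endpoint transforms
#'
#' Both absorption endpoints are modeled on a negative decimal-log scale:
#' rate -> -log10(rate) (requires rate > 0) and dG_abs -> -log10(-dG_abs)
#' (requires dG_abs < 0). Lower transformed values mean faster absorption /
#' more negative absorption free energy.
#'
#' @param x raw endpoint values.
#' @param endpoint `"rate"` or `"dG_abs"`.
#' @return transformed numeric vector.
#' @export
endpoint_transform <- function(x, endpoint = c("rate", "dG_abs")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "rate") {
    if (any(x <= 0)) abort("rate endpoint requires raw values > 0")
    -log10(x)
  } else {
    if (any(x >= 0)) abort("dG_abs endpoint requires raw values < 0")
    -log10(-x)
  }
}

#' @rdname endpoint_transform
#' @export
endpoint_back_transform <- function(x, endpoint = c("rate", "dG_abs")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "rate") 10^(-x) else -10^(-x)
}

#' Cross-validation metrics
#'
#' Q2, RMSE and MAE of cross-validated predictions. By default, each
#' repetition of the CV cycle pools its out-of-fold predictions over the
#' whole learning set and Q2 = 1 - SSres/SStot is computed against the
#' learning-set mean; RMSE and MAE likewise. The three statistics are then
#' averaged over repetitions. Supplying `folds` switches to the stricter
#' per-fold reading: statistics are computed within each (repetition,
#' fold) cell with SStot against that fold's mean, then averaged.
#'
#' @param y_exp observed values, one per compound.
#' @param y_pred matrix (n x n_repeats) or vector of CV predictions: each
#'   compound predicted exactly once per repetition.
#' @param folds optional matrix (same shape) of fold labels for the
#'   per-fold reading.
#' @return tibble: `q2_cv`, `rmse_cv`, `mae_cv`, `n`, `n_repeats`.
#' @examples
#' cv_metrics(c(1, 2, 3), c(1, 2, 4))  # Q2 0.5, RMSE 0.577, MAE 0.333
#' @export
cv_metrics <- function(y_exp, y_pred, folds = NULL) {
  if (is.vector(y_pred)) y_pred <- matrix(y_pred, ncol = 1L)
  stopifnot(nrow(y_pred) == length(y_exp))
  if (!is.null(folds) && is.vector(folds)) folds <- matrix(folds, ncol = 1L)
  one_cell <- function(obs, pred) {
    sstot <- sum((obs - mean(obs))^2)
    if (sstot == 0) abort("undefined Q2: zero variance in y_exp")
    tibble::tibble(
      q2 = 1 - sum((obs - pred)^2) / sstot,
      rmse = sqrt(mean((obs - pred)^2)),
      mae = mean(abs(obs - pred))
    )
  }
  per_rep <- purrr::map(seq_len(ncol(y_pred)), function(j) {
    if (is.null(folds)) return(one_cell(y_exp, y_pred[, j]))
    cells <- purrr::map(unique(folds[, j]), function(f) {
      sel <- folds[, j] == f
      one_cell(y_exp[sel], y_pred[sel, j])
    })
    dplyr::summarise(dplyr::bind_rows(cells), dplyr::across(dplyr::everything(), mean))
  })
  agg <- dplyr::bind_rows(per_rep)
  tibble::tibble(q2_cv = mean(agg$q2), rmse_cv = mean(agg$rmse),
                 mae_cv = mean(agg$mae), n = length(y_exp),
                 n_repeats = ncol(y_pred))
}

# Seeded uniform random partition into k folds, sizes as equal as possible.
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Hyperparameter grids
#'
#' Default grids for the three regression algorithms. `reduced = TRUE`
#' returns small grids suitable for tests and routine pipeline runs; the
#' full grids are the published screening configuration. "Unbounded" tree
#' depth is encoded as `Inf`. The `features` axis for random forest maps to
#' mtry = p, p/3 or log2(p).
#'
#' @param algorithms subset of `"random_forest"`,
#'   `"gradient_boosted_trees"`, `"support_vector_regression"`.
#' @param reduced use the small grids?
#' @return named list of tibbles, one per algorithm, one row per
#'   hyperparameter combination, ordered simple-to-complex (grid-search
#'   ties break toward the earlier, simpler row).
#' @export
default_grids <- function(algorithms = c("random_forest",
                                         "gradient_boosted_trees",
                                         "support_vector_regression"),
                          reduced = FALSE) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  grids <- list()
  if ("random_forest" %in% algorithms) {
    g <- if (reduced) {
      expand.grid(trees = c(100, 300), features = c("one_third", "all"),
                  depth = c(10, Inf), bootstrap = TRUE,
                  stringsAsFactors = FALSE)
    } else {
      expand.grid(trees = c(100, 300, 1000),
                  features = c("all", "one_third", "log2"),
                  depth = c(10, 30, Inf), bootstrap = c(TRUE, FALSE),
                  stringsAsFactors = FALSE)
    }
    grids$random_forest <- dplyr::arrange(tibble::as_tibble(g),
                                          .data$trees, .data$depth)
  }
  if ("gradient_boosted_trees" %in% algorithms) {
    g <- if (reduced) {
      expand.grid(trees = c(50, 100), feature_fraction = 1.0,
                  sample_fraction = 1.0, depth = c(5, 20),
                  learning_rate = c(0.3, 0.1), stringsAsFactors = FALSE)
    } else {
      expand.grid(trees = c(50, 100, 300, 500),
                  feature_fraction = c(1.0, 0.7),
                  sample_fraction = c(1.0, 0.7), depth = c(5, 20, Inf),
                  learning_rate = c(0.3, 0.1, 0.5, 0.05),
                  stringsAsFactors = FALSE)
    }
    grids$gradient_boosted_trees <- dplyr::arrange(tibble::as_tibble(g),
                                                   .data$trees, .data$depth)
  }
  if ("support_vector_regression" %in% algorithms) {
    g <- if (reduced) {
      expand.grid(kernel = c("linear", "rbf"), gamma = c(0.1, 0.01),
                  cost = c(1, 10, 100), stringsAsFactors = FALSE)
    } else {
      expand.grid(kernel = c("linear", "rbf", "poly", "sigmoid"),
                  gamma = c(1, 0.1, 0.01, 0.001, 0.0001),
                  cost = c(0.1, 1, 10, 100, 1000), stringsAsFactors = FALSE)
    }
    grids$support_vector_regression <-
      dplyr::arrange(tibble::as_tibble(g), dplyr::desc(.data$cost))
  }
  grids
}

# ---- model fitting backends -------------------------------------------------

# X: numeric matrix (no id); y: numeric; config: one grid row; seed: int.
fit_one_model <- function(algorithm, X, y, config, seed) {
  if (algorithm == "random_forest") {
    p <- ncol(X)
    mtry <- switch(config$features,
                   all = p, one_third = max(1L, floor(p / 3)),
                   log2 = max(1L, floor(log2(p))))
    fit <- ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = config$trees, mtry = mtry,
      max.depth = if (is.infinite(config$depth)) 0 else config$depth,
      replace = config$bootstrap,
      sample.fraction = if (config$bootstrap) 1 else 0.632,
      num.threads = 1L, seed = seed, verbose = FALSE
    )
    list(algorithm = algorithm, fit = fit)
  } else if (algorithm == "gradient_boosted_trees") {
    fit <- xgboost::xgboost(
      x = X, y = y, nrounds = config$trees,
      max_depth = if (is.infinite(config$depth)) 25L else config$depth,
      learning_rate = config$learning_rate,
      subsample = config$sample_fraction,
      colsample_bytree = config$feature_fraction,
      nthreads = 1L, seed = seed %% .Machine$integer.max, verbosity = 0L
    )
    list(algorithm = algorithm, fit = fit)
  } else if (algorithm == "support_vector_regression") {
    # inputs scaled to [0, 1] on the training ranges
    rng <- apply(X, 2L, range)
    span <- pmax(rng[2, ] - rng[1, ], 1e-12)
    Xs <- sweep(sweep(X, 2L, rng[1, ]), 2L, span, "/")
    kernel <- switch(config$kernel, rbf = "radial", poly = "polynomial",
                     config$kernel)
    fit <- e1071::svm(x = Xs, y = y, kernel = kernel, gamma = config$gamma,
                      cost = config$cost, scale = FALSE)
    list(algorithm = algorithm, fit = fit, scale_min = rng[1, ],
         scale_span = span)
  } else {
    abort(paste0("unknown algorithm: ", algorithm))
  }
}

predict_one_model <- function(model, X) {
  if (model$algorithm == "random_forest") {
    predict(model$fit, data = as.data.frame(X), num.threads = 1L)$predictions
  } else if (model$algorithm == "gradient_boosted_trees") {
    predict(model$fit, X)
  } else {
    Xs <- sweep(sweep(X, 2L, model$scale_min), 2L, model$scale_span, "/")
    unname(predict(model$fit, Xs))
  }
}

as_feature_matrix <- function(X) {
  stopifnot(is.data.frame(X), "id" %in% names(X))
  m <- as.matrix(X[setdiff(names(X), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- X$id
  m
}

# CV predictions for one (algorithm, config): matrix n x n_repeats.
cv_predictions <- function(algorithm, X, y, config, seed, n_folds = 5L,
                           n_repeats = 5L) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    folds <- make_folds(n, n_folds, seed + 1000L * r)
    for (f in seq_len(n_folds)) {
      test <- folds == f
      model <- fit_one_model(algorithm, X[!test, , drop = FALSE], y[!test],
                             config, seed + 1000L * r + f)
      pred[test, r] <- predict_one_model(model, X[test, , drop = FALSE])
    }
  }
  pred
}

#' Exhaustive grid search under repeated cross-validation
#'
#' Evaluates every hyperparameter combination of one algorithm by repeated
#' k-fold cross-validation and returns the combination with the highest
#' Q2. Ties break toward the earlier grid row (grids are ordered
#' simple-to-complex). Deterministic under a fixed seed: fold assignments
#' and model seeds are derived from it.
#'
#' @param X a descriptor matrix ([build_matrix()] output or any data frame
#'   with an `id` column plus numeric features).
#' @param y transformed endpoint values aligned with `X$id`.
#' @param algorithm one of the three supported algorithms.
#' @param grid tibble of hyperparameter combinations (one of
#'   [default_grids()]); defaults to the reduced grid of `algorithm`.
#' @param seed integer master seed.
#' @param n_folds,n_repeats CV shape (5 x 5 by default).
#' @return list: `algorithm`, `config` (best row), `metrics`
#'   ([cv_metrics()] row), `cv_pred` (n x n_repeats matrix), `results`
#'   (per-row metrics).
#' @export
grid_search_cv <- function(X, y, algorithm, grid = NULL, seed = 1L,
                           n_folds = 5L, n_repeats = 5L) {
  Xm <- as_feature_matrix(X)
  if (nrow(Xm) < 3L * n_folds) {
    abort(paste0("need at least ", 3L * n_folds, " compounds for ", n_folds,
                 "-fold grid search"))
  }
  if (any(!is.finite(Xm))) abort("descriptors must be finite")
  if (is.null(grid)) grid <- default_grids(algorithm, reduced = TRUE)[[algorithm]]
  evals <- purrr::map(seq_len(nrow(grid)), function(i) {
    config <- grid[i, ]
    pred <- tryCatch(
      cv_predictions(algorithm, Xm, y, config, seed, n_folds, n_repeats),
      error = function(e) e
    )
    if (inherits(pred, "error")) {
      return(list(metrics = NULL, pred = NULL, error = conditionMessage(pred)))
    }
    list(metrics = cv_metrics(y, pred), pred = pred, error = NA_character_)
  })
  ok <- !purrr::map_lgl(evals, ~ is.null(.x$metrics))
  if (!any(ok)) {
    abort(paste0("all grid points failed: ",
                 paste(unique(purrr::map_chr(evals, "error")), collapse = "; ")))
  }
  q2 <- rep(-Inf, length(evals))
  q2[ok] <- purrr::map_dbl(evals[ok], ~ .x$metrics$q2_cv)
  best <- which.max(q2)   # first maximum = simplest of the tied bests
  results <- dplyr::bind_cols(
    grid,
    dplyr::bind_rows(purrr::map(evals, ~ .x$metrics %||%
                                  tibble::tibble(q2_cv = NA_real_,
                                                 rmse_cv = NA_real_,
                                                 mae_cv = NA_real_,
                                                 n = nrow(Xm),
                                                 n_repeats = n_repeats)))
  )
  list(algorithm = algorithm, config = grid[best, ],
       metrics = evals[[best]]$metrics, cv_pred = evals[[best]]$pred,
       results = results)
}

#' Build a consensus model pool
#'
#' One candidate model per (algorithm, descriptor space): hyperparameters
#' are grid-searched under repeated CV, and the candidate is admitted to
#' the pool iff its Q2 meets the threshold (0.6 for the rate endpoint, 0.7
#' for the dG endpoint, by convention). Admitted models are refit on the
#' full learning set and stamped with their boundary-box applicability
#' domain (per-feature training min/max, closed intervals).
#'
#' @param spaces named list of descriptor matrices sharing the same
#'   compounds in the same order.
#' @param y transformed endpoint values.
#' @param grids named list of grids as from [default_grids()].
#' @param q2_threshold admission threshold on cross-validated Q2.
#' @param seed integer master seed.
#' @param n_folds,n_repeats CV shape.
#' @return object of class `model_pool`: list of entries (algorithm,
#'   config, space_name, metrics, model, ad_box, cv_pred) plus attributes
#'   recording the descriptor configuration.
#' @export
build_pool <- function(spaces, y, grids = default_grids(reduced = TRUE),
                       q2_threshold = 0.7, seed = 1L, n_folds = 5L,
                       n_repeats = 5L) {
  stopifnot(is.list(spaces), length(spaces) >= 1L)
  if (is.null(names(spaces)) || any(!nzchar(names(spaces)))) {
    names(spaces) <- purrr::map_chr(spaces, ~ attr(.x, "space_name") %||% "space")
  }
  ids <- spaces[[1]]$id
  for (s in spaces) if (!identical(s$id, ids)) abort("spaces must share compound ids")
  entries <- list()
  for (space_name in names(spaces)) {
    X <- spaces[[space_name]]
    for (algorithm in names(grids)) {
      gs <- grid_search_cv(X, y, algorithm, grids[[algorithm]],
                           seed = seed + utf8_seed(paste0(algorithm, space_name)),
                           n_folds = n_folds, n_repeats = n_repeats)
      if (gs$metrics$q2_cv >= q2_threshold) {
        Xm <- as_feature_matrix(X)
        model <- fit_one_model(algorithm, Xm, y, gs$config, seed)
        ad_box <- apply(Xm, 2L, range)
        entries <- c(entries, list(list(
          algorithm = algorithm, config = gs$config, space_name = space_name,
          metrics = gs$metrics, model = model, ad_box = ad_box,
          features = colnames(Xm), cv_pred = gs$cv_pred
        )))
      }
    }
  }
  if (length(entries) == 0L) {
    abort(paste0("no model passed the Q2 threshold ", q2_threshold))
  }
  structure(entries, class = "model_pool", ids = ids,
            q2_threshold = q2_threshold,
            descriptor_config = purrr::map(spaces, ~ attr(.x, "scheme")))
}

# stable small integer hash so per-(algorithm, space) seeds differ
utf8_seed <- function(s) sum(utf8ToInt(s)) %% 997L

#' @export
print.model_pool <- function(x, ...) {
  cat("Consensus model pool:", length(x), "model(s), Q2 threshold",
      attr(x, "q2_threshold"), "\n")
  for (e in x) {
    cat(sprintf("  %-28s %-22s Q2 = %.3f RMSE = %.3f\n", e$algorithm,
                e$space_name, e$metrics$q2_cv, e$metrics$rmse_cv))
  }
  invisible(x)
}

#' Nested cross-validation
#'
#' Unbiased performance estimate: hyperparameters (and the winning
#' algorithm/space combination) are chosen only inside each inner k-fold
#' loop; predictions are made for the untouched outer fold. The whole cycle
#' is repeated after reshuffling the compounds, and Q2/RMSE/MAE are
#' averaged over repeats.
#'
#' @inheritParams build_pool
#' @param n_outer outer folds (default 5).
#' @param n_inner inner folds for hyperparameter selection (default 5).
#' @param n_repeats reshuffled repetitions of the whole cycle (default 5).
#' @return tibble: `q2_ncv`, `rmse_ncv`, `mae_ncv`, `n`, `n_repeats`, plus
#'   a `per_repeat` list-column of the per-repeat statistics.
#' @export
nested_cv <- function(spaces, y, grids = default_grids(reduced = TRUE),
                      seed = 1L, n_outer = 5L, n_inner = 5L, n_repeats = 5L) {
  stopifnot(is.list(spaces), length(spaces) >= 1L)
  if (is.null(names(spaces)) || any(!nzchar(names(spaces)))) {
    names(spaces) <- purrr::map_chr(spaces, ~ attr(.x, "space_name") %||% "space")
  }
  n <- nrow(spaces[[1]])
  reps <- purrr::map(seq_len(n_repeats), function(r) {
    folds <- make_folds(n, n_outer, seed + 7919L * r)
    pred <- rep(NA_real_, n)
    for (f in seq_len(n_outer)) {
      test <- folds == f
      best <- NULL
      for (space_name in names(spaces)) {
        Xtr <- spaces[[space_name]][!test, , drop = FALSE]
        for (algorithm in names(grids)) {
          gs <- grid_search_cv(
            Xtr, y[!test], algorithm, grids[[algorithm]],
            seed = seed + 7919L * r + 13L * f + utf8_seed(paste0(algorithm, space_name)),
            n_folds = n_inner, n_repeats = 1L
          )
          if (is.null(best) || gs$metrics$q2_cv > best$q2) {
            best <- list(q2 = gs$metrics$q2_cv, algorithm = algorithm,
                         config = gs$config, space_name = space_name)
          }
        }
      }
      Xtr <- as_feature_matrix(spaces[[best$space_name]][!test, , drop = FALSE])
      Xte <- as_feature_matrix(spaces[[best$space_name]][test, , drop = FALSE])
      model <- fit_one_model(best$algorithm, Xtr, y[!test], best$config,
                             seed + 7919L * r + 13L * f)
      pred[test] <- predict_one_model(model, Xte)
    }
    cv_metrics(y, pred)
  })
  agg <- dplyr::bind_rows(reps)
  tibble::tibble(q2_ncv = mean(agg$q2_cv), rmse_ncv = mean(agg$rmse_cv),
                 mae_ncv = mean(agg$mae_cv), n = n, n_repeats = n_repeats,
                 per_repeat = list(agg))
}

#' Y-randomization test
#'
#' Permutes the response, refits the model with the supplied hyperparameter
#' configuration under k-fold CV, and records the shuffled Q2 for each
#' permutation. A real structure-property relationship shows true Q2 far
#' above the shuffled maximum.
#'
#' @param X descriptor matrix (with `id` column).
#' @param y transformed endpoint values.
#' @param algorithm,config model to refit (a single grid row).
#' @param n_shuffles number of label permutations (the published protocol
#'   uses 100).
#' @param seed integer master seed.
#' @param n_folds CV folds per shuffle.
#' @param include_identity prepend the identity permutation as a control
#'   (its Q2 equals the unshuffled Q2)?
#' @return list: `q2_shuffled` (vector), `q2_max`, `q2_mean`, `q2_true`.
#' @export
y_randomization <- function(X, y, algorithm, config, n_shuffles = 100L,
                            seed = 1L, n_folds = 5L,
                            include_identity = FALSE) {
  Xm <- as_feature_matrix(X)
  run_cv <- function(yy, s) {
    pred <- cv_predictions(algorithm, Xm, yy, config, s, n_folds,
                           n_repeats = 1L)
    cv_metrics(yy, pred)$q2_cv
  }
  q2_true <- run_cv(y, seed)
  perms <- purrr::map(seq_len(n_shuffles), function(i) {
    set.seed(seed + 31L * i)
    sample(length(y))
  })
  offsets <- 31L * seq_len(n_shuffles)
  if (include_identity) {
    # control case: same seed as the true run, so its Q2 matches exactly
    perms <- c(list(seq_along(y)), perms)
    offsets <- c(0L, offsets)
  }
  q2_shuffled <- purrr::map_dbl(seq_along(perms), function(i) {
    run_cv(y[perms[[i]]], seed + offsets[i])
  })
  list(q2_shuffled = q2_shuffled, q2_max = max(q2_shuffled),
       q2_mean = mean(q2_shuffled), q2_true = q2_true)
}

#' Consensus prediction with applicability-domain filtering
#'
#' Predicts new compounds with every model in the pool and aggregates to a
#' mean and standard deviation. In AD-filtered mode (default) only models
#' whose boundary box contains the compound (every feature inside the
#' closed training [min, max]) contribute; when no model's box contains
#' it, the compound is flagged `in_ad = FALSE` and all models are used as
#' a fallback.
#'
#' @param pool a [build_pool()] result.
#' @param spaces named list of descriptor matrices for the new compounds;
#'   names and feature columns must cover every pool entry (build them with
#'   `prune = FALSE`).
#' @param ad_filter use AD-filtered aggregation?
#' @return tibble: `id`, `mean`, `sd`, `n_models_total`, `n_models_in_ad`,
#'   `in_ad`.
#' @export
consensus_predict <- function(pool, spaces, ad_filter = TRUE) {
  stopifnot(inherits(pool, "model_pool"))
  ids <- spaces[[1]]$id
  per_model <- purrr::map(pool, function(e) {
    if (!e$space_name %in% names(spaces)) {
      abort(paste0("descriptor space '", e$space_name,
                   "' missing from prediction input"))
    }
    X <- spaces[[e$space_name]]
    missing <- setdiff(e$features, names(X))
    if (length(missing) > 0L) {
      if (inherits(attr(X, "scheme"), "fragment_scheme")) {
        # a fragment absent from the candidate has count zero
        X[missing] <- 0
      } else {
        abort(paste0("feature(s) missing for space '", e$space_name, "': ",
                     paste(head(missing, 5L), collapse = ", ")))
      }
    }
    Xm <- as_feature_matrix(X[, c("id", e$features)])
    in_box <- rep(TRUE, nrow(Xm))
    for (j in seq_along(e$features)) {
      in_box <- in_box & Xm[, j] >= e$ad_box[1, j] & Xm[, j] <= e$ad_box[2, j]
    }
    list(pred = predict_one_model(e$model, Xm), in_ad = in_box)
  })
  pred_mat <- do.call(cbind, purrr::map(per_model, "pred"))
  ad_mat <- do.call(cbind, purrr::map(per_model, "in_ad"))
  rows <- purrr::map(seq_along(ids), function(i) {
    p <- pred_mat[i, ]
    inad <- ad_mat[i, ]
    use <- if (ad_filter && any(inad)) inad else rep(TRUE, length(p))
    tibble::tibble(
      id = ids[i], mean = mean(p[use]),
      sd = if (sum(use) > 1L) stats::sd(p[use]) else 0,
      n_models_total = length(p), n_models_in_ad = sum(inad),
      in_ad = any(inad)
    )
  })
  dplyr::bind_rows(rows)
}

#' Flag cross-validation outliers
#'
#' Compounds whose absolute CV error exceeds 2 x RMSE_CV (strictly) are
#' flagged as outlying data points.
#'
#' @param ids compound ids.
#' @param y_exp,y_pred_cv aligned observed and cross-validated values.
#' @param rmse_cv the cross-validation RMSE.
#' @return character vector of flagged ids.
#' @export
flag_outliers <- function(ids, y_exp, y_pred_cv, rmse_cv) {
  stopifnot(length(ids) == length(y_exp), length(y_exp) == length(y_pred_cv))
  ids[abs(y_exp - y_pred_cv) > 2 * rmse_cv]
}
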