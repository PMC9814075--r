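test_that("endpoint transforms are bijective on their domains", {
  r <- c(0.1, 2, 30)
  expect_equal(endpoint_back_transform(endpoint_transform(r, "rate"), "rate"), r)
  g <- c(-50, -12, -0.3)
  expect_equal(endpoint_back_transform(endpoint_transform(g, "dG_abs"), "dG_abs"), g)
  expect_error(endpoint_transform(c(1, -1), "rate"), "> 0")
  expect_error(endpoint_transform(c(-1, 1), "dG_abs"), "< 0")
})

test_that("cv_metrics reproduces the worked single-fold case", {
  m <- cv_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$q2_cv, 0.5)
  expect_equal(m$rmse_cv, sqrt(1 / 3))
  expect_equal(round(m$rmse_cv, 4), 0.5774)
  expect_equal(m$mae_cv, 1 / 3)
})

test_that("cv_metrics has perfect and null predictor fixed points", {
  y <- c(2, 4, 6, 8)
  perf <- cv_metrics(y, y)
  expect_equal(perf$q2_cv, 1); expect_equal(perf$rmse_cv, 0)
  null <- cv_metrics(y, rep(mean(y), 4))
  expect_equal(null$q2_cv, 0)
  expect_error(cv_metrics(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("cv_metrics agrees with a direct transcription of the formulas", {
  # oracle: Q2 = mean_j(1 - SSres_j/SStot_j), RMSE = mean_j sqrt(SSres_j/n),
  # MAE = mean_j mean|err|, written independently of the implementation
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    k <- sample(1:5, 1)
    y <- rnorm(n)
    pred <- matrix(rnorm(n * k), n, k)
    q2 <- rmse <- mae <- numeric(k)
    for (j in 1:k) {
      q2[j] <- 1 - sum((y - pred[, j])^2) / sum((y - mean(y))^2)
      rmse[j] <- sqrt(sum((y - pred[, j])^2) / n)
      mae[j] <- sum(abs(y - pred[, j])) / n
    }
    m <- cv_metrics(y, pred)
    expect_equal(m$q2_cv, mean(q2), tolerance = 1e-12)
    expect_equal(m$rmse_cv, mean(rmse), tolerance = 1e-12)
    expect_equal(m$mae_cv, mean(mae), tolerance = 1e-12)
  }
})

test_that("per-fold metric reading uses fold means", {
  y <- c(1, 2, 3, 10, 20, 30)
  pred <- c(1, 2, 4, 10, 20, 33)
  folds <- c(1, 1, 1, 2, 2, 2)
  m <- cv_metrics(y, pred, folds = folds)
  # fold 1 is the worked case (Q2 .5); fold 2: SSres 9, SStot 200
  expect_equal(m$q2_cv, mean(c(0.5, 1 - 9 / 200)))
})

test_that("grid search learns a learnable fixture and is deterministic", {
  fx <- fixture_learnable()
  gs1 <- grid_search_cv(fx$X, fx$y, "random_forest", seed = 5, n_repeats = 2)
  expect_gt(gs1$metrics$q2_cv, 0.85)
  gs2 <- grid_search_cv(fx$X, fx$y, "random_forest", seed = 5, n_repeats = 2)
  expect_identical(gs1$config, gs2$config)
  expect_identical(gs1$cv_pred, gs2$cv_pred)
})

test_that("grid search on pure noise reports weak models", {
  set.seed(1)
  n <- 50
  X <- tibble::tibble(id = as.character(1:n), f1 = runif(n), f2 = runif(n))
  y <- rnorm(n)
  gs <- grid_search_cv(X, y, "random_forest", tiny_rf_grid(), seed = 2,
                       n_repeats = 2)
  expect_lt(gs$metrics$q2_cv, 0.3)
})

test_that("SVR route scales descriptors and learns a linear signal", {
  fx <- fixture_learnable(noise = 0.01)
  gs <- grid_search_cv(fx$X, fx$y, "support_vector_regression", seed = 5,
                       n_repeats = 2)
  expect_gt(gs$metrics$q2_cv, 0.95)
})

test_that("pool admission respects the Q2 threshold", {
  fx <- fixture_learnable()
  spaces <- list(main = fx$X)
  pool <- build_pool(spaces, fx$y,
                     grids = list(random_forest = tiny_rf_grid()),
                     q2_threshold = 0.7, seed = 5, n_repeats = 2)
  expect_s3_class(pool, "model_pool")
  expect_true(all(purrr::map_dbl(pool, ~ .x$metrics$q2_cv) >= 0.7))
  expect_error(
    build_pool(spaces, fx$y, grids = list(random_forest = tiny_rf_grid()),
               q2_threshold = 1.01, seed = 5, n_repeats = 2),
    "no model passed")
})

test_that("pool entries carry training-range AD boxes", {
  fx <- fixture_learnable()
  pool <- build_pool(list(main = fx$X), fx$y,
                     grids = list(random_forest = tiny_rf_grid()),
                     q2_threshold = 0.5, seed = 5, n_repeats = 2)
  e <- pool[[1]]
  expect_equal(unname(e$ad_box[1, ]),
               unname(vapply(fx$X[e$features], min, 0)))
  expect_equal(unname(e$ad_box[2, ]),
               unname(vapply(fx$X[e$features], max, 0)))
})

test_that("consensus predictions aggregate and respect the AD box", {
  fx <- fixture_learnable()
  pool <- build_pool(list(main = fx$X), fx$y,
                     grids = list(random_forest = tiny_rf_grid()),
                     q2_threshold = 0.5, seed = 5, n_repeats = 2)
  # training points lie inside every box (closed intervals)
  pred <- consensus_predict(pool, list(main = fx$X))
  expect_true(all(pred$in_ad))
  expect_true(all(pred$sd >= 0))
  expect_true(all(pred$n_models_in_ad <= pred$n_models_total))
  # one feature pushed above the training max leaves the domain
  out <- fx$X[1, ]
  out$f1 <- max(fx$X$f1) + 1
  pred_out <- consensus_predict(pool, list(main = out))
  expect_false(pred_out$in_ad)
  expect_false(is.na(pred_out$mean))   # all-model fallback still predicts
})

test_that("single-model pool consensus has zero spread", {
  fx <- fixture_learnable()
  pool <- build_pool(list(main = fx$X), fx$y,
                     grids = list(random_forest = tiny_rf_grid()),
                     q2_threshold = 0.5, seed = 5, n_repeats = 2)
  # aggregate over a single model: sd must be exactly 0
  one <- structure(pool[1], class = "model_pool",
                   q2_threshold = attr(pool, "q2_threshold"))
  pred1 <- consensus_predict(one, list(main = fx$X))
  expect_true(all(pred1$sd == 0))
})

test_that("nested CV estimates track but do not exceed selection estimates", {
  fx <- fixture_learnable()
  grids <- list(random_forest = tiny_rf_grid())
  pool <- build_pool(list(main = fx$X), fx$y, grids, q2_threshold = 0.5,
                     seed = 5, n_repeats = 2)
  ncv <- nested_cv(list(main = fx$X), fx$y, grids, seed = 5, n_repeats = 2)
  expect_gt(ncv$q2_ncv, 0.7)
  best_sel <- max(purrr::map_dbl(pool, ~ .x$metrics$q2_cv))
  expect_lte(ncv$q2_ncv, best_sel + 0.05)
})

test_that("nested CV on pure noise stays near zero", {
  set.seed(3)
  n <- 50
  X <- tibble::tibble(id = as.character(1:n), f1 = runif(n), f2 = runif(n))
  y <- rnorm(n)
  ncv <- nested_cv(list(main = X), y, list(random_forest = tiny_rf_grid()),
                   seed = 4, n_repeats = 2)
  expect_lt(ncv$q2_ncv, 0.1)
})

test_that("Y-randomization separates real signal from chance correlation", {
  fx <- fixture_learnable(n = 40, noise = 0.02)
  yr <- y_randomization(fx$X, fx$y, "random_forest", tiny_rf_grid()[1, ],
                        n_shuffles = 20, seed = 9)
  expect_gte(yr$q2_true, 0.7)
  expect_lt(yr$q2_mean, 0.2)
  expect_gte(yr$q2_max, yr$q2_mean)
})

test_that("identity permutation control reproduces the unshuffled Q2", {
  fx <- fixture_learnable(n = 30)
  yr <- y_randomization(fx$X, fx$y, "random_forest", tiny_rf_grid()[1, ],
                        n_shuffles = 1, seed = 9, include_identity = TRUE)
  expect_equal(yr$q2_shuffled[1], yr$q2_true)
})

test_that("outlier flagging applies the strict 2x RMSE rule", {
  ids <- c("a", "b", "c", "d")
  y <- c(0, 0, 0, 0)
  expect_equal(flag_outliers(ids, y, y, rmse_cv = 1), character())
  pred <- c(0, 3, 0, 0)     # error 3 = 3x rmse
  expect_equal(flag_outliers(ids, y, pred, rmse_cv = 1), "b")
  pred2 <- c(0, 2, 0, 0)    # error exactly 2x rmse: NOT flagged
  expect_equal(flag_outliers(ids, y, pred2, rmse_cv = 1), character())
})

test_that("model pool tidiers expose metrics", {
  fx <- fixture_learnable()
  pool <- build_pool(list(main = fx$X), fx$y,
                     grids = list(random_forest = tiny_rf_grid()),
                     q2_threshold = 0.5, seed = 5, n_repeats = 2)
  td <- tidy(pool)
  expect_true(all(c("algorithm", "space", "q2_cv", "rmse_cv") %in% names(td)))
  gl <- glance(pool)
  expect_equal(gl$n_models, length(pool))
})
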