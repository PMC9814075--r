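#' Tidy a consensus model pool
#'
#' One row per pool entry with its algorithm, descriptor space,
#' hyperparameters (as a list-column) and cross-validation metrics.
#'
#' @param x a [build_pool()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.model_pool <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x, function(e) {
    dplyr::bind_cols(
      tibble::tibble(algorithm = e$algorithm, space = e$space_name,
                     hyperparameters = list(as.list(e$config))),
      e$metrics
    )
  }))
}

#' @rdname tidy.model_pool
#' @export
glance.model_pool <- function(x, ...) {
  m <- dplyr::bind_rows(purrr::map(x, "metrics"))
  tibble::tibble(n_models = length(x), q2_threshold = attr(x, "q2_threshold"),
                 q2_cv_best = max(m$q2_cv), q2_cv_mean = mean(m$q2_cv),
                 rmse_cv_mean = mean(m$rmse_cv))
}

#' Tidy a Polanyi-Evans calibration
#'
#' @param x a [calibrate_rate_model()] result.
#' @param ... unused.
#' @return a tibble with the fitted slope `a`, the combined intercept and
#'   (when identifiable) `b`.
#' @export
tidy.rate_calibration <- function(x, ...) {
  tibble::tibble(term = c("a", "intercept", "b"),
                 estimate = c(x$a, x$intercept, x$b))
}

#' @rdname tidy.rate_calibration
#' @export
glance.rate_calibration <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$n, T_K = x$T_K, r_squared = s$r.squared,
                 sigma = s$sigma)
}

#' Tidy a screening result
#'
#' @param x a [screen()] result.
#' @param ... unused.
#' @return the per-candidate records tibble.
#' @export
tidy.screen_result <- function(x, ...) x$records

#' @rdname tidy.screen_result
#' @export
glance.screen_result <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(ref_pred_rate = x$reference$pred_rate_mean,
                                  ref_pred_dg = x$reference$pred_dg_mean))
}

#' Plot a screening result
#'
#' Ranked candidates on the chosen endpoint scale (lower -log10 rate =
#' faster), with the reference prediction as a horizontal line and
#' out-of-domain candidates marked.
#'
#' @param object a [screen()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.screen_result <- function(object, ...) {
  rec <- object$records[!is.na(object$records$rank), ]
  key <- if (object$ranking_endpoint == "rate") "pred_rate_mean" else "pred_dg_mean"
  sdk <- if (object$ranking_endpoint == "rate") "pred_rate_sd" else "pred_dg_sd"
  ref <- if (object$ranking_endpoint == "rate") {
    object$reference$pred_rate_mean
  } else {
    object$reference$pred_dg_mean
  }
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$rank, y = .data[[key]])) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[key]] - .data[[sdk]], ymax = .data[[key]] + .data[[sdk]],
      colour = .data$beats_reference), size = 0.2) +
    ggplot2::geom_hline(yintercept = ref, linetype = "dashed") +
    ggplot2::labs(x = "rank", y = paste0("-log10 ", object$ranking_endpoint,
                                         " (consensus mean +/- sd)"),
                  colour = "faster than reference") +
    ggplot2::theme_minimal()
}

#' Plot a kinetic-trace fit
#'
#' The pressure trace with the fitted slope window and the 50%-absorption
#' point marked.
#'
#' @param object an [rco2_slope()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rco2_fit <- function(object, ...) {
  tr <- object$trace
  p50 <- object$p0 - 0.5 * (object$p0 - object$p_eq)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$p_co2_bar)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_abline(intercept = unname(coef(object$window_fit)[1]),
                         slope = unname(coef(object$window_fit)[2]),
                         colour = "red") +
    ggplot2::annotate("point", x = object$t50, y = p50, colour = "red") +
    ggplot2::geom_hline(yintercept = object$p_eq, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "p(CO2) (bar)",
                  subtitle = paste0("r(CO2) = ", signif(object$rate_bar_s, 4),
                                    " bar/s at t50 = ", signif(object$t50, 4),
                                    " s")) +
    ggplot2::theme_minimal()
}

#' Plot a Polanyi-Evans calibration
#'
#' The linearized rate data against dG3 with the fitted line.
#'
#' @param object a [calibrate_rate_model()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rate_calibration <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dg3, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::labs(x = "dG3 (kJ/mol)", y = "ln rate - ln([CO2][OH-])") +
    ggplot2::theme_minimal()
}
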