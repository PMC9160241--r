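# Descriptive regressions of organ volume on weight and age, and the
# allometric power law y = alpha * LW^beta fitted on log-transformed data.

#' Linear regression of organ volume on weight and age
#'
#' Ordinary least squares with intercept, standard errors from the unbiased
#' residual-variance estimator (the standard `lm` machinery).
#'
#' @param table data frame of phenotype records.
#' @param response response column, e.g. `"heart_ml"` or `"lung_ml"`.
#' @param regressors regressor columns, default weight and age at scanning.
#' @return a `volume_regression` object wrapping the `lm` fit.
#' @export
fit_volume_regression <- function(table, response,
                                  regressors = c("live_weight_kg", "age_days")) {
  stopifnot(response %in% names(table), all(regressors %in% names(table)))
  dat <- table[stats::complete.cases(table[c(response, regressors)]), ]
  if (nrow(dat) < length(regressors) + 2L) {
    stop("need more observations than parameters", call. = FALSE)
  }
  form <- stats::reformulate(regressors, response = response)
  fit <- stats::lm(form, data = dat)
  if (fit$rank < length(regressors) + 1L) {
    stop("singular design: regressors are collinear", call. = FALSE)
  }
  structure(list(fit = fit, response = response, regressors = regressors,
                 n = nrow(dat)),
            class = "volume_regression")
}

#' @export
print.volume_regression <- function(x, ...) {
  cat(sprintf("<volume_regression> %s ~ %s  (n = %d)\n", x$response,
              paste(x$regressors, collapse = " + "), x$n))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.volume_regression <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1], std_error = co[, 2],
                 statistic = co[, 3], p_value = co[, 4])
}

#' @export
glance.volume_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma, n = x$n,
                 df_residual = x$fit$df.residual)
}

#' Fit the allometric scaling law
#'
#' Fits `y = alpha * LW^beta` by OLS of `log(y)` on `log(LW)` (natural
#' logarithms; `beta` is base-invariant). A `beta` close to one indicates
#' organ volume proportional to live weight.
#'
#' @param table data frame of phenotype records.
#' @param response response column (volumes, must be positive).
#' @param weight live-weight column (must be positive).
#' @return an `allometric_fit` with `alpha`, `beta`, `se_beta`, `n`.
#' @export
fit_allometric <- function(table, response, weight = "live_weight_kg") {
  stopifnot(response %in% names(table), weight %in% names(table))
  y <- table[[response]]; lw <- table[[weight]]
  keep <- !is.na(y) & !is.na(lw)
  y <- y[keep]; lw <- lw[keep]
  bad <- which(y <= 0 | lw <= 0)
  if (length(bad)) {
    stop("non-positive values in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  fit <- stats::lm(log(y) ~ log(lw))
  co <- summary(fit)$coefficients
  structure(
    list(alpha = exp(co[1, 1]), beta = co[2, 1], se_beta = co[2, 2],
         se_log_alpha = co[1, 2], n = length(y), fit = fit,
         response = response),
    class = "allometric_fit"
  )
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> %s = %.4g * LW^%.3f  (SE(beta) %.3f, n = %d)\n",
              x$response, x$alpha, x$beta, x$se_beta, x$n))
  invisible(x)
}

#' @export
tidy.allometric_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta),
                 std_error = c(x$alpha * x$se_log_alpha, x$se_beta))
}

#' @export
glance.allometric_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(beta = x$beta, alpha = x$alpha, r_squared = s$r.squared,
                 sigma_log = s$sigma, n = x$n)
}

#' @export
autoplot.allometric_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("log_volume", "log_weight")
  ggplot2::ggplot(d, ggplot2::aes(.data$log_weight, .data$log_volume)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(intercept = log(object$alpha), slope = object$beta,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "log live weight (kg)", y = paste("log", object$response),
      title = sprintf("Allometric fit: beta = %.3f (SE %.3f)",
                      object$beta, object$se_beta)
    )
}

#' Simulate organ volumes under the allometric power law
#'
#' `log(volume) = log(alpha) + beta * log(LW) + N(0, log_noise_sd^2)` with
#' live weight drawn uniformly on `lw_range`.
#'
#' @param n number of animals.
#' @param alpha,beta power-law coefficients (`alpha > 0`).
#' @param lw_range live-weight range in kg (positive).
#' @param log_noise_sd standard deviation of the log-scale noise.
#' @param seed integer seed.
#' @return tibble with `live_weight_kg` and `volume_ml`.
#' @export
simulate_allometric_weights <- function(n, alpha, beta, lw_range = c(100, 140),
                                        log_noise_sd = 0.1, seed = 1L) {
  stopifnot(alpha > 0, all(lw_range > 0), n >= 2)
  with_local_seed(seed, {
    lw <- stats::runif(n, lw_range[1], lw_range[2])
    vol <- exp(log(alpha) + beta * log(lw) + stats::rnorm(n, 0, log_noise_sd))
    tibble::tibble(live_weight_kg = lw, volume_ml = vol)
  })
}
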