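#' Lyapunov exponent from forecast-error growth across horizons
#'
#' Forecast error measures the distance between a predicted and an observed
#' trajectory, so its growth with the time-to-prediction interval mirrors
#' the divergence of nearby trajectories. Fitting ordinary least squares to
#' log(MAE) against horizon, the slope estimates the Lyapunov exponent
#' (per grid step) and the intercept estimates log of the initial error:
#' error(t) ~ error(0) * exp(lambda * t). A positive slope (trajectory
#' divergence) is the operational signature of chaos; a negative slope
#' indicates local convergence toward a stable equilibrium.
#'
#' @param mae_by_tp Positive MAE values, one per horizon. Zero values are
#'   dropped with a warning (their log is undefined).
#' @param horizons Horizons (grid steps) matching `mae_by_tp`.
#' @return Object of class `lyapunov_estimate`: `lambda` (slope per step),
#'   `intercept` (log initial error), `p_value` (two-sided test of zero
#'   slope; `NA` with fewer than 3 horizons), `n_horizons`.
#' @export
#' @examples
#' lyapunov_from_horizons(exp(0.5 * (1:10)), 1:10)  # lambda = 0.5
lyapunov_from_horizons <- function(mae_by_tp, horizons = seq_along(mae_by_tp)) {
  stopifnot(length(mae_by_tp) == length(horizons))
  if (any(mae_by_tp < 0)) stop("MAE values must be nonnegative")
  keep <- mae_by_tp > 0
  if (!all(keep)) {
    warning(sum(!keep), " horizon(s) with MAE = 0 dropped (log undefined)")
  }
  y <- log(mae_by_tp[keep])
  t <- horizons[keep]
  if (length(y) < 2) stop("need at least 2 horizons with positive MAE")
  fit <- stats::lm(y ~ t)
  # exactly exponential error growth is a legitimate input; silence the
  # perfect-fit note summary.lm emits for it
  cf <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(cf) == 2 && ncol(cf) >= 4 && fit$df.residual > 0) {
    cf["t", "Pr(>|t|)"]
  } else NA_real_
  structure(list(lambda = unname(stats::coef(fit)["t"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 p_value = p, n_horizons = length(y)),
            class = "lyapunov_estimate")
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("<lyapunov_estimate> lambda = %.4g per step (p = %.3g, %d horizons)\n",
              x$lambda, x$p_value, x$n_horizons))
  invisible(x)
}

#' Stepwise Lyapunov rate from consecutive-horizon RMSE values
#'
#' Solves RMSE(t[i+1]) = RMSE(t[i]) * exp(lambda * (t[i+1] - t[i])) for
#' lambda, i.e. lambda = log(RMSE(t[i+1]) / RMSE(t[i])) / dt. Given a
#' sequence of RMSE values over consecutive horizons, the per-step rates
#' are averaged. Error that doubles per step gives log 2; error that
#' shrinks gives a negative rate (locally stable dynamics).
#'
#' @param rmse Positive RMSE values at >= 2 consecutive horizons.
#' @param dt Horizon spacing in grid steps (default 1), or a vector of
#'   spacings of length `length(rmse) - 1`.
#' @return Scalar lambda estimate (per grid step).
#' @export
lyapunov_stepwise <- function(rmse, dt = 1) {
  if (length(rmse) < 2) stop("need RMSE at >= 2 horizons")
  if (any(rmse <= 0)) stop("RMSE values must be positive")
  if (any(dt <= 0)) stop("dt must be positive")
  rates <- diff(log(rmse)) / dt
  mean(rates)
}

#' Partition prediction error into nonlinearity, chaos, and stochasticity
#'
#' Starting from the mean squared error of the global linear fit
#' (theta = 0, the "total variation") and of the best-theta S-map fit:
#' the nonlinearity component is the error removed by allowing
#' state-dependent dynamics, `mse_total - mse_best`; the chaos component is
#' the part of the remaining error attributable to exponential divergence,
#' `mse_best * (1 - exp(-lambda_est))` when `lambda_est > 0` and exactly 0
#' otherwise (divergence cannot contribute when trajectories converge); and
#' stochasticity is the remainder. Each component is divided by
#' `mse_total` to give fractions that sum to 1. If numerical clamping to
#' [0, 1] was needed the fractions are renormalized and flagged.
#'
#' @param mse_total MSE of the theta = 0 fit (> 0).
#' @param mse_best MSE at the best theta (>= 0). Should not exceed
#'   `mse_total`; if it does, the nonlinearity component is floored at 0
#'   and the partition is flagged.
#' @param lambda_est Lyapunov rate per grid step (see
#'   [lyapunov_stepwise()]).
#' @param chaos_formula `"squared"` (default) uses the factor
#'   `1 - exp(-2 * lambda_est)`, the variance-consistent form implied by
#'   the implied non-chaotic error `rmse0 = rmse_best / exp(lambda_est)`
#'   (chaos component = `mse_best - rmse0^2`); `"printed"` uses
#'   `1 - exp(-lambda_est)`, which treats the exponential divergence factor
#'   on the RMSE scale as if it applied to the MSE directly.
#' @return Object of class `error_partition` with the inputs, `rmse0` (the
#'   implied non-chaotic RMSE), the three fractions, and `flags`.
#' @export
partition_error <- function(mse_total, mse_best, lambda_est,
                            chaos_formula = c("squared", "printed")) {
  chaos_formula <- match.arg(chaos_formula)
  if (!is.finite(mse_total) || mse_total <= 0) stop("mse_total must be > 0")
  if (!is.finite(mse_best) || mse_best < 0) stop("mse_best must be >= 0")
  flags <- character(0)
  nonlin_raw <- mse_total - mse_best
  if (nonlin_raw < 0) {
    flags <- c(flags, "mse_best_exceeds_total")
    nonlin_raw <- 0
  }
  if (lambda_est > 0) {
    k <- if (chaos_formula == "printed") 1 else 2
    chaos_raw <- mse_best * (1 - exp(-k * lambda_est))
    rmse0 <- sqrt(mse_best) / exp(lambda_est)
  } else {
    chaos_raw <- 0
    rmse0 <- sqrt(mse_best)
  }
  stoch_raw <- mse_total - nonlin_raw - chaos_raw
  fr <- c(nonlinearity = nonlin_raw, chaos = chaos_raw,
          stochasticity = stoch_raw) / mse_total
  if (any(fr < 0) || any(fr > 1)) {
    flags <- c(flags, "clamped")
    fr <- pmin(pmax(fr, 0), 1)
    fr <- fr / sum(fr)
  }
  structure(list(mse_total = mse_total, mse_best = mse_best,
                 lambda_est = lambda_est, rmse0 = rmse0,
                 chaos_formula = chaos_formula,
                 frac_nonlinearity = unname(fr["nonlinearity"]),
                 frac_chaos = unname(fr["chaos"]),
                 frac_stochasticity = unname(fr["stochasticity"]),
                 flags = flags),
            class = "error_partition")
}

#' @export
print.error_partition <- function(x, ...) {
  cat(sprintf(
    "<error_partition> lambda_est = %.4g; fractions: nonlinearity %.3f, chaos %.3f, stochasticity %.3f%s\n",
    x$lambda_est, x$frac_nonlinearity, x$frac_chaos, x$frac_stochasticity,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Classify forecast skill against the half-standard-deviation rule
#'
#' A forecast is "good" when its MAE is strictly below half the standard
#' deviation of the observations, a common rule of thumb for acceptable
#' model performance; the standardized MAE (MAE / sd) is returned for
#' contouring.
#'
#' @param mae Nonnegative MAE.
#' @param observed_sd Standard deviation of the observed series (> 0).
#' @return List with `class` (`"good"` or `"poor"`) and `standardized_mae`.
#' @export
classify_fit <- function(mae, observed_sd) {
  if (!is.finite(observed_sd) || observed_sd <= 0) {
    stop("classification undefined: observed standard deviation must be > 0")
  }
  list(class = if (mae < observed_sd / 2) "good" else "poor",
       standardized_mae = mae / observed_sd)
}

#' Full error partition for one series
#'
#' Runs the complete single-series partition pipeline: select the embedding
#' dimension (leave-one-out simplex), profile theta (leave-one-out S-map at
#' horizon 1), take the theta = 0 MSE as the total variation and the
#' minimum-MSE theta as the best fit, estimate the Lyapunov rate from the
#' growth of the best-theta RMSE across `lambda_horizons`, and partition.
#'
#' @param series A [replicate_series()] on a regular grid.
#' @param E Embedding dimension; `NULL` selects it via [select_E()].
#' @param theta_grid Candidate theta values (must include 0).
#' @param tau Lag in grid steps.
#' @param lambda_horizons Horizons whose RMSE growth defines the Lyapunov
#'   rate; default `c(1, 2)` (consecutive one-step comparison), longer
#'   sequences average the per-step rates.
#' @param chaos_formula Passed to [partition_error()].
#' @param target_species Species analyzed (univariate embedding).
#' @param E_grid Candidate dimensions when `E` is `NULL`.
#' @return An `error_partition` with attributes `E` and `theta` recording
#'   the selected hyperparameters.
#' @export
partition_series <- function(series, E = NULL,
                             theta_grid = default_theta_grid(),
                             tau = 1, lambda_horizons = c(1, 2),
                             chaos_formula = c("squared", "printed"),
                             target_species = NULL, E_grid = 1:8) {
  chaos_formula <- match.arg(chaos_formula)
  if (is.null(E)) {
    E <- select_E(series, E_grid = E_grid, tau = tau, tp = 1,
                  target_species = target_species)$E
  }
  sel <- select_theta(series, E = E, theta_grid = theta_grid, tau = tau,
                      tp = 1, target_species = target_species)
  tab <- sel$table
  mse_total <- tab$mse[tab$theta == 0]
  if (!length(mse_total)) stop("theta_grid must include 0")
  theta_best <- sel$theta_mse
  mse_best <- min(tab$mse)
  rmse_seq <- vapply(lambda_horizons, function(tp) {
    block <- embed_series(series, embedding_spec(E, tau, tp, "univariate",
                                                 target_species))
    smap_forecast(block, theta = theta_best)$diagnostics$rmse
  }, numeric(1))
  lam <- lyapunov_stepwise(rmse_seq, dt = diff(lambda_horizons))
  part <- partition_error(mse_total, mse_best, lam, chaos_formula)
  attr(part, "E") <- E
  attr(part, "theta") <- theta_best
  part
}
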