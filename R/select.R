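#' Default S-map localization grid
#'
#' The customary grid of candidate theta values, from 0 (a single global
#' linear model) to strongly localized regressions.
#'
#' @return Numeric vector of theta candidates.
#' @export
default_theta_grid <- function() {
  c(0, 1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 0.5,
    0.75, 1, 1.5, 2, 3, 4, 6, 8)
}

#' Select the embedding dimension by leave-one-out simplex projection
#'
#' Each candidate E is scored by the leave-one-out cross-validated MAE of
#' simplex projection on the series; the E minimizing MAE wins, with exact
#' ties broken in favor of the smaller E. Candidates for which the series is
#' too short are skipped with a warning.
#'
#' @param series A [replicate_series()] on a regular grid.
#' @param E_grid Candidate embedding dimensions (default 1:8).
#' @param tau Lag in grid steps.
#' @param tp Forecast horizon in grid steps.
#' @param target_species Species to forecast (univariate lag embedding).
#' @return List with `E` (the selected dimension) and `table`, a data frame
#'   of per-candidate diagnostics (E, mae, mse, rmse, e2, n).
#' @export
select_E <- function(series, E_grid = 1:8, tau = 1, tp = 1,
                     target_species = NULL) {
  stopifnot(length(E_grid) >= 1)
  rows <- lapply(E_grid, function(E) {
    sp <- embedding_spec(E, tau, tp, "univariate", target_species)
    res <- tryCatch({
      block <- embed_series(series, sp)
      simplex_forecast(block)$diagnostics
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("E = ", E, " skipped: ", conditionMessage(res), call. = FALSE)
      return(NULL)
    }
    data.frame(E = E, mae = res$mae, mse = res$mse, rmse = res$rmse,
               e2 = res$e2, n = res$n)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) {
    stop("no embedding dimension in E_grid is usable for this series")
  }
  tab <- tab[order(tab$E), , drop = FALSE]
  ysd <- stats::sd(series$abundances[, if (is.null(target_species))
    series$species[1] else target_species])
  list(E = tab$E[argmin_with_ties(tab$mae, 1e-10 * ysd)], table = tab)
}

# Smallest-parameter tie-break robust to floating-point jitter: when
# several candidates fit to numerical zero (error below `floor_tol`, a tiny
# multiple of the data scale) they are treated as exact ties and the first
# (smallest parameter, given a sorted table) wins.
argmin_with_ties <- function(err, floor_tol) {
  if (is.finite(floor_tol) && floor_tol > 0 && min(err) < floor_tol) {
    return(which(err < floor_tol)[1])
  }
  which.min(err)
}

#' Select the S-map localization exponent by leave-one-out cross-validation
#'
#' Profiles the leave-one-out S-map MAE over a grid of theta values and
#' returns the minimizer (ties broken toward smaller theta, so exactly
#' linear dynamics select theta = 0). The full MAE-vs-theta profile is the
#' standard nonlinearity diagnostic: forecast skill improving for theta > 0
#' indicates state-dependent (nonlinear) dynamics.
#'
#' @inheritParams select_E
#' @param E Embedding dimension (univariate mode).
#' @param theta_grid Candidate theta values; must contain 0 to anchor the
#'   linear benchmark.
#' @param mode `"univariate"` lag embedding or multivariate `"block"`.
#' @return List with `theta`, `theta_mse` (the theta minimizing MSE, used by
#'   the error partition), and `table` (theta, mae, mse, rmse, e2, n).
#' @export
select_theta <- function(series, E = 2, theta_grid = default_theta_grid(),
                         tau = 1, tp = 1, target_species = NULL,
                         mode = c("univariate", "block")) {
  mode <- match.arg(mode)
  stopifnot(length(theta_grid) >= 1)
  if (!0 %in% theta_grid) {
    warning("theta_grid does not contain 0; the linear benchmark is missing")
  }
  block <- embed_series(series, embedding_spec(E, tau, tp, mode, target_species))
  rows <- lapply(sort(theta_grid), function(th) {
    dg <- smap_forecast(block, theta = th)$diagnostics
    data.frame(theta = th, mae = dg$mae, mse = dg$mse, rmse = dg$rmse,
               e2 = dg$e2, n = dg$n)
  })
  tab <- do.call(rbind, rows)
  ysd <- stats::sd(block$targets)
  list(theta = tab$theta[argmin_with_ties(tab$mae, 1e-10 * ysd)],
       theta_mse = tab$theta[argmin_with_ties(tab$mse, (1e-10 * ysd)^2)],
       table = tab)
}
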