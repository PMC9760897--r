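#' Forecast diagnostics: MAE, MSE, RMSE and the coefficient of efficiency
#'
#' The coefficient of efficiency E2 = 1 - sum((obs - pred)^2) /
#' sum((obs - mean(obs))^2) measures scatter around the 1:1 line: 1 is a
#' perfect forecast and 0 is no better than predicting the observed mean.
#' Pairs with missing values are dropped before computation.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return An object of class `forecast_diagnostics` with fields `mae`,
#'   `mse`, `rmse`, `e2`, `n`. When the observations have zero variance `e2`
#'   is `NA` and the object carries the flag `"e2_undefined"`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 5))
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  n <- length(o)
  if (n < 2) stop("goodness_of_fit needs at least 2 defined pairs")
  err <- o - p
  ss_tot <- sum((o - mean(o))^2)
  flags <- character(0)
  if (ss_tot == 0) {
    e2 <- NA_real_
    flags <- "e2_undefined"
  } else {
    e2 <- 1 - sum(err^2) / ss_tot
  }
  structure(list(mae = mean(abs(err)), mse = mean(err^2),
                 rmse = sqrt(mean(err^2)), e2 = e2, n = n,
                 flags = flags),
            class = "forecast_diagnostics")
}

#' @export
print.forecast_diagnostics <- function(x, ...) {
  cat(sprintf("<forecast_diagnostics> n = %d, MAE = %.4g, RMSE = %.4g, E2 = %.4g\n",
              x$n, x$mae, x$rmse, x$e2))
  invisible(x)
}

# Diagnostics need >= 2 observed/predicted pairs; prediction-only queries
# (e.g. a single state, or NA targets) get NULL instead of an error.
maybe_diagnostics <- function(observed, predicted) {
  if (sum(is.finite(observed) & is.finite(predicted)) < 2) return(NULL)
  goodness_of_fit(observed, predicted)
}

# Indices of library rows usable for a given query under leave-one-out:
# rows sharing the query's time stamp are excluded.
usable_rows <- function(library, query_time, loo) {
  if (!loo) return(seq_len(nrow(library$rows)))
  which(library$row_times != query_time)
}

#' Simplex projection forecasting
#'
#' For each query state, the E+1 nearest library states (Euclidean distance)
#' are found and the forecast is the weighted mean of their targets with
#' weights w_i = exp(-d_i / d_1), where d_1 is the distance to the nearest
#' neighbor. If the nearest neighbor coincides with the query (d_1 = 0), all
#' zero-distance neighbors are averaged with equal weight. In
#' self-prediction (`loo = TRUE`) library rows sharing a query's time stamp
#' are excluded, giving leave-one-out cross-validation.
#'
#' @param library An [embed_series()] block providing states and targets.
#' @param queries An `embedded_block` of the same dimension to forecast for;
#'   defaults to the library itself (self-prediction).
#' @param loo Exclude library rows whose time stamp equals the query's.
#'   Defaults to `TRUE` when `queries` is the library itself.
#' @param n_neighbors Number of neighbors; defaults to dimension + 1.
#' @return List with `forecasts`, `observed`, and `diagnostics`
#'   (a [goodness_of_fit()] object), of class `simplex_forecast`.
#' @export
simplex_forecast <- function(library, queries = library,
                             loo = missing(queries), n_neighbors = NULL) {
  stopifnot(inherits(library, "embedded_block"),
            inherits(queries, "embedded_block"),
            ncol(library$rows) == ncol(queries$rows))
  k <- if (is.null(n_neighbors)) ncol(library$rows) + 1L else n_neighbors
  nq <- nrow(queries$rows)
  forecasts <- numeric(nq)
  for (i in seq_len(nq)) {
    use <- usable_rows(library, queries$row_times[i], loo)
    if (length(use) < k) {
      stop("fewer than ", k, " usable library rows for query at t = ",
           queries$row_times[i])
    }
    d <- state_distances(library$rows[use, , drop = FALSE],
                         queries$rows[i, ])
    ord <- order(d)[seq_len(k)]
    dn <- d[ord]
    tn <- library$targets[use][ord]
    if (dn[1] == 0) {
      forecasts[i] <- mean(tn[dn == 0])
    } else {
      w <- exp(-dn / dn[1])
      forecasts[i] <- sum(w * tn) / sum(w)
    }
  }
  structure(list(forecasts = forecasts,
                 observed = queries$targets,
                 row_times = queries$row_times,
                 diagnostics = maybe_diagnostics(queries$targets, forecasts)),
            class = "simplex_forecast")
}

# Weighted least squares through a rank-tolerant SVD (relative singular
# value cutoff 1e-10); returns the pseudoinverse solution when the design
# is rank deficient.
svd_wls <- function(X, y, w, rcond = 1e-10) {
  sw <- sqrt(w)
  s <- svd(X * sw)
  keep <- s$d > rcond * s$d[1]
  if (!any(keep)) stop("singular fit: design has no usable singular values")
  coef <- s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], y * sw)) / s$d[keep])
  drop(coef)
}

#' S-map forecasting (sequential locally weighted global linear maps)
#'
#' For each query state y, all library states are weighted by
#' w_i = exp(-theta d_i / dbar), where d_i is the Euclidean distance from y
#' to library state i and dbar is the mean distance from y to all library
#' states. A weighted linear regression of the targets on the states (with
#' intercept) is solved by a rank-tolerant SVD, and the forecast is the
#' fitted linear function evaluated at y. theta = 0 gives every state equal
#' weight, i.e. a single global linear model; larger theta localizes the
#' regression, which improves forecasts when the dynamics are nonlinear.
#'
#' The per-query regression coefficients are retained: in a multivariate
#' block embedding the coefficient of species j in the regression
#' forecasting species k is the time-varying interaction coefficient
#' (the effect of j on k) at that point of the trajectory.
#'
#' @inheritParams simplex_forecast
#' @param theta Nonnegative localization exponent.
#' @return An object of class `smap_fit` with fields `theta`,
#'   `coefficients` (one row per query; one named column per embedding
#'   dimension plus `"intercept"`), `forecasts`, `observed`, `row_times`,
#'   and `diagnostics`.
#' @export
smap_forecast <- function(library, queries = library, theta = 0,
                          loo = missing(queries)) {
  stopifnot(inherits(library, "embedded_block"),
            inherits(queries, "embedded_block"),
            ncol(library$rows) == ncol(queries$rows),
            theta >= 0)
  dim <- ncol(library$rows)
  nq <- nrow(queries$rows)
  forecasts <- numeric(nq)
  coefs <- matrix(NA_real_, nrow = nq, ncol = dim + 1L,
                  dimnames = list(NULL, c(colnames(library$rows), "intercept")))
  for (i in seq_len(nq)) {
    use <- usable_rows(library, queries$row_times[i], loo)
    if (length(use) <= dim + 1L) {
      stop("S-map needs more than dim + 1 usable library rows (have ",
           length(use), ")")
    }
    lib <- library$rows[use, , drop = FALSE]
    if (all(apply(lib, 2, function(v) max(v) == min(v)))) {
      stop("singular fit: all usable library states are identical")
    }
    if (theta == 0) {
      w <- rep(1, length(use))
    } else {
      d <- state_distances(lib, queries$rows[i, ])
      dbar <- mean(d)
      if (dbar == 0) stop("mean library distance is 0; cannot scale S-map weights")
      w <- exp(-theta * d / dbar)
    }
    b <- svd_wls(cbind(lib, 1), library$targets[use], w)
    coefs[i, ] <- b
    forecasts[i] <- sum(b * c(queries$rows[i, ], 1))
  }
  structure(list(theta = theta,
                 coefficients = coefs,
                 forecasts = forecasts,
                 observed = queries$targets,
                 row_times = queries$row_times,
                 target_species = queries$target_species,
                 diagnostics = maybe_diagnostics(queries$targets, forecasts)),
            class = "smap_fit")
}

#' @export
print.smap_fit <- function(x, ...) {
  cat(sprintf("<smap_fit> theta = %g, %d forecasts of '%s', MAE = %.4g, E2 = %.4g\n",
              x$theta, length(x$forecasts), x$target_species,
              x$diagnostics$mae, x$diagnostics$e2))
  invisible(x)
}
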