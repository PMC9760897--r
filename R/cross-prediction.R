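#' Euclidean distance between the initial abundances of two replicates
#'
#' Delta-N0 = sqrt(sum over species of (N0_A - N0_B)^2). Larger values mean
#' the two replicates started further apart in phase space.
#'
#' @param repA,repB [replicate_series()] objects with the same species list.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' a <- replicate_series("a", 0:3, cbind(prey = c(5, 6, 7, 8),
#'                                       predator = c(10, 9, 8, 7)))
#' b <- replicate_series("b", 0:3, cbind(prey = c(8, 6, 7, 8),
#'                                       predator = c(14, 9, 8, 7)))
#' initial_distance(a, b)  # 5 (the 3-4-5 triangle)
initial_distance <- function(repA, repB) {
  if (!identical(repA$species, repB$species)) {
    stop("replicates '", repA$replicate_id, "' and '", repB$replicate_id,
         "' have different species lists")
  }
  sqrt(sum((repA$N0 - repB$N0)^2))
}

#' Cross-predict one replicate from another
#'
#' Trains the S-map forecaster on the source replicate and applies it to the
#' target replicate, for each horizon `tp` in `horizons`. In the multivariate
#' block mode every species is forecast in turn (one regression per target
#' species) and a pooled error over all species is reported alongside the
#' per-species diagnostics. The Lyapunov exponent is then estimated from the
#' growth of the pooled log(MAE) with horizon via
#' [lyapunov_from_horizons()].
#'
#' @param source,target [replicate_series()] objects regularized on the same
#'   step. When `source` and `target` are the same replicate, leave-one-out
#'   exclusion is applied and the record reduces to self-prediction.
#' @param E Embedding dimension for the univariate mode (the block mode uses
#'   one dimension per species; for a two-species system that is the
#'   theoretically expected E = 2).
#' @param theta S-map localization exponent (typically selected on the
#'   source replicate by [select_theta()]).
#' @param horizons Forecast horizons in grid steps, default 1:10.
#' @param mode `"block"` (default) or `"univariate"`.
#' @param tau Lag for the univariate mode.
#' @param target_species Species forecast in univariate mode; in block mode
#'   all species are forecast.
#' @param loo Exclude same-time library rows. Defaults to `TRUE` exactly
#'   when source and target share a replicate id (self-prediction); set it
#'   explicitly when cross-predicting between replicates known to be copies
#'   of one another.
#' @return Object of class `cross_prediction_record`: ids, `delta_N0`,
#'   `E_used`, `theta_used`, a per-(horizon, species) diagnostics table, a
#'   pooled per-horizon table, and the `lyapunov` estimate (or NULL if
#'   fewer than 2 horizons were usable).
#' @export
cross_predict <- function(source, target, E = 2, theta = 0,
                          horizons = 1:10,
                          mode = c("block", "univariate"),
                          tau = 1, target_species = NULL,
                          loo = identical(source$replicate_id,
                                          target$replicate_id)) {
  mode <- match.arg(mode)
  species_set <- if (mode == "block") source$species
                 else if (is.null(target_species)) source$species[1]
                 else target_species
  E_used <- if (mode == "block") length(source$species) else E
  per_species <- list()
  pooled <- list()
  for (tp in horizons) {
    errs <- c()
    sp_rows <- list()
    skipped <- FALSE
    for (sp in species_set) {
      spec <- embedding_spec(E, tau, tp, mode, sp)
      fit <- tryCatch({
        lib <- embed_series(source, spec)
        qry <- embed_series(target, spec)
        smap_forecast(lib, qry, theta = theta, loo = loo)
      }, error = function(e) e)
      if (!inherits(fit, "error") && is.null(fit$diagnostics)) {
        fit <- simpleError("too few prediction points for diagnostics")
      }
      if (inherits(fit, "error")) {
        warning("pair (", source$replicate_id, " -> ", target$replicate_id,
                "), tp = ", tp, ", species '", sp, "' skipped: ",
                conditionMessage(fit), call. = FALSE)
        skipped <- TRUE
        next
      }
      dg <- fit$diagnostics
      sp_rows[[sp]] <- data.frame(tp = tp, species = sp, mae = dg$mae,
                                  mse = dg$mse, rmse = dg$rmse,
                                  e2 = dg$e2, n = dg$n)
      errs <- c(errs, fit$observed - fit$forecasts)
    }
    per_species <- c(per_species, sp_rows)
    if (length(errs) >= 2) {
      pooled[[as.character(tp)]] <- data.frame(
        tp = tp, mae = mean(abs(errs)), mse = mean(errs^2),
        rmse = sqrt(mean(errs^2)), n = length(errs),
        skipped = skipped)
    }
  }
  per_species <- rbind_rows(per_species)
  pooled <- rbind_rows(pooled)
  lyap <- NULL
  if (!is.null(pooled) && nrow(pooled) >= 2 && all(pooled$mae > 0)) {
    lyap <- lyapunov_from_horizons(pooled$mae, pooled$tp)
  }
  structure(list(source_id = source$replicate_id,
                 target_id = target$replicate_id,
                 delta_N0 = initial_distance(source, target),
                 E_used = E_used, theta_used = theta,
                 horizons = horizons, mode = mode,
                 table = per_species, pooled = pooled,
                 lyapunov = lyap),
            class = "cross_prediction_record")
}

#' @export
print.cross_prediction_record <- function(x, ...) {
  lam <- if (is.null(x$lyapunov)) NA_real_ else x$lyapunov$lambda
  cat(sprintf(
    "<cross_prediction_record> %s -> %s: dN0 = %.4g, theta = %g, mean MAE = %.4g, lambda = %.4g\n",
    x$source_id, x$target_id, x$delta_N0, x$theta_used,
    mean(x$pooled$mae), lam))
  invisible(x)
}

# theta selected on the source replicate: mean leave-one-out MAE across all
# species (block mode) or on the single target species (univariate mode).
select_theta_for_source <- function(series, E, theta_grid, tau, mode,
                                    target_species = NULL) {
  species_set <- if (mode == "block") series$species
                 else if (is.null(target_species)) series$species[1]
                 else target_species
  maes <- sapply(species_set, function(sp) {
    select_theta(series, E = E, theta_grid = theta_grid, tau = tau,
                 tp = 1, target_species = sp, mode = mode)$table$mae
  })
  grid <- sort(theta_grid)
  grid[which.min(rowMeans(matrix(maes, nrow = length(grid))))]
}

#' All ordered cross-prediction pairs of a dataset
#'
#' Runs [cross_predict()] for every ordered pair (A, B), A != B, giving
#' n (n - 1) records for n replicates; both orderings are retained. The
#' S-map theta for each pair is selected on the source replicate by
#' leave-one-out cross-validation (`theta_policy = "source"`) or supplied as
#' a fixed number.
#'
#' @param dataset An [edm_dataset()] with >= 2 replicates, already
#'   regularized on a common grid.
#' @param E Embedding dimension, fixed at 2 by default for cross-prediction.
#' @param theta Fixed theta, or `NULL` to select per source replicate.
#' @param theta_grid Grid used when selecting theta.
#' @param horizons Forecast horizons.
#' @param mode,tau,target_species Passed to [cross_predict()].
#' @param include_self Also produce the n self-pairs (leave-one-out
#'   self-prediction records), flagged by `source_id == target_id`.
#' @return List of `cross_prediction_record` objects, of class
#'   `pairwise_records`. Use [as.data.frame()] for the tidy table.
#' @export
pairwise_table <- function(dataset, E = 2, theta = NULL,
                           theta_grid = default_theta_grid(),
                           horizons = 1:10,
                           mode = c("block", "univariate"),
                           tau = 1, target_species = NULL,
                           include_self = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "edm_dataset"))
  reps <- dataset$replicates
  if (length(reps) < 2) {
    stop("cross-prediction needs at least 2 replicates; dataset '",
         dataset$name, "' has ", length(reps))
  }
  thetas <- if (is.null(theta)) {
    vapply(reps, select_theta_for_source, numeric(1), E = E,
           theta_grid = theta_grid, tau = tau, mode = mode,
           target_species = target_species)
  } else {
    stats::setNames(rep(theta, length(reps)), names(reps))
  }
  records <- list()
  for (a in names(reps)) {
    for (b in names(reps)) {
      if (a == b && !include_self) next
      records[[paste(a, b, sep = "->")]] <-
        cross_predict(reps[[a]], reps[[b]], E = E, theta = thetas[[a]],
                      horizons = horizons, mode = mode, tau = tau,
                      target_species = target_species)
    }
  }
  structure(records, class = "pairwise_records")
}

#' Flatten cross-prediction records into a tidy table
#'
#' One row per (pair, horizon, species), with the pair-level Delta-N0,
#' Lyapunov estimate and its p-value repeated across rows.
#'
#' @param x A `pairwise_records` list from [pairwise_table()].
#' @param ... Unused.
#' @return A data frame with columns source_id, target_id, delta_N0, tp,
#'   species, mae, mse, rmse, e2, n, lambda, lambda_p, E, theta.
#' @export
as.data.frame.pairwise_records <- function(x, ...) {
  rows <- lapply(unname(x), function(r) {
    if (is.null(r$table)) return(NULL)
    lam <- if (is.null(r$lyapunov)) c(NA_real_, NA_real_)
           else c(r$lyapunov$lambda, r$lyapunov$p_value)
    data.frame(source_id = r$source_id, target_id = r$target_id,
               delta_N0 = r$delta_N0, r$table,
               lambda = lam[1], lambda_p = lam[2],
               E = r$E_used, theta = r$theta_used,
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

rbind_rows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
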