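#' Specify a state-space embedding
#'
#' In univariate mode the reconstructed state at time t is the lag vector
#' (x(t), x(t - tau), ..., x(t - (E-1) tau)) of the target species. In
#' multivariate block mode the state is the simultaneous abundance vector of
#' all species (one embedding dimension per species), which is equivalent to
#' the lagged reconstruction by Takens' theorem for a closed system.
#'
#' @param E Embedding dimension (>= 1). In block mode E is implied by the
#'   number of species and this value is ignored.
#' @param tau Lag, in grid steps (>= 1).
#' @param tp Time-to-prediction horizon, in grid steps (>= 1).
#' @param mode `"univariate"` or `"block"`.
#' @param target_species Species whose future value is forecast. Required in
#'   univariate mode when the series has more than one species; defaults to
#'   the first species.
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(E = 2, tau = 1, tp = 1,
                           mode = c("univariate", "block"),
                           target_species = NULL) {
  mode <- match.arg(mode)
  stopifnot(E >= 1, tau >= 1, tp >= 1,
            E == round(E), tau == round(tau), tp == round(tp))
  structure(list(E = as.integer(E), tau = as.integer(tau),
                 tp = as.integer(tp), mode = mode,
                 target_species = target_species),
            class = "embedding_spec")
}

#' Build the embedded state matrix and forecast targets for a series
#'
#' Rows whose lags would fall before the start of the series, or whose
#' target would fall after its end, are excluded, so every returned row is a
#' complete state vector paired with the observed target value `tp` steps
#' ahead. In univariate mode the row count is
#' `n - (E - 1) * tau - tp` for a series of length `n`; in block mode it is
#' `n - tp`.
#'
#' @param series A [replicate_series()] on a regular grid.
#' @param spec An [embedding_spec()].
#' @return An object of class `embedded_block` with fields `rows` (state
#'   matrix, one named column per embedding dimension), `targets`,
#'   `row_times` (time stamps of the states), `target_times`, and `spec`.
#' @export
embed_series <- function(series, spec) {
  validate_replicate_series(series)
  stopifnot(inherits(spec, "embedding_spec"))
  target <- spec$target_species
  if (is.null(target)) target <- series$species[1]
  if (!target %in% series$species) {
    stop("target species '", target, "' not present in replicate '",
         series$replicate_id, "'")
  }
  n <- length(series$times)
  y <- series$abundances[, target]
  if (spec$mode == "univariate") {
    first <- (spec$E - 1L) * spec$tau + 1L
    last <- n - spec$tp
    if (last < first) {
      stop("insufficient data: series '", series$replicate_id,
           "' too short for E = ", spec$E, ", tau = ", spec$tau,
           ", tp = ", spec$tp)
    }
    idx <- first:last
    rows <- vapply(0:(spec$E - 1L),
                   function(k) y[idx - k * spec$tau],
                   numeric(length(idx)))
    rows <- matrix(rows, nrow = length(idx))
    colnames(rows) <- paste0(target, "_lag", 0:(spec$E - 1L) * spec$tau)
  } else {
    last <- n - spec$tp
    if (last < 1L) {
      stop("insufficient data: series '", series$replicate_id,
           "' too short for tp = ", spec$tp)
    }
    idx <- seq_len(last)
    rows <- series$abundances[idx, , drop = FALSE]
    colnames(rows) <- series$species
  }
  structure(list(rows = rows,
                 targets = y[idx + spec$tp],
                 row_times = series$times[idx],
                 target_times = series$times[idx + spec$tp],
                 spec = spec,
                 target_species = target,
                 replicate_id = series$replicate_id),
            class = "embedded_block")
}

#' @export
print.embedded_block <- function(x, ...) {
  cat("<embedded_block> ", nrow(x$rows), " states of dimension ",
      ncol(x$rows), " (", x$spec$mode, "), target '", x$target_species,
      "' at tp = ", x$spec$tp, "\n", sep = "")
  invisible(x)
}

# Euclidean distances from one query state to every library row, computed
# by direct differencing (no cross-product shortcut) to keep full precision
# for near-coincident states.
state_distances <- function(lib_rows, query) {
  d2 <- colSums((t(lib_rows) - query)^2)
  sqrt(pmax(d2, 0))
}
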