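#' Construct a single experimental replicate time series
#'
#' A `replicate_series` holds one experimental replicate: a strictly
#' increasing time grid (in days), a nonnegative abundance matrix with one
#' column per species, the species roles (prey, predator, or other), and the
#' initial-abundance vector `N0`, which is always the first row of the
#' abundance matrix.
#'
#' @param replicate_id Character scalar identifying the replicate.
#' @param times Numeric vector of observation times in days, strictly
#'   increasing.
#' @param abundances Numeric matrix, `length(times)` rows by one column per
#'   species, all entries nonnegative. Column names are the species labels.
#' @param roles Named character vector mapping each species to one of
#'   `"prey"`, `"predator"`, `"other"`. Defaults to `"other"` for all.
#' @param unit Opaque unit string carried along with the abundances (e.g.
#'   `"individuals"` or `"individuals per 0.5 cm^3"`).
#'
#' @return An object of class `replicate_series` with fields
#'   `replicate_id`, `species`, `roles`, `times`, `abundances`, `N0`, `unit`.
#' @export
#' @examples
#' rs <- replicate_series("r1", times = c(0, 1, 2),
#'                        abundances = cbind(prey = c(5, 7, 6),
#'                                           predator = c(1, 2, 4)),
#'                        roles = c(prey = "prey", predator = "predator"))
#' rs$N0
replicate_series <- function(replicate_id, times, abundances,
                             roles = NULL, unit = "individuals") {
  if (is.data.frame(abundances)) abundances <- as.matrix(abundances)
  if (is.null(dim(abundances))) {
    abundances <- matrix(abundances, ncol = 1,
                         dimnames = list(NULL, "x"))
  }
  if (is.null(colnames(abundances))) {
    colnames(abundances) <- paste0("x", seq_len(ncol(abundances)))
  }
  species <- colnames(abundances)
  if (is.null(roles)) {
    roles <- stats::setNames(rep("other", length(species)), species)
  }
  x <- structure(list(
    replicate_id = as.character(replicate_id),
    species      = species,
    roles        = roles[species],
    times        = as.numeric(times),
    abundances   = abundances,
    N0           = abundances[1, , drop = TRUE],
    unit         = unit
  ), class = "replicate_series")
  validate_replicate_series(x)
  x
}

#' Validate the invariants of a replicate series
#'
#' Checks that times are strictly increasing, abundances are nonnegative and
#' conformable with the time grid, and `N0` equals the first abundance row.
#'
#' @param x A `replicate_series`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_replicate_series <- function(x) {
  stopifnot(inherits(x, "replicate_series"))
  if (length(x$times) != nrow(x$abundances)) {
    stop("times and abundance rows do not match for replicate '",
         x$replicate_id, "'")
  }
  if (length(x$times) >= 2 && any(diff(x$times) <= 0)) {
    stop("times must be strictly increasing in replicate '",
         x$replicate_id, "'")
  }
  if (anyNA(x$abundances)) {
    stop("missing abundances in replicate '", x$replicate_id, "'")
  }
  if (any(x$abundances < 0)) {
    stop("negative abundance in replicate '", x$replicate_id, "'")
  }
  if (!isTRUE(all.equal(unname(x$N0),
                        unname(x$abundances[1, , drop = TRUE]),
                        tolerance = 0))) {
    stop("N0 must equal the first abundance row in replicate '",
         x$replicate_id, "'")
  }
  bad <- setdiff(x$roles, c("prey", "predator", "other"))
  if (length(bad)) stop("unknown species role(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

#' @export
print.replicate_series <- function(x, ...) {
  cat("<replicate_series> ", x$replicate_id, ": ",
      length(x$times), " time points over [",
      format(min(x$times)), ", ", format(max(x$times)), "] days; species: ",
      paste0(x$species, " (", x$roles, ")", collapse = ", "),
      "; unit: ", x$unit, "\n", sep = "")
  invisible(x)
}

#' Construct a dataset of experimental replicates
#'
#' A dataset bundles replicates that share a species list and units, together
#' with the target interpolation step (in days) used to regularize them.
#' A dataset may hold a single replicate, but cross-prediction requires at
#' least two.
#'
#' @param name Dataset label, e.g. `"PS"` or `"AC"`.
#' @param replicates List of [replicate_series()] objects sharing the same
#'   species list, roles, and unit string.
#' @param step Target interpolation step in days (> 0).
#' @return An object of class `edm_dataset`.
#' @export
edm_dataset <- function(name, replicates, step) {
  stopifnot(length(replicates) >= 1, step > 0)
  for (r in replicates) validate_replicate_series(r)
  sp <- replicates[[1]]$species
  for (r in replicates) {
    if (!identical(r$species, sp)) {
      stop("all replicates must share the same species list")
    }
    if (!identical(r$unit, replicates[[1]]$unit)) {
      stop("all replicates must share the same unit string")
    }
  }
  ids <- vapply(replicates, function(r) r$replicate_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate replicate ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(replicates) <- ids
  structure(list(name = name, replicates = replicates, step = step,
                 species = sp, roles = replicates[[1]]$roles,
                 unit = replicates[[1]]$unit),
            class = "edm_dataset")
}

#' @export
print.edm_dataset <- function(x, ...) {
  cat("<edm_dataset> '", x$name, "': ", length(x$replicates),
      " replicates, species: ", paste(x$species, collapse = ", "),
      ", step = ", x$step, " days\n", sep = "")
  invisible(x)
}

#' Read a replicated time-series dataset from a wide CSV file
#'
#' The expected layout is one row per (replicate, time) observation with a
#' header `replicate_id, time, <species1>, <species2>, ...`. Rows are sorted
#' by time within each replicate; duplicate (replicate, time) rows and
#' negative abundances are rejected.
#'
#' @param path Path to a UTF-8 CSV file with '.' as decimal separator.
#' @param name Dataset label.
#' @param step Target interpolation step in days.
#' @param roles Named character vector of species roles (see
#'   [replicate_series()]); defaults to `"other"` for every species.
#' @param unit Unit string shared by all abundances.
#' @return An [edm_dataset()].
#' @export
read_dataset <- function(path, name = "dataset", step = 1,
                         roles = NULL, unit = "individuals") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("replicate_id", "time")
  if (!all(req %in% names(df))) {
    stop("format error: CSV must contain columns 'replicate_id' and 'time'")
  }
  species <- setdiff(names(df), req)
  if (!length(species)) stop("format error: no species columns found")
  key <- paste(df$replicate_id, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (replicate_id, time) rows in ", path)
  }
  reps <- lapply(split(df, df$replicate_id), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    replicate_series(d$replicate_id[1], d$time,
                     as.matrix(d[, species, drop = FALSE]),
                     roles = roles, unit = unit)
  })
  edm_dataset(name, unname(reps), step)
}

#' Write a dataset back to the wide CSV layout
#'
#' Numbers are formatted with 17 significant digits so that a
#' read/write/read round trip reproduces the doubles bit-for-bit.
#'
#' @param dataset An [edm_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "edm_dataset"))
  rows <- lapply(dataset$replicates, function(r) {
    data.frame(replicate_id = r$replicate_id,
               time = r$times,
               r$abundances,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write_canonical_csv(df, path)
  invisible(path)
}

# Canonical CSV writer: %.17g for doubles so round trips are exact.
write_canonical_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regularize a replicate onto an even time grid by cubic-spline interpolation
#'
#' Irregularly sampled abundances are interpolated with the classic cubic
#' spline (`stats::spline`, `method = "fmm"`), which passes exactly through
#' the observed points and reproduces polynomials up to cubic order. The
#' output grid is anchored at the first observation and never extrapolates
#' beyond the last one. Interpolated abundances are floored at 0, since
#' negative abundances are not meaningful.
#'
#' @param series A [replicate_series()] with at least 4 time points.
#' @param step Grid spacing in days (> 0, and no larger than the observed
#'   time span).
#' @return A new `replicate_series` on the regular grid.
#' @export
spline_regularize <- function(series, step) {
  validate_replicate_series(series)
  if (length(series$times) < 4) {
    stop("insufficient data: cubic spline interpolation needs >= 4 time points")
  }
  if (step <= 0) stop("step must be > 0")
  span <- diff(range(series$times))
  if (step > span) stop("step (", step, ") exceeds the series span (", span, ")")
  t0 <- series$times[1]
  k <- floor(span / step + 1e-9)
  grid <- t0 + step * (0:k)
  interp <- vapply(seq_along(series$species), function(j) {
    y <- stats::spline(series$times, series$abundances[, j],
                       xout = grid, method = "fmm")$y
    pmax(y, 0)
  }, numeric(length(grid)))
  interp <- matrix(interp, nrow = length(grid),
                   dimnames = list(NULL, series$species))
  replicate_series(series$replicate_id, grid, interp,
                   roles = series$roles, unit = series$unit)
}

#' Regularize every replicate in a dataset
#'
#' @param dataset An [edm_dataset()].
#' @param step Grid spacing in days; defaults to the dataset's own `step`.
#' @return An [edm_dataset()] whose replicates lie on regular grids.
#' @export
regularize_dataset <- function(dataset, step = dataset$step) {
  reps <- lapply(dataset$replicates, spline_regularize, step = step)
  edm_dataset(dataset$name, unname(reps), step)
}

#' Combine two datasets that share species, roles and step
#'
#' Useful for assembling mixed-regime synthetic datasets from separately
#' parameterized generator runs.
#'
#' @param a,b [edm_dataset()] objects with identical species lists and steps.
#' @param name Name for the combined dataset.
#' @return An [edm_dataset()] containing the replicates of both inputs.
#' @export
bind_datasets <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  stopifnot(identical(a$species, b$species), isTRUE(all.equal(a$step, b$step)))
  edm_dataset(name, c(unname(a$replicates), unname(b$replicates)), a$step)
}
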