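#' Assign replicates to two groups by a line in initial-abundance space
#'
#' Replicates whose initial abundances fall on opposite sides of a supplied
#' straight line (in phase space of initial abundances) are assigned to
#' groups 1 and 2. The signed side is `sum(N0 * normal) - offset`: strictly
#' positive values go to group 2, everything else — including points exactly
#' on the boundary — to group 1.
#'
#' @param dataset An [edm_dataset()].
#' @param boundary List with `normal` (numeric vector, one entry per
#'   species, not all zero) and `offset` (scalar).
#' @return Object of class `group_assignment`: a data frame with columns
#'   `replicate_id` and `group`, carrying the boundary as an attribute.
#'   Warns when every replicate lands in a single group.
#' @export
assign_groups <- function(dataset, boundary) {
  stopifnot(inherits(dataset, "edm_dataset"),
            is.list(boundary), !is.null(boundary$normal),
            !is.null(boundary$offset))
  normal <- as.numeric(boundary$normal)
  if (length(normal) != length(dataset$species)) {
    stop("boundary normal must have one entry per species")
  }
  if (all(normal == 0)) stop("degenerate boundary: normal vector is zero")
  side <- vapply(dataset$replicates,
                 function(r) sum(r$N0 * normal) - boundary$offset,
                 numeric(1))
  group <- ifelse(side > 0, 2L, 1L)
  if (length(unique(group)) == 1) {
    warning("all replicates fall on one side of the boundary (group ",
            group[1], ")")
  }
  out <- data.frame(replicate_id = names(dataset$replicates),
                    group = unname(group),
                    stringsAsFactors = FALSE)
  attr(out, "boundary") <- boundary
  class(out) <- c("group_assignment", class(out))
  out
}

group_lookup <- function(groups) {
  stats::setNames(groups$group, groups$replicate_id)
}

#' Per-group mean and standard error of interaction-coefficient trajectories
#'
#' Given multivariate block S-map fits (one per replicate, all forecasting
#' the same target species), extracts the coefficient of a chosen predictor
#' species at every time step — the time-varying interaction coefficient,
#' e.g. the effect of the predator on the prey when the target is the prey
#' — and summarizes it per group as mean +/- standard error over replicates.
#' Trajectories are compared only over time steps present in every member
#' of a group.
#'
#' @param fits Named list of [smap_forecast()] fits (block mode), one per
#'   replicate, names matching replicate ids.
#' @param groups A [assign_groups()] result (or a data frame with
#'   `replicate_id` and `group`).
#' @param effect_of Species whose coefficient is extracted (the predictor).
#' @return Data frame with columns `group`, `time`, `mean`, `se`, `n`.
#'   Groups with a single member get `se = NA` and a warning.
#' @export
mean_interaction_trajectories <- function(fits, groups, effect_of) {
  lk <- group_lookup(groups)
  missing_ids <- setdiff(names(fits), names(lk))
  if (length(missing_ids)) {
    stop("no group assignment for replicate(s): ",
         paste(missing_ids, collapse = ", "))
  }
  out <- list()
  for (g in sort(unique(lk[names(fits)]))) {
    members <- names(fits)[lk[names(fits)] == g]
    if (length(members) < 2) {
      warning("group ", g, " has fewer than 2 replicates; SE undefined")
    }
    common <- Reduce(intersect, lapply(members, function(id) fits[[id]]$row_times))
    if (!length(common)) next
    mat <- vapply(members, function(id) {
      f <- fits[[id]]
      if (!effect_of %in% colnames(f$coefficients)) {
        stop("fit for '", id, "' has no coefficient column '", effect_of, "'")
      }
      f$coefficients[match(common, f$row_times), effect_of]
    }, numeric(length(common)))
    mat <- matrix(mat, nrow = length(common))
    out[[as.character(g)]] <- data.frame(
      group = g, time = common,
      mean = rowMeans(mat),
      se = if (ncol(mat) >= 2) apply(mat, 1, stats::sd) / sqrt(ncol(mat))
           else NA_real_,
      n = ncol(mat))
  }
  rbind_rows(out)
}

#' Within- versus between-group cross-prediction error
#'
#' Averages each record's pooled MAE over its horizons, then summarizes the
#' records by category: within group 1, within group 2, and between groups.
#' Self-pairs (source == target) are excluded.
#'
#' @param records A `pairwise_records` list from [pairwise_table()].
#' @param groups A [assign_groups()] result.
#' @return Data frame with columns `category` (`"within_1"`, `"within_2"`,
#'   `"between"`), `mean_mae`, `n_pairs`. Empty categories are retained
#'   with `n_pairs = 0` and `mean_mae = NA`, with a warning.
#' @export
within_between_mae <- function(records, groups) {
  lk <- group_lookup(groups)
  cat_of <- function(r) {
    ga <- lk[[r$source_id]]; gb <- lk[[r$target_id]]
    if (ga != gb) "between" else paste0("within_", ga)
  }
  recs <- Filter(function(r) r$source_id != r$target_id &&
                   !is.null(r$pooled), unname(records))
  cats <- vapply(recs, cat_of, character(1))
  maes <- vapply(recs, function(r) mean(r$pooled$mae), numeric(1))
  out <- lapply(c("within_1", "within_2", "between"), function(cc) {
    sel <- cats == cc
    if (!any(sel)) {
      warning("no pairs in category ", cc)
      return(data.frame(category = cc, mean_mae = NA_real_, n_pairs = 0L))
    }
    data.frame(category = cc, mean_mae = mean(maes[sel]),
               n_pairs = sum(sel))
  })
  rbind_rows(out)
}
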