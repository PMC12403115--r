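#' Normalized per-tree trajectory
#'
#' Internal constructor for the container shared by all normalization
#' operations: an ordered day vector with values rescaled to \[0, 1\] and a
#' `kind` distinguishing instantaneous state curves (bud score, LAI, NDVI)
#' from cumulative capture curves (frass, caterpillar counts). A trajectory
#' whose metric is undefined for that tree (flat series, zero season total)
#' carries `flag = "undefined"` and no numeric values.
#'
#' @keywords internal
new_trajectory <- function(tree_id, metric, days, y, kind,
                           flag = "ok", observer_id = NULL) {
  if (flag == "ok") {
    stopifnot(length(days) == length(y), !is.unsorted(days, strictly = TRUE),
              all(y >= -1e-12 & y <= 1 + 1e-12))
    y <- pmin(pmax(y, 0), 1)
    if (kind == "cumulative") {
      stopifnot(all(diff(y) >= -1e-12), abs(y[length(y)] - 1) <= 1e-12)
    }
  }
  structure(list(tree_id = tree_id, metric = metric, days = days, y = y,
                 kind = kind, flag = flag, observer_id = observer_id),
            class = "pheno_trajectory")
}

#' @export
print.pheno_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> tree %s, metric %s, %d visits, kind %s, flag %s\n",
              x$tree_id, x$metric, length(x$days), x$kind, x$flag))
  invisible(x)
}

#' Normalize ordinal bud scores to the unit interval
#'
#' Rescales per-tree bud-development scores so that the minimum score of 1
#' maps to 0 and the full-leaf stage (5 for non-oaks, 7 for oaks) maps to 1:
#' y = (score - 1) / (max_stage - 1). Visit-level scores are typically the
#' mean of 12 crown sections (dead sections excluded), so fractional values
#' are accepted.
#'
#' @param days day-of-year of each visit (1 = 1 January).
#' @param scores bud scores in \[1, max_stage\].
#' @param max_stage 5 or 7.
#' @param tree_id identifier used in error messages and downstream tables.
#' @param observer_id optional per-visit observer labels, carried through to
#'   the trajectory for use as a random intercept in [fit_sigmoid()].
#' @return a `pheno_trajectory` of kind `"state"`.
#' @export
normalize_bud_scores <- function(days, scores, max_stage, tree_id = "tree",
                                 observer_id = NULL) {
  stopifnot(max_stage %in% c(5L, 7L), length(days) == length(scores))
  bad <- which(!is.finite(scores) | scores < 1 | scores > max_stage)
  if (length(bad))
    stop(sprintf("tree %s: bud score out of [1, %d] at day(s) %s",
                 tree_id, max_stage, paste(days[bad], collapse = ", ")),
         call. = FALSE)
  o <- order(days)
  if (!is.null(observer_id)) observer_id <- observer_id[o]
  new_trajectory(tree_id, "budburst", days[o],
                 (scores[o] - 1) / (max_stage - 1), "state",
                 observer_id = observer_id)
}

#' Min-max normalize a continuous trajectory (LAI or NDVI)
#'
#' Rescales a per-tree series by its own minimum and maximum:
#' y = (v - min) / (max - min). A flat series leaves the metric undefined for
#' that tree and is returned flagged rather than as numbers. An optional
#' winsorizing hook clamps the series to the given quantiles before the
#' min/max are taken (off by default; outlier screening is otherwise the
#' caller's responsibility).
#'
#' @param days day-of-year of each visit.
#' @param values nonnegative measurements (effective LAI or mean crown NDVI).
#' @param metric metric label, e.g. `"half_leaf"` or `"half_ndvi"`.
#' @param tree_id identifier.
#' @param winsor `NULL`, or a length-2 vector of probabilities, e.g.
#'   `c(0.02, 0.98)`, to clamp to empirical quantiles first.
#' @return a `pheno_trajectory` of kind `"state"`.
#' @export
normalize_minmax <- function(days, values, metric = "half_leaf",
                             tree_id = "tree", winsor = NULL) {
  stopifnot(length(days) == length(values), all(is.finite(values)))
  if (length(unique(days)) < 3)
    stop(sprintf("tree %s: need at least 3 visit days for min-max normalization",
                 tree_id), call. = FALSE)
  o <- order(days)
  days <- days[o]; values <- values[o]
  if (!is.null(winsor)) {
    q <- stats::quantile(values, sort(winsor), names = FALSE)
    values <- pmin(pmax(values, q[1]), q[2])
  }
  rng <- range(values)
  if (diff(rng) <= 0)
    return(new_trajectory(tree_id, metric, days, NULL, "state",
                          flag = "undefined"))
  new_trajectory(tree_id, metric, days, (values - rng[1]) / diff(rng), "state")
}

#' Cumulative-proportion normalization for trap captures
#'
#' Converts per-visit caterpillar counts or frass masses into the cumulative
#' proportion of the season total captured by each visit:
#' y(day) = cumulative sum to that visit / season total. Trees whose season
#' total is zero have no defined half-fall and come back flagged
#' `"undefined"` with no numeric values.
#'
#' @param days day-of-year of each visit.
#' @param values nonnegative per-visit quantities.
#' @param metric metric label, e.g. `"tc_half_fall"`.
#' @param tree_id identifier.
#' @return a `pheno_trajectory` of kind `"cumulative"`.
#' @export
cumulative_proportion <- function(days, values, metric = "half_fall",
                                  tree_id = "tree") {
  stopifnot(length(days) == length(values))
  if (any(!is.finite(values) | values < 0))
    stop(sprintf("tree %s: negative or non-finite capture values", tree_id),
         call. = FALSE)
  o <- order(days)
  days <- days[o]; values <- values[o]
  total <- sum(values)
  if (total <= 0)
    return(new_trajectory(tree_id, metric, days, NULL, "cumulative",
                          flag = "undefined"))
  new_trajectory(tree_id, metric, days, cumsum(values) / total, "cumulative")
}

# method label -> (metric label, normalizer kind)
.method_metric <- c(bud_score = "budburst", lai = "half_leaf",
                    ndvi = "half_ndvi", frass_mass_g = "frass_half_fall",
                    count_total = "tc_half_fall", count_fwm = "fwm_half_fall")

#' Normalize a long-format observation table
#'
#' Dispatches each tree x method series to the appropriate normalization
#' ([normalize_bud_scores()], [normalize_minmax()] or
#' [cumulative_proportion()]) and returns the trajectories as a list.
#'
#' @param observations long-format data.frame with columns `tree_id`,
#'   `method`, `day`, `value` and optionally `observer_id`.
#' @param trees tree metadata with `tree_id` and `max_stage` (required when
#'   bud scores are present).
#' @param methods subset of methods to process (default: all present).
#' @return named list of `pheno_trajectory` objects (`tree_id.metric`).
#' @export
normalize_observations <- function(observations, trees = NULL,
                                   methods = NULL) {
  stopifnot(all(c("tree_id", "method", "day", "value") %in% names(observations)))
  methods <- methods %||% intersect(names(.method_metric),
                                    unique(observations$method))
  unknown <- setdiff(unique(observations$method), names(.method_metric))
  if (length(unknown))
    warning("ignoring unknown method(s): ", paste(unknown, collapse = ", "))
  out <- list()
  for (m in methods) {
    sub <- observations[observations$method == m, , drop = FALSE]
    for (id in unique(sub$tree_id)) {
      s <- sub[sub$tree_id == id, , drop = FALSE]
      tr <- switch(
        m,
        bud_score = {
          if (is.null(trees)) stop("bud scores need a trees table with max_stage")
          ms <- trees$max_stage[match(id, trees$tree_id)]
          normalize_bud_scores(s$day, s$value, ms, tree_id = id,
                               observer_id = s$observer_id)
        },
        lai  = normalize_minmax(s$day, s$value, "half_leaf", tree_id = id),
        ndvi = normalize_minmax(s$day, s$value, "half_ndvi", tree_id = id),
        frass_mass_g = cumulative_proportion(s$day, s$value,
                                             "frass_half_fall", tree_id = id),
        count_total  = cumulative_proportion(s$day, s$value,
                                             "tc_half_fall", tree_id = id),
        count_fwm    = cumulative_proportion(s$day, s$value,
                                             "fwm_half_fall", tree_id = id))
      out[[paste(id, tr$metric, sep = ".")]] <- tr
    }
  }
  out
}
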