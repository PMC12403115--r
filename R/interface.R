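## Schema-validated I/O and the end-to-end pipeline.

.methods_known <- c("bud_score", "lai", "ndvi", "frass_mass_g",
                    "count_total", "count_fwm")

#' Read and validate a long-format observation CSV
#'
#' Expects columns `tree_id`, `method`, `day`, `value` (plus optional
#' `species`, `area`, `observer_id`). Each row is checked: known method
#' label, integer day of year in \[1, 366\] (1 = 1 January), nonnegative
#' value, integer counts, and bud scores within \[1, max_stage\] for the
#' tree's species when a `trees` table is supplied. Row-level problems are
#' collected and reported with line numbers; the run aborts unless
#' `skip_bad = TRUE`, in which case offending rows are dropped with a
#' warning.
#'
#' @param path CSV file path.
#' @param trees optional tree metadata (with `tree_id`, `max_stage`) for
#'   bud-score range checks.
#' @param skip_bad drop invalid rows instead of aborting.
#' @return validated data.frame of observation records.
#' @export
read_observations <- function(path, trees = NULL, skip_bad = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(obs) == 0)
    stop("empty input: ", path, " contains no observation rows", call. = FALSE)
  need <- c("tree_id", "method", "day", "value")
  if (!all(need %in% names(obs)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(obs)), collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(obs)) + 1L   # header is line 1
  errs <- character()
  bad <- rep(FALSE, nrow(obs))
  chk <- function(cond, msg) {
    w <- which(cond & !bad)
    if (length(w)) {
      errs <<- c(errs, sprintf("line %d: %s", line[w], msg))
      bad[w] <<- TRUE
    }
  }
  chk(!obs$method %in% .methods_known,
      sprintf("unknown method label (expected one of %s)",
              paste(.methods_known, collapse = ", ")))
  day_num <- suppressWarnings(as.numeric(obs$day))
  chk(!is.finite(day_num) | day_num != round(day_num) |
        day_num < 1 | day_num > 366,
      "day must be an integer day-of-year in [1, 366]")
  val <- suppressWarnings(as.numeric(obs$value))
  chk(!is.finite(val) | val < 0, "value must be a nonnegative number")
  counts <- obs$method %in% c("count_total", "count_fwm")
  chk(counts & is.finite(val) & val != round(val), "counts must be integers")
  if (!is.null(trees)) {
    ms <- trees$max_stage[match(obs$tree_id, trees$tree_id)]
    budr <- obs$method == "bud_score" & !is.na(ms)
    chk(budr & is.finite(val) & (val < 1 | val > ms),
        "bud score outside [1, max_stage] for this species")
  }
  if (length(errs)) {
    if (!skip_bad)
      stop("invalid observation rows:\n  ",
           paste(utils::head(errs, 20), collapse = "\n  "),
           if (length(errs) > 20) sprintf("\n  ... and %d more", length(errs) - 20),
           call. = FALSE)
    warning(sprintf("dropping %d invalid row(s)", sum(bad)))
    obs <- obs[!bad, , drop = FALSE]
  }
  obs$day <- as.integer(obs$day)
  obs$value <- as.numeric(obs$value)
  rownames(obs) <- NULL
  obs
}

#' Assemble the per-tree metrics table
#'
#' Runs the full metric-extraction stage: normalizes every tree x method
#' series, fits sigmoidal trajectories and extracts the six half-date
#' metrics (budburst, half-leaf, half-NDVI, frass / total-caterpillar /
#' final-instar-winter-moth half-falls), fits count-intensity curves to the
#' three trap streams (frass in centigrams) and extracts their peak days,
#' and returns one wide row per tree. Trees whose series are flagged
#' (zero season total, flat series, too few visits, no crossing) get NA for
#' that metric; the long per-estimate table with flags is attached as
#' attribute `"estimates"`.
#'
#' @param observations long-format observation records.
#' @param trees tree metadata (`tree_id`, `species`, `area`, `x`, `y`,
#'   `max_stage`).
#' @param herbivory optional herbivory table (`tree_id`, `canopy_level`,
#'   `herbivory_frac`) merged into the output.
#' @param fit_settings a [sigmoid_settings()].
#' @param peak_settings a [count_settings()].
#' @param verbose print progress.
#' @return data.frame: tree metadata columns plus `budburst`, `half_leaf`,
#'   `half_ndvi`, `frass_half_fall`, `tc_half_fall`, `fwm_half_fall`,
#'   `frass_peak`, `tc_peak`, `fwm_peak` (and herbivory columns if given).
#' @export
extract_metrics_table <- function(observations, trees, herbivory = NULL,
                                  fit_settings = sigmoid_settings(),
                                  peak_settings = count_settings(),
                                  verbose = FALSE) {
  trajs <- normalize_observations(observations, trees)
  half <- list()
  for (tr in trajs) {
    if (tr$flag != "ok") {
      half[[length(half) + 1L]] <- data.frame(
        tree_id = tr$tree_id, metric = tr$metric, half_day = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, ci_width = NA_real_,
        gradient_at_half = NA_real_, flag = "undefined", n_crossings = 0L,
        stringsAsFactors = FALSE)
      next
    }
    est <- tryCatch({
      curve <- fit_sigmoid(tr, fit_settings)
      extract_half_date(curve)
    }, error = function(e) data.frame(
      tree_id = tr$tree_id, metric = tr$metric, half_day = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, ci_width = NA_real_,
      gradient_at_half = NA_real_, flag = "fit_error", n_crossings = 0L,
      stringsAsFactors = FALSE))
    half[[length(half) + 1L]] <- est
    if (verbose) message(tr$tree_id, " ", tr$metric, ": ", est$flag)
  }
  half <- do.call(rbind, half)

  peak_map <- c(frass_mass_g = "frass_peak", count_total = "tc_peak",
                count_fwm = "fwm_peak")
  peaks <- list()
  for (m in intersect(names(peak_map), unique(observations$method))) {
    sub <- observations[observations$method == m, , drop = FALSE]
    for (id in unique(sub$tree_id)) {
      s <- sub[sub$tree_id == id, , drop = FALSE]
      cnt <- if (m == "frass_mass_g") frass_to_centigrams(s$value)
             else as.integer(s$value)
      est <- tryCatch({
        curve <- fit_count_curve(s$day, cnt, peak_settings,
                                 tree_id = id, metric = peak_map[[m]])
        extract_peak(curve)
      }, error = function(e) data.frame(
        tree_id = id, metric = peak_map[[m]], peak_day = NA_real_,
        peak_height = NA_real_, height_ci_low = NA_real_,
        height_ci_high = NA_real_, flag = "undefined",
        stringsAsFactors = FALSE))
      peaks[[length(peaks) + 1L]] <- est
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else NULL

  wide <- trees[, intersect(c("tree_id", "species", "area", "x", "y",
                              "max_stage"), names(trees)), drop = FALSE]
  for (m in unique(half$metric)) {
    v <- half[half$metric == m & half$flag == "ok", c("tree_id", "half_day")]
    wide[[m]] <- v$half_day[match(wide$tree_id, v$tree_id)]
  }
  if (!is.null(peaks)) for (m in unique(peaks$metric)) {
    v <- peaks[peaks$metric == m & peaks$flag %in% c("ok", "boundary"),
               c("tree_id", "peak_day")]
    wide[[m]] <- v$peak_day[match(wide$tree_id, v$tree_id)]
  }
  if (!is.null(herbivory))
    wide <- merge(wide, herbivory, by = "tree_id", all.x = TRUE, sort = FALSE)
  attr(wide, "estimates") <- list(half_dates = half, peaks = peaks)
  wide
}

#' Configure a pipeline run
#'
#' @param input_dir directory with `observations.csv`, `trees.csv` and
#'   optionally `herbivory.csv` (as written by [write_woodland()]); `NULL`
#'   to simulate instead.
#' @param woodland a [woodland_config()] used when simulating.
#' @param output_dir where stage outputs are written.
#' @param fit_settings,peak_settings trajectory and count fit settings.
#' @param seed top-level seed; each stage derives its own stream from it.
#' @param verbose print stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, woodland = woodland_config(),
                            output_dir = tempfile("phenowood_run_"),
                            fit_settings = sigmoid_settings(),
                            peak_settings = count_settings(),
                            seed = 1L, verbose = FALSE) {
  structure(list(input_dir = input_dir, woodland = woodland,
                 output_dir = output_dir, fit_settings = fit_settings,
                 peak_settings = peak_settings, seed = seed,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the phenology pipeline end to end
#'
#' Orchestrates the stages in order: `simulate` (or load the input CSVs),
#' `fit` (metric extraction: normalization, sigmoid half-dates and count
#' peaks), `compare` (Spearman matrix over the nine metrics; cross-trophic
#' and herbivory models when enough oak rows are present) and `report`
#' (plain-text summary). Every output file is recorded in a manifest with
#' its MD5 content hash, so two runs with the same seed are verifiably
#' identical. A stage that depends on a missing earlier output fails
#' naming the missing file.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("simulate", "fit", "compare", "report")` or
#'   `"all"`.
#' @return invisibly, the manifest data.frame (`file`, `md5`, `bytes`).
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "fit", "compare", "report")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (config$verbose) message(...)

  if ("simulate" %in% stages) {
    note("stage simulate")
    if (is.null(config$input_dir)) {
      cfg <- config$woodland
      cfg$seed <- (config$seed * 1000L + cfg$seed) %% .Machine$integer.max
      w <- generate_woodland(cfg)
      write_woodland(w, out)
    } else {
      for (f in c("observations.csv", "trees.csv")) {
        src <- file.path(config$input_dir, f)
        if (!file.exists(src))
          stop("input file missing: ", src, call. = FALSE)
        file.copy(src, file.path(out, f), overwrite = TRUE)
      }
      hsrc <- file.path(config$input_dir, "herbivory.csv")
      if (file.exists(hsrc)) file.copy(hsrc, file.path(out, "herbivory.csv"),
                                       overwrite = TRUE)
    }
  }

  if ("fit" %in% stages) {
    note("stage fit")
    for (f in c("observations.csv", "trees.csv")) {
      if (!file.exists(file.path(out, f)))
        stop("fit stage requires ", file.path(out, f),
             "; run the simulate stage first", call. = FALSE)
    }
    trees <- utils::read.csv(file.path(out, "trees.csv"),
                             stringsAsFactors = FALSE)
    obs <- read_observations(file.path(out, "observations.csv"), trees = trees)
    herb <- NULL
    if (file.exists(file.path(out, "herbivory.csv")))
      herb <- utils::read.csv(file.path(out, "herbivory.csv"),
                              stringsAsFactors = FALSE)
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(config$seed * 1000L + 2L)
    metrics <- extract_metrics_table(obs, trees, herb,
                                     config$fit_settings,
                                     config$peak_settings,
                                     verbose = config$verbose)
    est <- attr(metrics, "estimates")
    utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
    utils::write.csv(est$half_dates, file.path(out, "half_dates.csv"),
                     row.names = FALSE)
    if (!is.null(est$peaks))
      utils::write.csv(est$peaks, file.path(out, "peaks.csv"),
                       row.names = FALSE)
  }

  if ("compare" %in% stages) {
    note("stage compare")
    mpath <- file.path(out, "metrics.csv")
    if (!file.exists(mpath))
      stop("compare stage requires ", mpath, "; run the fit stage first",
           call. = FALSE)
    metrics <- utils::read.csv(mpath, stringsAsFactors = FALSE)
    mcols <- intersect(c("budburst", "half_leaf", "half_ndvi",
                         "frass_half_fall", "tc_half_fall", "fwm_half_fall",
                         "frass_peak", "tc_peak", "fwm_peak"),
                       names(metrics))
    cm <- spearman_matrix(metrics, mcols)
    utils::write.csv(cm, file.path(out, "correlations.csv"),
                     row.names = FALSE)
    oaks <- metrics[metrics$species == "oak", , drop = FALSE]
    models <- list()
    if (nrow(oaks) >= 10 && all(c("budburst", "tc_half_fall") %in% mcols)) {
      for (pred in intersect(c("budburst", "half_leaf", "half_ndvi"), mcols)) {
        m <- tryCatch(fit_cross_trophic_model(oaks, "tc_half_fall", pred,
                                              seed = config$seed),
                      error = function(e) NULL)
        if (!is.null(m)) models[[paste0("tc_half_fall~", pred)]] <- m
      }
    }
    if ("herbivory_frac" %in% names(metrics) &&
        sum(stats::complete.cases(oaks[c("herbivory_frac", "half_leaf")])) >= 10) {
      mh <- tryCatch(fit_herbivory_model(oaks, "half_leaf",
                                         seed = config$seed),
                     error = function(e) NULL)
      if (!is.null(mh)) models[["herbivory~half_leaf"]] <- mh
    }
    if (length(models)) {
      summ <- do.call(rbind, lapply(names(models), function(nm) {
        m <- models[[nm]]
        cf <- m$coefficients
        cf$model <- nm; cf$r2 <- m$variance_explained; cf$elpd <- m$elpd
        cf$moran_i <- if (!is.null(m$moran)) m$moran$I else NA_real_
        cf
      }))
      utils::write.csv(summ, file.path(out, "models.csv"), row.names = FALSE)
    }
  }

  if ("report" %in% stages) {
    note("stage report")
    rpt <- c(sprintf("phenowood pipeline report (seed %d)", config$seed), "")
    mpath <- file.path(out, "metrics.csv")
    if (file.exists(mpath)) {
      metrics <- utils::read.csv(mpath, stringsAsFactors = FALSE)
      rpt <- c(rpt, sprintf("%d trees, %d species", nrow(metrics),
                            length(unique(metrics$species))), "")
      if ("budburst" %in% names(metrics)) {
        mm <- stats::aggregate(metrics$budburst,
                               list(species = metrics$species),
                               mean, na.rm = TRUE)
        rpt <- c(rpt, "mean budburst by species:",
                 sprintf("  %-10s %7.2f", mm$species, mm$x), "")
      }
    }
    writeLines(rpt, file.path(out, "report.txt"))
  }

  files <- sort(list.files(out, full.names = TRUE))
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out, "MANIFEST.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
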