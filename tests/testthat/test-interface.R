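make_obs_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

test_that("valid observation files load and invalid rows are named", {
  dir <- withr::local_tempdir()
  good <- data.frame(tree_id = "T1", species = "oak", area = "Great Wood",
                     method = c("bud_score", "lai", "count_total"),
                     day = c(110L, 110L, 140L), value = c(3, 1.2, 7),
                     observer_id = c("o1", NA, NA))
  obs <- read_observations(make_obs_csv(good, file.path(dir, "ok.csv")))
  expect_equal(nrow(obs), 3)

  trees <- data.frame(tree_id = "T1", species = "birch", max_stage = 5L)
  bad <- good
  bad$value[1] <- 9   # bud score 9 on a 5-stage (non-oak) key
  p <- make_obs_csv(bad, file.path(dir, "bad.csv"))
  expect_error(read_observations(p, trees = trees), "line 2.*bud score")
  expect_warning(ok <- read_observations(p, trees = trees, skip_bad = TRUE),
                 "dropping 1")
  expect_equal(nrow(ok), 2)

  bad2 <- good; bad2$method[2] <- "drone_flight"
  expect_error(read_observations(make_obs_csv(bad2, file.path(dir, "m.csv"))),
               "unknown method")
  bad3 <- good; bad3$day[3] <- 400L
  expect_error(read_observations(make_obs_csv(bad3, file.path(dir, "d.csv"))),
               "day-of-year")
  bad4 <- good; bad4$value[3] <- 2.5
  expect_error(read_observations(make_obs_csv(bad4, file.path(dir, "c.csv"))),
               "integers")
})

test_that("an empty observation file is an explicit error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.csv")
  writeLines("tree_id,method,day,value", p)
  expect_error(read_observations(p), "empty input")
  expect_error(read_observations(file.path(dir, "nothere.csv")), "no such file")
})

test_that("csv artifacts round-trip to full precision", {
  w <- generate_woodland(tiny_config(seed = 51L))
  dir <- withr::local_tempdir()
  write_woodland(w, dir)
  obs <- utils::read.csv(file.path(dir, "observations.csv"))
  expect_equal(obs$value, w$observations$value, tolerance = 1e-12)
  tru <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(tru$half_date, w$truth$half_date, tolerance = 1e-12)
})

test_that("the pipeline is deterministic given a seed", {
  cfg <- function(dir) pipeline_config(
    woodland = tiny_config(n_oak = 5L, n_birch = 3L),
    output_dir = dir, seed = 9L,
    fit_settings = sigmoid_settings(B = 50),
    peak_settings = count_settings(B = 50))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- run_pipeline(cfg(d1), stages = c("simulate", "fit", "report"))
  m2 <- run_pipeline(cfg(d2), stages = c("simulate", "fit", "report"))
  expect_identical(m1$file, m2$file)
  expect_identical(m1$md5, m2$md5)
  expect_true(all(c("observations.csv", "metrics.csv", "half_dates.csv",
                    "report.txt") %in% m1$file))
})

test_that("stages fail loudly when their inputs are missing", {
  d <- withr::local_tempdir()
  cfg <- pipeline_config(output_dir = d, seed = 1L)
  expect_error(run_pipeline(cfg, stages = "compare"), "metrics.csv")
  expect_error(run_pipeline(cfg, stages = "fit"), "observations.csv")
})

test_that("trees without caterpillars yield flagged rows, not failures", {
  w <- generate_woodland(tiny_config(n_oak = 5L, seed = 61L))
  # silence one tree's traps entirely
  mute <- w$trees$tree_id[1]
  sel <- w$observations$tree_id == mute &
    w$observations$method %in% c("count_total", "count_fwm", "frass_mass_g")
  w$observations$value[sel] <- 0
  mt <- extract_metrics_table(w$observations, w$trees,
                              fit_settings = sigmoid_settings(B = 50),
                              peak_settings = count_settings(B = 50))
  expect_true(is.na(mt$tc_half_fall[mt$tree_id == mute]))
  est <- attr(mt, "estimates")$half_dates
  expect_identical(
    est$flag[est$tree_id == mute & est$metric == "tc_half_fall"], "undefined")
  # other trees unaffected
  expect_true(any(is.finite(mt$tc_half_fall)))
})
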