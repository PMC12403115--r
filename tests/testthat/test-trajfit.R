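test_that("a noiseless logistic trajectory is recovered almost exactly", {
  tr <- logistic_traj(t0 = 120, k = 0.3)
  cur <- fit_sigmoid(tr, fast_fit)
  expect_true(cur$converged)
  truth <- plogis(0.3 * (cur$grid - 120))
  expect_lt(max(abs(cur$central - truth)), 0.01)
  est <- extract_half_date(cur)
  expect_identical(est$flag, "ok")
  expect_equal(est$half_day, 120, tolerance = 0.05)
  # slope of a logistic at its midpoint is k/4
  expect_equal(est$gradient_at_half, 0.3 / 4, tolerance = 1e-3)
  expect_true(est$ci_low <= est$half_day & est$half_day <= est$ci_high)
})

test_that("exact boundary values are handled by the squeeze without NaNs", {
  days <- seq(100, 140, by = 2)
  y <- round(plogis(0.4 * (days - 118)), 2)  # contains exact 0s and 1s
  tr <- phenowood:::new_trajectory("T1", "budburst", days, y, "state")
  cur <- fit_sigmoid(tr, fast_fit)
  expect_true(all(is.finite(cur$central)))
  expect_true(all(is.finite(cur$ensemble)))
  expect_true(all(cur$central > 0 & cur$central < 1))
  est <- extract_half_date(cur)
  expect_identical(est$flag, "ok")
  expect_equal(est$half_day, 118, tolerance = 1)
})

test_that("curves that never reach one half are flagged, not numbered", {
  days <- seq(100, 140)
  tr <- phenowood:::new_trajectory("T1", "half_leaf", days,
                                   0.4 * plogis(0.3 * (days - 120)), "state")
  est <- extract_half_date(fit_sigmoid(tr, fast_fit))
  expect_identical(est$flag, "no_crossing")
  expect_true(is.na(est$half_day))
})

test_that("half-date is translation equivariant", {
  delta <- 7
  tr <- logistic_traj(t0 = 120, k = 0.25, days = seq(102, 138, by = 3))
  tr2 <- phenowood:::new_trajectory("T1", tr$metric, tr$days + delta, tr$y,
                                    "state")
  e1 <- extract_half_date(fit_sigmoid(tr, fast_fit))
  e2 <- extract_half_date(fit_sigmoid(tr2, fast_fit))
  expect_equal(e2$half_day - e1$half_day, delta, tolerance = 0.01)
})

test_that("fitting refuses short or flagged series", {
  tr <- logistic_traj(days = c(110, 115, 120, 125))
  expect_error(fit_sigmoid(tr), ">= 5 distinct")
  flat <- normalize_minmax(1:5, rep(2, 5))
  expect_error(fit_sigmoid(flat), "flagged")
})

test_that("observer random intercepts are accepted for bud streams", {
  set.seed(42)
  days <- seq(100, 141, by = 1.5)   # observers alternate between rounds
  obs <- rep_len(c("a", "b"), length(days))
  shift <- ifelse(obs == "a", -1, 1)
  score <- pmin(pmax(ceiling(plogis(0.3 * (days - 118 - shift)) * 7), 1), 7)
  tr <- normalize_bud_scores(days, score, 7, observer_id = obs)
  est <- extract_half_date(fit_sigmoid(tr, fast_fit))
  expect_identical(est$flag, "ok")
  expect_equal(est$half_day, 118, tolerance = 2)
})

test_that("noisy simulated trajectories are recovered with small error", {
  # logit-scale noise, visits every 3 days
  set.seed(7)
  errs <- replicate(15, {
    t0 <- runif(1, 112, 124)
    days <- seq(100, 140, by = 3)
    y <- plogis(qlogis(pmin(pmax(plogis(0.3 * (days - t0)), 1e-5), 1 - 1e-5)) +
                  rnorm(length(days), 0, 0.5))
    tr <- phenowood:::new_trajectory("T", "half_ndvi", days, y, "state")
    est <- extract_half_date(fit_sigmoid(tr, fast_fit))
    if (est$flag == "ok") est$half_day - t0 else NA_real_
  })
  expect_lt(median(abs(errs), na.rm = TRUE), 1.5)
})

test_that("interval widths summarize correctly by group", {
  est <- data.frame(
    tree_id = c("a", "b", "c"), metric = c("m1", "m2", "m2"),
    half_day = c(120, 121, 122), ci_low = c(118, 120, 119),
    ci_high = c(122, 122, 125), ci_width = c(4, 2, 6),
    gradient_at_half = 0.1, flag = "ok", n_crossings = 1L)
  s <- summarize_ci_widths(est, by = "metric")
  m1 <- s[s$metric == "m1", ]
  expect_equal(m1$mean_width, 4)
  expect_true(is.na(m1$sd_width))
  m2 <- s[s$metric == "m2", ]
  expect_equal(m2$mean_width, 4)
  expect_equal(m2$sd_width, 2 * sqrt(2))
  # groups with no usable estimates are absent, not zero
  est$flag <- c("ok", "no_crossing", "no_crossing")
  s2 <- summarize_ci_widths(est, by = "metric")
  expect_false("m2" %in% s2$metric)
})

test_that("noisier cohorts earn wider uncertainty intervals", {
  width_for <- function(sd_noise, seed) {
    set.seed(seed)
    days <- seq(100, 140, by = 3)
    mean(replicate(8, {
      y <- plogis(qlogis(plogis(0.3 * (days - 119))) +
                    rnorm(length(days), 0, sd_noise))
      tr <- phenowood:::new_trajectory("T", "m", days, y, "state")
      est <- extract_half_date(fit_sigmoid(tr, sigmoid_settings(B = 100)))
      if (est$flag == "ok") est$ci_width else NA_real_
    }), na.rm = TRUE)
  }
  expect_gt(width_for(0.8, 3), width_for(0.15, 3))
})
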