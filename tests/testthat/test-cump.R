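test_that("the CUMP curve matches hand-enumerated running counts", {
  cv <- cump_curve(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1))
  expect_equal(cv$time, c(1, 2, 3, 4, 5))
  expect_equal(cv$cump, c(0, 0, 1 / 3, 1 / 2, 3 / 5))
  expect_equal(cv$cum_total, 1:5)

  # ties are absorbed together at their grid time
  cv2 <- cump_curve(c(2, 2, 5), c(1, 0, 1))
  expect_equal(cv2$time, c(2, 5))
  expect_equal(cv2$cump, c(1 / 2, 2 / 3))

  # all-correct item: cump identically one
  cv3 <- cump_curve(c(3, 1, 2), c(1, 1, 1))
  expect_equal(cv3$cump, rep(1, 3))

  expect_error(cump_curve(c(NA, 1), c(0, NA), item_id = "q"),
               "q", class = "rtcump_empty_item_error")
})

test_that("the threshold rule picks the largest time still at or below g", {
  cv <- cump_curve(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1))
  thr <- cump_threshold(cv, g = 0.25)
  expect_equal(thr$cump_threshold, 2)
  expect_identical(thr$cump_status, "ok")

  # the inequality is <=, not <: cump(4) = 0.5 qualifies at g = 0.5
  thr2 <- cump_threshold(cv, g = 0.5)
  expect_equal(thr2$cump_threshold, 4)

  expect_error(cump_threshold(cv, g = 0), class = "rtcump_config_error")
  expect_error(cump_threshold(cv, g = 1.2), class = "rtcump_config_error")
})

test_that("degenerate items get explicit statuses and clipping is recorded", {
  all_correct <- cump_curve(c(1, 2, 3), c(1, 1, 1))
  thr <- cump_threshold(all_correct, g = 0.25, lower_limit = 0)
  expect_identical(thr$cump_status, "no_crossing")
  expect_equal(thr$cump_threshold, 0)

  all_wrong <- cump_curve(c(1, 2, 7), c(0, 0, 0))
  thr2 <- cump_threshold(all_wrong, g = 0.25)
  expect_identical(thr2$cump_status, "all_below")
  expect_equal(thr2$cump_threshold, 7)

  # clipping overrides the raw value and the status says so
  thr3 <- cump_threshold(all_wrong, g = 0.25, upper_limit = 5)
  expect_identical(thr3$cump_status, "clipped_high")
  expect_equal(thr3$cump_threshold, 5)
  cv <- cump_curve(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1))
  thr4 <- cump_threshold(cv, g = 0.25, lower_limit = 3)
  expect_identical(thr4$cump_status, "clipped_low")
  expect_equal(thr4$cump_threshold, 3)

  # single-response item
  single <- cump_curve(4, 1)
  expect_identical(cump_threshold(single, 0.25)$cump_status, "no_crossing")
})

test_that("descriptive thresholds are the mean and mean-plus-SD", {
  expect_equal(descriptive_thresholds(c(10, 10, 10)),
               tibble::tibble(mean_rt = 10, sd_rt = 0, mean_plus_1sd = 10))
  d <- descriptive_thresholds(c(2, 4), sd_ddof = 1)
  expect_equal(d$mean_rt, 3)
  expect_equal(d$sd_rt, sqrt(2))
  expect_equal(d$mean_plus_1sd, 3 + sqrt(2))
  d0 <- descriptive_thresholds(c(2, 4), sd_ddof = 0)
  expect_equal(d0$sd_rt, 1)
  expect_equal(descriptive_thresholds(7)$sd_rt, 0)
  expect_error(descriptive_thresholds(c(NA_real_, NA_real_)),
               class = "rtcump_empty_item_error")
})

test_that("fast threshold computation agrees exactly with the recount oracle", {
  withr::with_seed(401, {
    for (rep in 1:60) {
      inst <- random_item_instance()
      g <- sample(c(0.2, 0.25, 0.5), 1)
      lims <- if (rep %% 3 == 0) c(1, 20) else c(0, Inf)
      cv <- cump_curve(inst$rt, inst$score)
      got <- cump_threshold(cv, g, lims[1], lims[2])
      want <- oracle_cump_threshold(inst$rt, inst$score, g, lims[1], lims[2])
      expect_identical(got$cump_status, want$status)
      expect_identical(got$cump_threshold, want$threshold)
      expect_equal(cv$time, want$times)
      expect_equal(cv$cump, want$cump)
    }
  })
})

test_that("cump values are invariant and thresholds equivariant under affine time maps", {
  withr::with_seed(402, {
    for (rep in 1:40) {
      inst <- random_item_instance()
      a <- stats::runif(1, 0.1, 5)
      b <- stats::runif(1, 0, 10)
      cv <- cump_curve(inst$rt, inst$score)
      cv2 <- cump_curve(a * inst$rt + b, inst$score)
      expect_equal(cv2$cump, cv$cump)
      t1 <- cump_threshold(cv, 0.25)
      t2 <- cump_threshold(cv2, 0.25)
      if (t1$cump_status %in% c("ok", "all_below")) {
        expect_equal(t2$cump_threshold, a * t1$cump_threshold + b)
        expect_identical(t2$cump_status, t1$cump_status)
      }
    }
  })
})

test_that("curve conservation, duplication invariance and g-monotonicity hold", {
  withr::with_seed(403, {
    for (rep in 1:25) {
      inst <- random_item_instance()
      keep <- !is.na(inst$rt) & !is.na(inst$score)
      cv <- cump_curve(inst$rt, inst$score)
      # final cump equals the overall proportion correct among used pairs
      expect_equal(cv$cump[nrow(cv)], mean(inst$score[keep]))
      # duplicating every pair changes nothing
      cv2 <- cump_curve(rep(inst$rt, 2), rep(inst$score, 2))
      expect_equal(cv2$cump, cv$cump)
      expect_equal(cv2$time, cv$time)
      # lowering g weakly lowers the unclipped threshold
      t_lo <- cump_threshold(cv, 0.15)$cump_threshold
      t_hi <- cump_threshold(cv, 0.35)$cump_threshold
      expect_lte(t_lo, t_hi)
    }
  })
})

test_that("cump_analysis reports per-item rows, warns on chance-level items and ignores row order", {
  sim <- simulate_sample(sim_design(n_persons = 80), seed = 5)
  fit <- suppressWarnings(cump_analysis(sim$rt, sim$score))
  expect_equal(nrow(fit$thresholds), 9)
  expect_identical(fit$thresholds$item_id, default_item_bank()$item_id)
  expect_equal(fit$thresholds$mean_plus_1sd,
               fit$thresholds$mean_rt + fit$thresholds$sd_rt)

  # permuting persons leaves thresholds identical
  perm <- sample(nrow(sim$rt))
  fit2 <- suppressWarnings(
    cump_analysis(sim$rt[perm, ], sim$score[perm, ]))
  expect_equal(fit2$thresholds, fit$thresholds)

  # an item at or below chance difficulty triggers a warning
  rt <- tibble::tibble(person_id = as.character(1:20),
                       q1 = seq(1, 20))
  score <- tibble::tibble(person_id = as.character(1:20),
                          q1 = rep(0, 20))
  expect_warning(cump_analysis(rt, score), "chance level")

  # all-missing item excluded with a warning, not silently dropped
  rt$q2 <- NA_real_
  score$q2 <- rep(1, 20)
  fit3 <- suppressWarnings(cump_analysis(rt, score))
  expect_identical(fit3$skipped_items, "q2")
  expect_true(any(grepl("excluded",
                        capture_warnings(cump_analysis(rt, score)))))
  # every item empty is fatal
  rt_all_na <- tibble::tibble(person_id = c("1", "2"), q1 = c(NA_real_, NA))
  sc <- tibble::tibble(person_id = c("1", "2"), q1 = c(1, 0))
  expect_error(cump_analysis(rt_all_na, sc),
               class = "rtcump_empty_item_error")
})

test_that("tidy, glance and autoplot expose the analysis", {
  sim <- simulate_sample(sim_design(n_persons = 50), seed = 9)
  fit <- suppressWarnings(cump_analysis(sim$rt, sim$score))
  expect_identical(tidy(fit), fit$thresholds)
  g <- glance(fit)
  expect_equal(g$n_items, 9)
  expect_equal(g$n_ok + g$n_no_crossing + g$n_all_below +
                 sum(fit$thresholds$cump_status %in%
                       c("clipped_low", "clipped_high")), 9)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
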