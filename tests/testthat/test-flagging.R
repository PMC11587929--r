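test_that("item deviations follow the k-SD band with strict edges", {
  expect_identical(item_deviation(2, 10, 2, k = 1.3), "fast")
  expect_identical(item_deviation(12.5, 10, 2, k = 1.3), "none")  # 12.5 <= 12.6
  expect_identical(item_deviation(12.7, 10, 2, k = 1.3), "slow")
  expect_identical(item_deviation(10, 10, 2, k = 1.3), "none")
  expect_identical(item_deviation(10, 10, 0, k = 5), "none")
  # degenerate band: any departure from the center is aberrant
  expect_identical(item_deviation(10.001, 10, 0, k = 1.3), "slow")
  expect_identical(item_deviation(9.999, 10, 0, k = 1.3), "fast")
  # band edges themselves are not aberrant
  expect_identical(item_deviation(10 - 2.6, 10, 2, k = 1.3), "none")
  expect_true(is.na(item_deviation(NA, 10, 2)))
  expect_error(item_deviation(1, 10, 2, k = 0), class = "rtcump_config_error")
  expect_error(item_deviation(1, 10, -1), class = "rtcump_validation_error")
})

test_that("a person is flagged when at least proportion p of usable items deviate", {
  rep1 <- flag_person(c(2, 2, 2, 2, 2, 12, 11, 10, 9),
                      centers = rep(10, 9), sds = rep(2, 9),
                      k = 1.3, p = 0.5)
  expect_equal(rep1$n_aberrant, 5L)
  expect_equal(rep1$n_fast, 5L)
  expect_equal(rep1$n_slow, 0L)
  expect_equal(rep1$prop_aberrant, 5 / 9)
  expect_equal(rep1$flag, 1L)

  # 4 of 9 deviations stay under the 50% bar
  rep2 <- flag_person(c(2, 2, 2, 2, 10, 10, 10, 10, 10),
                      centers = rep(10, 9), sds = rep(2, 9))
  expect_equal(rep2$n_aberrant, 4L)
  expect_equal(rep2$flag, 0L)

  # on-threshold RTs never deviate
  rep3 <- flag_person(rep(10, 9), centers = rep(10, 9), sds = rep(2, 9))
  expect_equal(rep3$n_aberrant, 0L)
  expect_equal(rep3$flag, 0L)

  # missing items drop out of the denominator
  rep4 <- flag_person(c(2, 2, NA, NA, NA, NA, NA, NA, 9),
                      centers = rep(10, 9), sds = rep(2, 9))
  expect_equal(rep4$n_items_used, 3L)
  expect_equal(rep4$prop_aberrant, 2 / 3)
  expect_equal(rep4$flag, 1L)

  # zero usable items: unflagged, marked all-missing
  rep5 <- flag_person(rep(NA_real_, 4), centers = rep(10, 4),
                      sds = rep(2, 4))
  expect_equal(rep5$n_items_used, 0L)
  expect_true(is.na(rep5$prop_aberrant))
  expect_equal(rep5$flag, 0L)

  # fast-only mode ignores slow deviations
  rep6 <- flag_person(c(2, 2, 2, 2, 2, 99, 99, 99, 99),
                      centers = rep(10, 9), sds = rep(2, 9), sided = "fast")
  expect_equal(rep6$n_aberrant, 5L)
  expect_equal(rep6$n_slow, 4L)
  expect_equal(rep6$flag, 1L)
})

test_that("widening the band or raising p never increases flags", {
  withr::with_seed(404, {
    for (rep in 1:15) {
      n_items <- 9
      rts <- stats::rlnorm(n_items, 2, 1)
      centers <- stats::rlnorm(n_items, 2, 0.5)
      sds <- stats::runif(n_items, 0.1, 5)
      ks <- c(0.5, 1.3, 2, 5)
      n_ab <- vapply(ks, function(k) {
        flag_person(rts, centers, sds, k = k)$n_aberrant
      }, integer(1))
      expect_true(all(diff(n_ab) <= 0))
      ps <- c(0.2, 0.5, 0.8, 1)
      flags <- vapply(ps, function(p) {
        flag_person(rts, centers, sds, p = p)$flag
      }, integer(1))
      expect_true(all(diff(flags) <= 0))
    }
  })
})

test_that("flag_sample is permutation-equivariant and column-order invariant", {
  sim <- simulate_sample(separated_design(n_persons = 120), seed = 21)
  fit <- suppressWarnings(cump_analysis(sim$rt, sim$score))
  flags <- flag_sample(sim$rt, fit, quiet = TRUE)
  expect_identical(flags$person_id, sim$rt$person_id)

  perm <- sample(nrow(sim$rt))
  flags_perm <- flag_sample(sim$rt[perm, ], fit, quiet = TRUE)
  expect_equal(flags_perm, flags[perm, ], ignore_attr = TRUE)

  cols <- c("person_id", sample(setdiff(names(sim$rt), "person_id")))
  flags_cols <- flag_sample(sim$rt[cols], fit, quiet = TRUE)
  expect_equal(flags_cols$n_aberrant, flags$n_aberrant)
  expect_equal(flags_cols$flag, flags$flag)
})

test_that("planted whole-test rapid guessers are always caught, calm samples never", {
  # engaged times tightly around 30 s; one person guesses at ~0.5 s on all
  # items, far more than 3 engaged SDs below the mean
  withr::with_seed(405, {
    n <- 40
    n_items <- 9
    rt_mat <- matrix(stats::rlnorm(n * n_items, log(30), 0.2),
                     nrow = n)
    rt_mat[7, ] <- 0.5
    rt <- tibble::as_tibble(as.data.frame(rt_mat))
    names(rt) <- paste0("q", seq_len(n_items))
    rt <- dplyr::bind_cols(tibble::tibble(person_id = as.character(1:n)), rt)
    score <- rt
    score[-1] <- lapply(score[-1], function(x) as.numeric(x > 25))

    fit <- suppressWarnings(cump_analysis(rt, score))
    flags <- flag_sample(rt, fit, rt_config(sided = "fast"), quiet = TRUE)
    expect_equal(flags$flag[7], 1L)

    # an absurdly wide band flags nobody
    none <- flag_sample(rt, fit, rt_config(flag_sd_multiplier = 99),
                        quiet = TRUE)
    expect_equal(sum(none$flag), 0L)
  })
})

test_that("the cump-centered band reading stays available as an override", {
  sim <- simulate_sample(separated_design(n_persons = 100), seed = 31)
  fit <- suppressWarnings(cump_analysis(sim$rt, sim$score))
  f_mean <- flag_sample(sim$rt, fit, rt_config(center = "mean"),
                        quiet = TRUE)
  f_cump <- flag_sample(sim$rt, fit, rt_config(center = "cump"),
                        quiet = TRUE)
  expect_identical(names(f_cump), names(f_mean))
  expect_true(all(f_cump$n_aberrant == f_cump$n_fast + f_cump$n_slow))
  # the two readings center the band differently, so deviation counts differ
  expect_false(identical(f_cump$n_aberrant, f_mean$n_aberrant))
})
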