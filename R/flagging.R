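#' Classify one response time against an item's flag band
#'
#' A response is aberrantly *fast* when it falls strictly below
#' `threshold - k * sd`, aberrantly *slow* strictly above
#' `threshold + k * sd`, and unremarkable otherwise. Comparisons are strict,
#' so values exactly on a band edge are not aberrant; with `sd = 0` the band
#' is degenerate and any response different from the threshold is aberrant.
#' Vectorised over all arguments.
#'
#' @param rt Response time(s), seconds; `NA` gives `NA`.
#' @param threshold Band center(s), seconds.
#' @param sd Item RT standard deviation(s), >= 0.
#' @param k Band width in SD units, > 0.
#' @return Character vector in `{"none", "fast", "slow"}` (or `NA`).
#' @examples
#' item_deviation(2, threshold = 10, sd = 2, k = 1.3)   # "fast"
#' item_deviation(12.5, threshold = 10, sd = 2, k = 1.3) # "none"
#' @export
item_deviation <- function(rt, threshold, sd, k = 1.3) {
  if (any(k <= 0)) {
    abort("`k` must be positive.", class = "rtcump_config_error")
  }
  if (any(!is.na(sd) & sd < 0)) {
    abort("`sd` must be non-negative.", class = "rtcump_validation_error")
  }
  dplyr::case_when(
    is.na(rt) | is.na(threshold) | is.na(sd) ~ NA_character_,
    rt < threshold - k * sd ~ "fast",
    rt > threshold + k * sd ~ "slow",
    .default = "none"
  )
}

#' Flag one person's response-time pattern
#'
#' Counts, across the items the person actually answered (present RT, usable
#' band), how many response times fall outside the item flag band, and flags
#' the person when the aberrant proportion reaches `p`. The denominator is
#' the number of usable items, not the test length, so missing cells do not
#' dilute the criterion.
#'
#' @param rts Numeric RT vector over items, `NA` allowed.
#' @param centers Band centers per item (threshold or mean RT), seconds.
#' @param sds Item RT standard deviations.
#' @param k Band width in SD units (default 1.3).
#' @param p Minimum aberrant item proportion to flag (default 0.5).
#' @param sided `"two"` or `"fast"` (count only fast deviations).
#' @param person_id Identifier carried into the result.
#' @return One-row tibble: `person_id, n_items_used, n_aberrant,
#'   prop_aberrant, n_fast, n_slow, flag`. A person with zero usable items
#'   gets `flag = 0` and `prop_aberrant = NA`.
#' @examples
#' flag_person(c(2, 2, 2, 2, 2, 12, 11, 10, 9),
#'             centers = rep(10, 9), sds = rep(2, 9))
#' @export
flag_person <- function(rts, centers, sds, k = 1.3, p = 0.5,
                        sided = c("two", "fast"), person_id = "1") {
  sided <- match.arg(sided)
  if (p <= 0 || p > 1) {
    abort("`p` must be in (0, 1].", class = "rtcump_config_error")
  }
  dev <- item_deviation(rts, centers, sds, k = k)
  usable <- !is.na(dev)
  n_used <- sum(usable)
  n_fast <- sum(dev[usable] == "fast")
  n_slow <- sum(dev[usable] == "slow")
  n_ab <- if (sided == "fast") n_fast else n_fast + n_slow
  prop <- if (n_used > 0) n_ab / n_used else NA_real_
  tibble(
    person_id = as.character(person_id),
    n_items_used = as.integer(n_used),
    n_aberrant = as.integer(n_ab),
    prop_aberrant = prop,
    n_fast = as.integer(n_fast),
    n_slow = as.integer(n_slow),
    flag = as.integer(n_used >= 1 && !is.na(prop) && prop >= p)
  )
}

#' Flag every respondent in a sample
#'
#' Applies the per-person flag rule over all rows of a response-time matrix,
#' using item thresholds from [cump_analysis()]. The band for item `j` is
#' `center_j +/- k * sd_j`, where `center_j` is the item's mean RT
#' (`config$center = "mean"`, default) or its CUMP threshold
#' (`config$center = "cump"`), and `sd_j` is the item's observed RT standard
#' deviation.
#'
#' @param rt Response-time matrix (tibble: `person_id` + item columns).
#' @param thresholds A `cump_analysis` object or its threshold tibble.
#' @param config An [rt_config()]; `flag_sd_multiplier`,
#'   `flag_item_proportion`, `center` and `sided` are used.
#' @param quiet Suppress the summary message.
#' @return A tibble with one [flag_person()] row per respondent, input order
#'   preserved.
#' @examples
#' sim <- simulate_sample(sim_design(n_persons = 60), seed = 1)
#' fit <- cump_analysis(sim$rt, sim$score)
#' flags <- flag_sample(sim$rt, fit)
#' table(flags$flag)
#' @export
flag_sample <- function(rt, thresholds, config = rt_config(), quiet = FALSE) {
  stopifnot(inherits(config, "rt_config"))
  rt <- as_rt_matrix(rt)
  thr <- if (inherits(thresholds, "cump_analysis")) {
    thresholds$thresholds
  } else {
    as_tibble(thresholds)
  }
  items <- intersect(setdiff(names(rt), "person_id"), thr$item_id)
  if (length(items) == 0L) {
    abort("No item in the RT matrix has a computed threshold.",
          class = "rtcump_alignment_error")
  }
  thr <- thr[match(items, thr$item_id), ]
  centers <- switch(config$center,
                    mean = thr$mean_rt,
                    cump = thr$cump_threshold)
  sds <- thr$sd_rt
  k <- config$flag_sd_multiplier
  p <- config$flag_item_proportion

  reports <- purrr::map(seq_len(nrow(rt)), function(i) {
    flag_person(as.numeric(unlist(rt[i, items], use.names = FALSE)),
                centers = centers, sds = sds, k = k, p = p,
                sided = config$sided, person_id = rt$person_id[i])
  })
  out <- purrr::list_rbind(reports)
  if (!quiet) {
    inform(sprintf("Flagged %d of %d respondents (%.1f%%).",
                   sum(out$flag), nrow(out),
                   100 * mean(out$flag)))
  }
  out
}
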