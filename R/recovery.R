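#' Threshold recovery study on simulated mixtures
#'
#' Monte-Carlo check of the central claim behind the CUMP rule: when rapid
#' guesses are fast and near chance while engaged responses are slower and
#' ability-driven, the estimated item threshold separates the two. For each
#' seed a sample is simulated, thresholds are estimated, and every
#' person-item cell is classified as a rapid guess iff its RT falls below
#' the item's CUMP threshold; the classification is scored against the
#' generator's truth table. Items whose overall proportion correct is within
#' `margin` of the chance level are excluded — at chance-level difficulty
#' the curve carries no signal and the threshold is flagged unreliable.
#'
#' @param design A [sim_design()]; the default is a well-separated
#'   per-response mixture (guess median 2 s vs engaged median 30 s,
#'   `pi_guess = 0.25`) at `n_persons = 500`.
#' @param seeds Integer vector of simulation seeds (default 20 replicates).
#' @param config An [rt_config()] for the threshold estimation.
#' @param margin Items must have `p_correct > g + margin` to be scored
#'   (default 0.1).
#' @return A tibble with one row per (seed, scored item): `seed, item_id,
#'   cump_threshold, cump_status, accuracy`.
#' @examples
#' rec <- threshold_recovery_study(sim_design(n_persons = 150), seeds = 1:2)
#' mean(rec$accuracy)
#' @export
threshold_recovery_study <- function(design = sim_design(n_persons = 500),
                                     seeds = 1:20,
                                     config = rt_config(),
                                     margin = 0.1) {
  stopifnot(inherits(design, "sim_design"))
  purrr::list_rbind(purrr::map(seeds, function(s) {
    sim <- simulate_sample(design, seed = s)
    fit <- suppressWarnings(cump_analysis(sim$rt, sim$score,
                                          config = config))
    thr <- fit$thresholds
    scored <- thr[thr$p_correct > config$g + margin, ]
    purrr::list_rbind(purrr::map(seq_len(nrow(scored)), function(r) {
      item <- scored$item_id[r]
      pred <- sim$rt[[item]] < scored$cump_threshold[r]
      truth <- sim$truth[[item]] == 1
      tibble(seed = s, item_id = item,
             cump_threshold = scored$cump_threshold[r],
             cump_status = scored$cump_status[r],
             accuracy = mean(pred == truth))
    }))
  }))
}

#' Flag recovery study with planted whole-test guessers
#'
#' Simulates samples in which a fraction of respondents rapid-guesses on
#' every item, runs the full threshold + flagging pipeline, and scores the
#' person flags against the planted labels. Reported per seed: sensitivity
#' (flagged among planted guessers) and false-positive rate (flagged among
#' engaged respondents).
#'
#' @param design A [sim_design()]; default plants 5% whole-test guessers at
#'   `n_persons = 500` under the well-separated mixture.
#' @param seeds Integer vector of simulation seeds.
#' @param config An [rt_config()]; the default uses the fast-only band at
#'   `k = 1.3`, `p = 0.5` — rapid guessing is a fast phenomenon.
#' @return A tibble: `seed, n_guessers, sensitivity, false_positive_rate`.
#' @examples
#' rec <- flag_recovery_study(
#'   sim_design(n_persons = 150, regime = "per_person"), seeds = 1:2)
#' colMeans(rec[c("sensitivity", "false_positive_rate")])
#' @export
flag_recovery_study <- function(design = sim_design(n_persons = 500,
                                                    regime = "per_person"),
                                seeds = 1:20,
                                config = rt_config(sided = "fast")) {
  stopifnot(inherits(design, "sim_design"))
  purrr::list_rbind(purrr::map(seeds, function(s) {
    sim <- simulate_sample(design, seed = s)
    fit <- suppressWarnings(cump_analysis(sim$rt, sim$score,
                                          config = config))
    flags <- flag_sample(sim$rt, fit, config = config, quiet = TRUE)
    planted <- sim$persons$planted_guesser
    tibble(
      seed = s,
      n_guessers = sum(planted),
      sensitivity = if (any(planted)) mean(flags$flag[planted] == 1)
                    else NA_real_,
      false_positive_rate = if (any(!planted)) {
        mean(flags$flag[!planted] == 1)
      } else {
        NA_real_
      }
    )
  }))
}
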