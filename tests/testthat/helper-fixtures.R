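# Shared fixture builders: tiny in-memory matrices and brute-force oracles.

toy_matrices <- function() {
  rt <- tibble::tibble(
    person_id = c("1", "2", "3"),
    item1 = c(1.5, 3.0, 0.5),
    item2 = c(2.0, NA, 9.9)
  )
  score <- tibble::tibble(
    person_id = c("1", "2", "3"),
    item1 = c(0, 1, 0),
    item2 = c(1, 1, NA)
  )
  list(rt = rt, score = score)
}

write_csv_text <- function(text) {
  f <- tempfile(fileext = ".csv")
  writeLines(text, f)
  f
}

# O(n^2) reference: recount correct/total from scratch at every distinct
# observed time, then apply the max-qualifying-time rule literally.
oracle_cump_threshold <- function(rts, scores, g,
                                  lower_limit = 0, upper_limit = Inf) {
  keep <- !is.na(rts) & !is.na(scores)
  rt <- rts[keep]
  sc <- scores[keep]
  times <- sort(unique(rt))
  cump <- vapply(times, function(t) sum(sc[rt <= t]) / sum(rt <= t),
                 numeric(1))
  below <- cump <= g
  if (!any(below)) {
    status <- "no_crossing"; raw <- lower_limit
  } else if (all(below)) {
    status <- "all_below"; raw <- max(times)
  } else {
    status <- "ok"; raw <- max(times[below])
  }
  value <- raw
  if (value < lower_limit) { value <- lower_limit; status <- "clipped_low" }
  if (value > upper_limit) { value <- upper_limit; status <- "clipped_high" }
  list(threshold = value, status = status, times = times, cump = cump)
}

# Random item instance with ties and missingness, for oracle comparisons.
random_item_instance <- function(n_max = 50) {
  n <- sample(2:n_max, 1)
  rt <- sample(c(round(stats::rlnorm(n, 2, 1), 1), NA), n, replace = TRUE)
  sc <- sample(c(0, 1, NA), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
  # guarantee at least one complete pair
  rt[1] <- 5
  sc[1] <- 1
  list(rt = rt, score = sc)
}

# Well-separated mixture design used by the recovery checks: guesses at a
# 2-second median, engaged responding at a 30-second median.
separated_design <- function(n_persons = 500,
                             regime = "per_response",
                             pi_guess = 0.25,
                             phi_guessers = 0.05) {
  sim_design(
    n_persons = n_persons,
    regime = regime,
    pi_guess = pi_guess,
    phi_guessers = phi_guessers
  )
}
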