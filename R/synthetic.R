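#' Default 2PL item bank
#'
#' Nine reading-comprehension items with published two-parameter logistic
#' estimates (discrimination `a`, difficulty `b` in logits), ordered from
#' easy to difficult. Used as the default item set of [sim_design()].
#'
#' @return Tibble with columns `item_id`, `a`, `b`.
#' @export
default_item_bank <- function() {
  tibble(
    item_id = c("RE41M09", "RE41M05", "RE41M07", "RE41M10", "RE41M13",
                "RE41M15", "RE41M02", "RE41M11", "RE41M14"),
    a = c(1.120, 1.900, 1.490, 2.230, 2.420, 0.350, 1.030, 0.760, 1.810),
    b = c(-0.930, -0.850, -0.530, -0.370, -0.110, 0.000, 0.080, 0.710, 1.620)
  )
}

#' Two-parameter logistic response probability
#'
#' `P(correct | theta) = 1 / (1 + exp(-a (theta - b)))`: the probability an
#' engaged respondent of ability `theta` answers an item of discrimination
#' `a` and difficulty `b` correctly. Vectorised.
#'
#' @param theta Ability, logits.
#' @param a Discrimination, > 0.
#' @param b Difficulty, logits.
#' @return Probabilities in (0, 1).
#' @examples
#' p_correct_2pl(0, a = 1.12, b = -0.93)
#' @export
p_correct_2pl <- function(theta, a, b) {
  if (any(a <= 0)) {
    abort("Discrimination `a` must be positive.",
          class = "rtcump_parameter_error")
  }
  stats::plogis(a * (theta - b))
}

#' Simulation design for joint response / response-time data
#'
#' Describes a population in which engaged responding follows a 2PL for
#' correctness and a lognormal distribution for response times, while rapid
#' guessing is correct at the chance level `g` with much faster lognormal
#' times. Guessing can be planted per response (each engaged-capable cell
#' flips to a guess independently with probability `pi_guess`) or per person
#' (a fraction `phi_guessers` of respondents guesses on every item).
#'
#' Default time scales put the engaged median at 30 s per item
#' (`beta = log(30)`, spread 0.5 log-seconds) and the guessing median at 2 s
#' (`mu_guess = log(2)`, spread 0.3): clearly separated fast and slow
#' mixture components, the regime the threshold method is designed for.
#'
#' @param n_persons Number of respondents (> 0). Default 494.
#' @param items Item bank: tibble with `item_id`, `a` (> 0), `b`.
#' @param g Chance level of a rapid guess, in (0, 1). Default 0.25.
#' @param beta Engaged log-median RT per item, log-seconds; length 1 or one
#'   per item. Default `log(30)`.
#' @param sigma_rt Engaged log-RT spread per item (> 0); length 1 or one per
#'   item. Default 0.5.
#' @param sigma_tau Between-person speed spread (> 0), log-seconds: person
#'   `i` shifts every engaged log-RT by `-tau_i`, `tau_i ~ N(0, sigma_tau^2)`.
#'   Default 0.2.
#' @param mu_guess,sigma_guess Guessing log-RT mean and spread. Defaults
#'   `log(2)` and 0.3.
#' @param regime `"per_response"` (default) or `"per_person"`.
#' @param pi_guess Per-response guessing probability, in [0, 1]. Default 0.25.
#' @param phi_guessers Fraction of whole-test guessers under
#'   `"per_person"`, in [0, 1]. Default 0.05.
#' @return A list of class `"sim_design"`.
#' @examples
#' sim_design(n_persons = 100, regime = "per_person")
#' @export
sim_design <- function(n_persons = 494,
                       items = default_item_bank(),
                       g = 0.25,
                       beta = log(30),
                       sigma_rt = 0.5,
                       sigma_tau = 0.2,
                       mu_guess = log(2),
                       sigma_guess = 0.3,
                       regime = c("per_response", "per_person"),
                       pi_guess = 0.25,
                       phi_guessers = 0.05) {
  regime <- match.arg(regime)
  items <- as_tibble(items)
  if (!all(c("item_id", "a", "b") %in% names(items)) || nrow(items) == 0) {
    abort("`items` needs columns item_id, a, b and at least one row.",
          class = "rtcump_parameter_error")
  }
  if (any(items$a <= 0)) {
    abort("Discrimination `a` must be positive.",
          class = "rtcump_parameter_error")
  }
  if (!is.numeric(n_persons) || n_persons < 1) {
    abort("`n_persons` must be at least 1.", class = "rtcump_parameter_error")
  }
  if (g <= 0 || g >= 1) {
    abort("`g` must be strictly between 0 and 1.",
          class = "rtcump_parameter_error")
  }
  n_items <- nrow(items)
  beta <- rep_len(beta, n_items)
  sigma_rt <- rep_len(sigma_rt, n_items)
  if (any(sigma_rt <= 0) || sigma_tau <= 0 || sigma_guess <= 0) {
    abort("All log-RT spreads must be positive.",
          class = "rtcump_parameter_error")
  }
  if (pi_guess < 0 || pi_guess > 1 || phi_guessers < 0 || phi_guessers > 1) {
    abort("`pi_guess` and `phi_guessers` must lie in [0, 1].",
          class = "rtcump_parameter_error")
  }
  structure(
    list(n_persons = as.integer(n_persons), items = items, g = g,
         beta = beta, sigma_rt = sigma_rt, sigma_tau = sigma_tau,
         mu_guess = mu_guess, sigma_guess = sigma_guess,
         regime = regime, pi_guess = pi_guess, phi_guessers = phi_guessers),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> %d persons x %d items, g = %g, regime = %s\n",
              x$n_persons, nrow(x$items), x$g, x$regime))
  cat(sprintf("  engaged RT: median %.3g s (spread %.3g); guess RT: median %.3g s (spread %.3g)\n",
              exp(x$beta[1]), x$sigma_rt[1], exp(x$mu_guess), x$sigma_guess))
  cat(sprintf("  guessing: pi = %g (per response) / phi = %g (per person)\n",
              x$pi_guess, x$phi_guessers))
  invisible(x)
}

#' Simulate a joint response / response-time sample
#'
#' Draws abilities `theta_i ~ N(0, 1)` and person speeds
#' `tau_i ~ N(0, sigma_tau^2)`, then for every person-item cell: engaged
#' cells score `Bernoulli(P_2PL(theta_i; a_j, b_j))` with
#' `log RT ~ N(beta_j - tau_i, sigma_j^2)`; guessed cells score
#' `Bernoulli(g)` with `log RT ~ N(mu_guess, sigma_guess^2)`. The truth
#' table records every guessed cell. Fully reproducible from `seed`.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `"sim_sample"` with tibbles `rt`, `score`,
#'   `truth` (person-by-item 0/1 indicator of rapid guessing) — all with a
#'   `person_id` column — plus `persons` (`person_id, theta, tau,
#'   planted_guesser`), the `design` and the `seed`.
#' @examples
#' sim <- simulate_sample(sim_design(n_persons = 20), seed = 42)
#' sim$rt
#' @export
simulate_sample <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  n <- design$n_persons
  items <- design$items
  J <- nrow(items)
  person_id <- as.character(seq_len(n))

  theta <- rnorm(n)
  tau <- rnorm(n, 0, design$sigma_tau)

  if (design$regime == "per_person") {
    guesser <- rbinom(n, 1L, design$phi_guessers) == 1L
    guess <- matrix(guesser, nrow = n, ncol = J)
  } else {
    guesser <- rep(FALSE, n)
    guess <- matrix(rbinom(n * J, 1L, design$pi_guess) == 1L, nrow = n)
  }

  p_engaged <- outer(theta, seq_len(J),
                     function(th, j) p_correct_2pl(th, items$a[j], items$b[j]))
  p <- ifelse(guess, design$g, p_engaged)
  score <- matrix(rbinom(n * J, 1L, as.vector(p)), nrow = n)

  mu_engaged <- outer(-tau, design$beta, `+`)
  mu <- ifelse(guess, design$mu_guess, mu_engaged)
  sigma <- ifelse(guess, design$sigma_guess,
                  matrix(design$sigma_rt, nrow = n, ncol = J, byrow = TRUE))
  rt <- exp(matrix(rnorm(n * J, as.vector(mu), as.vector(sigma)), nrow = n))

  to_tbl <- function(m) {
    colnames(m) <- items$item_id
    dplyr::bind_cols(tibble(person_id = person_id), as_tibble(m))
  }
  structure(
    list(
      rt = to_tbl(rt),
      score = to_tbl(score),
      truth = to_tbl(matrix(as.integer(guess), nrow = n)),
      persons = tibble(person_id = person_id, theta = theta, tau = tau,
                       planted_guesser = guesser),
      design = design,
      seed = seed
    ),
    class = "sim_sample"
  )
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("<sim_sample> %d persons x %d items (seed %s)\n",
              nrow(x$rt), ncol(x$rt) - 1L,
              x$seed %||% "<none>"))
  cat(sprintf("  rapid-guess cells: %d (%.1f%%)\n",
              sum(x$truth[-1]), 100 * mean(as.matrix(x$truth[-1]))))
  invisible(x)
}

#' Write a simulated sample as an input fixture
#'
#' Emits the tool's two-CSV input dialect (`rt.csv`, `resp.csv`) plus the
#' rapid-guess ground truth (`truth.csv`) and a `design.yaml` echo of all
#' generator settings, so a run can be reproduced and scored.
#'
#' @param design A [sim_design()].
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed passed to [simulate_sample()].
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(design, out_dir, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  sim <- simulate_sample(design, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rt = file.path(out_dir, "rt.csv"),
             resp = file.path(out_dir, "resp.csv"),
             truth = file.path(out_dir, "truth.csv"),
             design = file.path(out_dir, "design.yaml"))
  fmt_rt <- format_num_cols(sim$rt, setdiff(names(sim$rt), "person_id"))
  readr::write_csv(fmt_rt, paths["rt"], progress = FALSE)
  readr::write_csv(sim$score, paths["resp"], progress = FALSE)
  readr::write_csv(sim$truth, paths["truth"], progress = FALSE)
  yaml::write_yaml(design_to_list(design, seed), paths["design"])
  invisible(paths)
}

design_to_list <- function(design, seed = NULL) {
  list(
    n_persons = design$n_persons,
    items = lapply(seq_len(nrow(design$items)), function(j) {
      list(item_id = design$items$item_id[j],
           a = design$items$a[j], b = design$items$b[j])
    }),
    g = design$g,
    beta = as.numeric(design$beta),
    sigma_rt = as.numeric(design$sigma_rt),
    sigma_tau = design$sigma_tau,
    mu_guess = design$mu_guess,
    sigma_guess = design$sigma_guess,
    regime = design$regime,
    pi_guess = design$pi_guess,
    phi_guessers = design$phi_guessers,
    seed = seed
  )
}

#' Read a simulation design from YAML
#'
#' Inverse of the `design.yaml` echo written by [write_fixture()]; unknown
#' fields are rejected, absent fields fall back to the [sim_design()]
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `design` (a [sim_design()]) and `seed`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "rtcump_io_error")
  }
  y <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(sprintf("Malformed YAML in %s: %s", path, conditionMessage(e)),
          class = "rtcump_config_error")
  })
  if (!is.list(y)) {
    abort(sprintf("Malformed design file %s.", path),
          class = "rtcump_config_error")
  }
  known <- c("n_persons", "items", "g", "beta", "sigma_rt", "sigma_tau",
             "mu_guess", "sigma_guess", "regime", "pi_guess",
             "phi_guessers", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown design field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "rtcump_config_error")
  }
  seed <- y$seed
  y$seed <- NULL
  if (!is.null(y$items)) {
    y$items <- purrr::list_rbind(purrr::map(y$items, as_tibble))
  }
  design <- do.call(sim_design, y)
  list(design = design, seed = seed)
}
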