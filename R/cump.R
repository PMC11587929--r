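#' Cumulative proportion correct (CUMP) curve for one item
#'
#' For every distinct observed response time `t`, computes the proportion of
#' correct responses among all responses given in at most `t` seconds.
#' Responses tied at the same time enter the running counts together, so the
#' curve is evaluated on the closed set `RT <= t`. Pairs with a missing
#' response time or score are dropped (pairwise deletion). The curve starts
#' near the chance level when fast responses are blind guesses and converges
#' to the item's overall proportion correct as `t` grows.
#'
#' @param rts Numeric vector of response times, seconds; `NA` allowed.
#' @param scores Numeric vector of the same length, values 0/1/`NA`.
#' @param item_id Optional identifier carried into the result (and error
#'   messages).
#' @return A tibble with columns `time` (strictly increasing distinct RTs),
#'   `cum_correct`, `cum_total` and `cump = cum_correct / cum_total`.
#' @examples
#' cump_curve(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1))
#' @export
cump_curve <- function(rts, scores, item_id = NULL) {
  if (length(rts) != length(scores)) {
    abort("`rts` and `scores` must have the same length.",
          class = "rtcump_validation_error")
  }
  keep <- !is.na(rts) & !is.na(scores)
  if (!any(keep)) {
    abort(sprintf("Item %s has no complete (rt, score) pair.",
                  item_id %||% "<unnamed>"),
          class = "rtcump_empty_item_error")
  }
  rt <- rts[keep]
  sc <- scores[keep]
  ord <- order(rt)
  rt <- rt[ord]
  sc <- sc[ord]
  cum_total <- seq_along(rt)
  cum_correct <- cumsum(sc)
  last_of_tie <- !duplicated(rt, fromLast = TRUE)
  cc <- as.integer(cum_correct[last_of_tie])
  ct <- as.integer(cum_total[last_of_tie])
  tibble(
    time = rt[last_of_tie],
    cum_correct = cc,
    cum_total = ct,
    cump = cc / ct
  )
}

#' CUMP response-time threshold for one item
#'
#' The threshold is the largest observed time at which the cumulative
#' proportion correct is still at or below the chance level `g`:
#' `C = max { t : CUMP(t) <= g }`. Responses faster than `C` are consistent
#' with blind guessing. Two boundary regimes get explicit statuses instead of
#' a silent number: `"no_crossing"` when the curve never drops to `g` (easy
#' items, or fast responders who are nonetheless accurate — `C` is set to
#' `lower_limit`), and `"all_below"` when the curve never rises above `g`
#' (items at or below chance difficulty — `C` is the largest observed RT and
#' the threshold is unreliable). The raw threshold is then clipped to
#' `[lower_limit, upper_limit]`, with statuses `"clipped_low"` /
#' `"clipped_high"` when clipping changed the value.
#'
#' @param curve A curve from [cump_curve()].
#' @param g Chance level, in (0, 1).
#' @param lower_limit,upper_limit Clipping limits in seconds.
#' @return A one-row tibble with `cump_threshold` (seconds) and `cump_status`.
#' @examples
#' cv <- cump_curve(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1))
#' cump_threshold(cv, g = 0.25)
#' @export
cump_threshold <- function(curve, g, lower_limit = 0, upper_limit = Inf) {
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g <= 0 || g >= 1) {
    abort("`g` must be a single number strictly between 0 and 1.",
          class = "rtcump_config_error")
  }
  if (nrow(curve) == 0L) {
    abort("Empty CUMP curve.", class = "rtcump_empty_item_error")
  }
  below <- curve$cump <= g
  if (!any(below)) {
    status <- "no_crossing"
    raw <- lower_limit
  } else if (all(below)) {
    status <- "all_below"
    raw <- max(curve$time)
  } else {
    status <- "ok"
    raw <- max(curve$time[below])
  }
  value <- raw
  if (value < lower_limit) {
    value <- lower_limit
    status <- "clipped_low"
  } else if (value > upper_limit) {
    value <- upper_limit
    status <- "clipped_high"
  }
  tibble(cump_threshold = value, cump_status = status)
}

#' Descriptive response-time thresholds for one item
#'
#' The sample mean RT and the mean plus one standard deviation, the two
#' descriptive cutoffs reported next to the CUMP threshold. A mean-minus-1SD
#' cutoff is deliberately not produced: response times are right-skewed, so
#' that value can be negative and is not a meaningful time.
#'
#' @param rts Numeric RT vector for one item; `NA` dropped.
#' @param sd_ddof 1 for the sample SD (default), 0 for the population SD.
#'   With a single observation the SD is defined as 0.
#' @param item_id Optional identifier for error messages.
#' @return A one-row tibble with `mean_rt`, `sd_rt`, `mean_plus_1sd`.
#' @examples
#' descriptive_thresholds(c(2, 4))
#' @export
descriptive_thresholds <- function(rts, sd_ddof = 1, item_id = NULL) {
  rt <- rts[!is.na(rts)]
  if (length(rt) == 0L) {
    abort(sprintf("Item %s has no observed response time.",
                  item_id %||% "<unnamed>"),
          class = "rtcump_empty_item_error")
  }
  m <- mean(rt)
  n <- length(rt)
  if (n == 1L) {
    s <- 0
  } else if (sd_ddof == 1) {
    s <- stats::sd(rt)
  } else {
    s <- stats::sd(rt) * sqrt((n - 1) / n)
  }
  tibble(mean_rt = m, sd_rt = s, mean_plus_1sd = m + s)
}

#' Item-level threshold analysis of a response-time / score pair
#'
#' Runs the full per-item pipeline over an aligned person-by-item pair:
#' CUMP curve, CUMP threshold with status, and the descriptive mean /
#' mean+1SD cutoffs. Items with no complete (rt, score) pair are excluded
#' with a warning naming them; an analysis where every item is empty is an
#' error.
#'
#' @param rt Response-time matrix (tibble: `person_id` + item columns).
#' @param score Score matrix, aligned or alignable with `rt`.
#' @param config An [rt_config()].
#' @return An object of class `"cump_analysis"`: a list with
#'   * `thresholds` — one row per item: `item_id, n_used, p_correct, g,
#'     cump_threshold, cump_status, mean_rt, sd_rt, mean_plus_1sd`;
#'   * `curves` — tidy curve table `item_id, time, cum_correct, cum_total,
#'     cump`;
#'   * `config`, `n_persons`, `n_items`, `skipped_items`.
#'   Use [tidy()] for the threshold table, [glance()] for a one-row summary
#'   and [autoplot()] for the curve display.
#' @examples
#' sim <- simulate_sample(sim_design(n_persons = 60), seed = 1)
#' fit <- cump_analysis(sim$rt, sim$score)
#' tidy(fit)
#' @export
cump_analysis <- function(rt, score, config = rt_config()) {
  stopifnot(inherits(config, "rt_config"))
  pair <- align_pair(rt, score)
  items <- setdiff(names(pair$rt), "person_id")

  res <- purrr::map(items, function(item) {
    rts <- pair$rt[[item]]
    scs <- pair$score[[item]]
    keep <- !is.na(rts) & !is.na(scs)
    if (!any(keep)) {
      return(NULL)
    }
    curve <- cump_curve(rts, scs, item_id = item)
    thr <- cump_threshold(curve, config$g,
                          lower_limit = config$lower_limit,
                          upper_limit = config$upper_limit)
    desc <- descriptive_thresholds(rts[keep], sd_ddof = config$sd_ddof,
                                   item_id = item)
    n_used <- sum(keep)
    p_correct <- sum(scs[keep]) / n_used
    if (p_correct <= config$g) {
      warn(sprintf(
        "Item %s: overall proportion correct (%.3f) is at or below the chance level %.3f; CUMP threshold unreliable (status %s).",
        item, p_correct, config$g, thr$cump_status))
    }
    list(
      threshold = dplyr::bind_cols(
        tibble(item_id = item, n_used = as.integer(n_used),
               p_correct = p_correct, g = config$g),
        thr, desc),
      curve = dplyr::bind_cols(tibble(item_id = item), curve)
    )
  })
  names(res) <- items
  skipped <- items[purrr::map_lgl(res, is.null)]
  if (length(skipped) == length(items)) {
    abort("Every item has zero complete (rt, score) pairs.",
          class = "rtcump_empty_item_error")
  }
  if (length(skipped) > 0) {
    warn(sprintf("%d item(s) with no complete pair excluded: %s",
                 length(skipped), paste(skipped, collapse = ", ")))
  }
  res <- purrr::compact(res)
  structure(
    list(
      thresholds = purrr::list_rbind(purrr::map(res, "threshold")),
      curves = purrr::list_rbind(purrr::map(res, "curve")),
      config = config,
      n_persons = nrow(pair$rt),
      n_items = length(items) - length(skipped),
      skipped_items = skipped
    ),
    class = "cump_analysis"
  )
}

#' @export
print.cump_analysis <- function(x, ...) {
  cat(sprintf("<cump_analysis> %d persons x %d items (g = %g)\n",
              x$n_persons, x$n_items, x$config$g))
  print(x$thresholds, ...)
  invisible(x)
}

#' @rdname cump_analysis
#' @param x A `cump_analysis` object.
#' @param ... Unused.
#' @method tidy cump_analysis
#' @export
tidy.cump_analysis <- function(x, ...) {
  x$thresholds
}

#' @rdname cump_analysis
#' @method glance cump_analysis
#' @export
glance.cump_analysis <- function(x, ...) {
  tibble(
    n_persons = x$n_persons,
    n_items = x$n_items,
    n_items_skipped = length(x$skipped_items),
    g = x$config$g,
    n_ok = sum(x$thresholds$cump_status == "ok"),
    n_no_crossing = sum(x$thresholds$cump_status == "no_crossing"),
    n_all_below = sum(x$thresholds$cump_status == "all_below"),
    median_cump_threshold = stats::median(x$thresholds$cump_threshold)
  )
}

#' @rdname cump_analysis
#' @param object A `cump_analysis` object.
#' @param items Optional subset of item ids to display.
#' @method autoplot cump_analysis
#' @export
autoplot.cump_analysis <- function(object, items = NULL, ...) {
  curves <- object$curves
  thr <- object$thresholds
  if (!is.null(items)) {
    curves <- curves[curves$item_id %in% items, ]
    thr <- thr[thr$item_id %in% items, ]
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$cump)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$config$g, linetype = "dashed") +
    ggplot2::geom_vline(
      data = thr[thr$cump_status %in% c("ok", "clipped_low", "clipped_high"), ],
      ggplot2::aes(xintercept = .data$cump_threshold),
      colour = "#0072B2") +
    ggplot2::facet_wrap(~item_id, scales = "free_x") +
    ggplot2::labs(x = "response time (s)",
                  y = "cumulative proportion correct",
                  title = sprintf("CUMP curves (chance level g = %g)",
                                  object$config$g)) +
    ggplot2::theme_minimal()
}
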