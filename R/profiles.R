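#' Build a person's engagement profile
#'
#' Assembles the plot-ready record for one respondent: their response time
#' and correctness on every item, next to the item's CUMP, mean and
#' mean+1SD thresholds. Missing RT or score cells stay missing and simply
#' leave the corresponding marker out of the plot. No rendering happens
#' here.
#'
#' @param rt Response-time matrix (tibble: `person_id` + item columns).
#' @param score Score matrix, alignable with `rt`.
#' @param thresholds A `cump_analysis` object or its threshold tibble.
#' @param person Person identifier (as in `rt$person_id`).
#' @param order_by `"input"` (default) keeps the item column order;
#'   `"difficulty"` sorts ascending by the `difficulty` vector.
#' @param difficulty Optional named numeric vector (names = item ids) used
#'   when `order_by = "difficulty"`.
#' @param theta Optional ability score (logits) shown in the plot title.
#' @return A tibble of class `"person_profile"`: one row per item with
#'   `item_id, position, rt, correct, cump_threshold, mean_rt,
#'   mean_plus_1sd`; person id and theta carried as attributes.
#' @examples
#' sim <- simulate_sample(sim_design(n_persons = 30), seed = 7)
#' fit <- cump_analysis(sim$rt, sim$score)
#' build_profile(sim$rt, sim$score, fit, person = "3")
#' @export
build_profile <- function(rt, score, thresholds, person,
                          order_by = c("input", "difficulty"),
                          difficulty = NULL, theta = NULL) {
  order_by <- match.arg(order_by)
  pair <- align_pair(rt, score)
  thr <- if (inherits(thresholds, "cump_analysis")) {
    thresholds$thresholds
  } else {
    as_tibble(thresholds)
  }
  person <- as.character(person)
  i <- match(person, pair$rt$person_id)
  if (is.na(i)) {
    abort(sprintf("Unknown person id: %s", person),
          class = "rtcump_lookup_error")
  }
  items <- intersect(setdiff(names(pair$rt), "person_id"), thr$item_id)
  if (order_by == "difficulty") {
    if (is.null(difficulty)) {
      abort("`order_by = \"difficulty\"` needs a `difficulty` vector.",
            class = "rtcump_config_error")
    }
    items <- items[order(difficulty[items])]
  }
  thr <- thr[match(items, thr$item_id), ]
  out <- tibble(
    item_id = items,
    position = seq_along(items),
    rt = as.numeric(unlist(pair$rt[i, items], use.names = FALSE)),
    correct = as.numeric(unlist(pair$score[i, items], use.names = FALSE)),
    cump_threshold = thr$cump_threshold,
    mean_rt = thr$mean_rt,
    mean_plus_1sd = thr$mean_plus_1sd
  )
  structure(out, person_id = person, theta = theta,
            class = c("person_profile", class(out)))
}

#' Plot a person profile
#'
#' Response time per item (circles coloured by correctness) over the three
#' threshold series: CUMP, mean RT and mean+1SD. Default colours are a
#' colour-vision-safe green/vermillion pair; items with a missing RT or
#' score yield no marker.
#'
#' @param object A [build_profile()] result.
#' @param log_time Use a log10 time axis.
#' @param success_colour,failure_colour Marker colours for correct /
#'   incorrect responses.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot person_profile
#' @export
autoplot.person_profile <- function(object, log_time = FALSE,
                                    success_colour = "#009E73",
                                    failure_colour = "#D55E00", ...) {
  df <- as_tibble(object)
  lines <- tidyr::pivot_longer(
    df[c("position", "cump_threshold", "mean_rt", "mean_plus_1sd")],
    -"position", names_to = "series", values_to = "seconds")
  lines$series <- factor(lines$series,
                         levels = c("cump_threshold", "mean_rt",
                                    "mean_plus_1sd"),
                         labels = c("CUMP", "mean", "+1SD"))
  pts <- df[!is.na(df$rt) & !is.na(df$correct), ]
  pts$outcome <- factor(ifelse(pts$correct == 1, "correct", "incorrect"),
                        levels = c("correct", "incorrect"))
  theta <- attr(object, "theta")
  title <- sprintf("Participant %s", attr(object, "person_id"))
  if (!is.null(theta)) {
    title <- sprintf("%s (theta = %.3g)", title, theta)
  }
  p <- ggplot2::ggplot(lines,
                       ggplot2::aes(x = .data$position, y = .data$seconds)) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$series)) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$position, y = .data$rt,
                   colour = .data$outcome),
      size = 3, shape = 16, inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(
      values = c(correct = success_colour, incorrect = failure_colour),
      drop = FALSE) +
    ggplot2::scale_x_continuous(breaks = df$position, labels = df$item_id) +
    ggplot2::labs(x = NULL, y = "response time (s)", title = title,
                  linetype = "threshold", colour = "response") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (log_time) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

#' Render a person profile to an image file
#'
#' Deterministic for fixed input: no jitter, fixed device size.
#'
#' @param profile A [build_profile()] result.
#' @param path Output file path.
#' @param format `"png"`, `"svg"` or `"pdf"`; inferred from `path` when
#'   `NULL`.
#' @param width,height Device size in inches.
#' @param dpi Resolution for PNG.
#' @param ... Passed to [autoplot.person_profile()].
#' @return `path`, invisibly.
#' @export
render_profile <- function(profile, path, format = NULL,
                           width = 8, height = 5, dpi = 120, ...) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("png", "svg", "pdf")) {
    abort(sprintf("Unsupported plot format: \"%s\" (use png, svg or pdf).",
                  format), class = "rtcump_config_error")
  }
  p <- autoplot(profile, ...)
  open_dev <- switch(format,
    png = function() grDevices::png(path, width = width, height = height,
                                    units = "in", res = dpi),
    svg = function() grDevices::svg(path, width = width, height = height),
    pdf = function() grDevices::pdf(path, width = width, height = height))
  open_dev()
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' Render profiles for a set of persons
#'
#' Writes one image per selected person, named `person_<id>.<ext>`.
#'
#' @param rt,score,thresholds As in [build_profile()].
#' @param persons Character vector of person ids, or `"flagged"` to select
#'   every person with `flag == 1` in `flags`.
#' @param flags Flag tibble from [flag_sample()]; required when
#'   `persons = "flagged"`.
#' @param out_dir Output directory, created if needed.
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param theta Optional named numeric vector of ability scores (names =
#'   person ids) for plot titles.
#' @param ... Passed to [build_profile()] (`order_by`, `difficulty`).
#' @return Character vector of written paths, invisibly (empty with a
#'   warning when the selection is empty).
#' @export
render_batch <- function(rt, score, thresholds, persons, flags = NULL,
                         out_dir = ".", format = "png", theta = NULL, ...) {
  rt <- as_rt_matrix(rt)
  if (identical(persons, "flagged")) {
    if (is.null(flags)) {
      abort("`persons = \"flagged\"` needs a `flags` table.",
            class = "rtcump_config_error")
    }
    persons <- flags$person_id[flags$flag == 1]
  }
  persons <- as.character(persons)
  if (length(persons) == 0L) {
    warn("Empty person selection; no profile written.")
    return(invisible(character(0)))
  }
  unknown <- setdiff(persons, rt$person_id)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown person id(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "rtcump_lookup_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(persons, function(id) {
    prof <- build_profile(rt, score, thresholds, person = id,
                          theta = if (!is.null(theta)) {
                            unname(theta[id])
                          },
                          ...)
    out <- file.path(out_dir, sprintf("person_%s.%s", id, format))
    render_profile(prof, out, format = format)
    out
  })
  invisible(paths)
}
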