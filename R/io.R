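#' Read a person-by-item response-time matrix
#'
#' Reads a comma-delimited matrix whose first row names the items and whose
#' optional first column carries person identifiers. Empty cells and `"NA"`
#' are treated as missing. Every present value must be a strictly positive
#' number of seconds.
#'
#' A leading identifier column is auto-detected when its header is empty,
#' matches one of `"person_id"`, `"person"`, `"id"` (case-insensitive), or
#' when the column contains non-numeric entries; `id_col` overrides the
#' detection. When no identifier column exists, persons are numbered by row
#' order (`"1"`, `"2"`, ...), so "participant 216" is the 216th data row.
#'
#' @param path Path to a CSV file.
#' @param id_col Optional: name of the identifier column, or `FALSE` to force
#'   bare-matrix parsing, or `TRUE` to force the first column to be ids.
#' @param na Character vector of strings to read as missing.
#' @return A tibble with a `person_id` character column followed by one
#'   numeric column per item.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("item1,item2\n1.5,2.0\n3.0,\n0.5,9.9", f)
#' read_rt_matrix(f)
#' @export
read_rt_matrix <- function(path, id_col = NULL, na = c("", "NA")) {
  read_matrix(path, value_kind = "rt", id_col = id_col, na = na)
}

#' Read a person-by-item scored-response matrix
#'
#' Same file dialect as [read_rt_matrix()], but cells must be 0, 1 or
#' missing (pre-scored dichotomous responses).
#'
#' @inheritParams read_rt_matrix
#' @return A tibble with a `person_id` column followed by one numeric
#'   column per item, values in {0, 1, NA}.
#' @export
read_score_matrix <- function(path, id_col = NULL, na = c("", "NA")) {
  read_matrix(path, value_kind = "score", id_col = id_col, na = na)
}

read_matrix <- function(path, value_kind = c("rt", "score"),
                        id_col = NULL, na = c("", "NA")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "rtcump_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = na, progress = FALSE,
                         show_col_types = FALSE,
                         name_repair = "minimal")
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed CSV %s: %s (first problem at row %d)",
                  path, probs$expected[1], probs$row[1]),
          class = "rtcump_format_error")
  }
  nms <- names(raw)
  if (anyDuplicated(nms[nms != ""])) {
    abort("Duplicate item ids in header.", class = "rtcump_format_error")
  }

  first_is_id <- detect_id_column(raw, id_col)
  if (first_is_id) {
    person_id <- as.character(raw[[1L]])
    values <- raw[-1L]
  } else {
    person_id <- as.character(seq_len(nrow(raw)))
    values <- raw
  }
  if (anyDuplicated(person_id)) {
    abort("Person ids must be unique.", class = "rtcump_validation_error")
  }
  if (ncol(values) == 0L) {
    abort("No item columns found.", class = "rtcump_format_error")
  }

  parsed <- purrr::imap(values, function(col, item) {
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric cell \"%s\" at row %d, item %s",
                    col[bad[1]], bad[1], item),
            class = "rtcump_parse_error")
    }
    num
  })
  out <- tibble::tibble(person_id = person_id, !!!parsed)
  validate_matrix(out, value_kind)
}

detect_id_column <- function(raw, id_col) {
  if (isTRUE(id_col)) return(TRUE)
  if (isFALSE(id_col)) return(FALSE)
  first_name <- names(raw)[1L]
  if (is.character(id_col) && length(id_col) == 1L) {
    if (!identical(tolower(first_name), tolower(id_col))) {
      abort(sprintf("Declared id column \"%s\" is not the first column.",
                    id_col), class = "rtcump_format_error")
    }
    return(TRUE)
  }
  if (first_name == "" || grepl("^\\.\\.\\.", first_name) ||
      tolower(first_name) %in% c("person_id", "person", "id")) {
    return(TRUE)
  }
  col <- raw[[1L]]
  any(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
}

validate_matrix <- function(df, value_kind) {
  items <- setdiff(names(df), "person_id")
  for (item in items) {
    v <- df[[item]]
    if (value_kind == "rt") {
      bad <- which(!is.na(v) & v <= 0)
      if (length(bad) > 0) {
        abort(sprintf(
          "Response times must be strictly positive; found %g at row %d, item %s",
          v[bad[1]], bad[1], item), class = "rtcump_validation_error")
      }
    } else {
      bad <- which(!is.na(v) & !v %in% c(0, 1))
      if (length(bad) > 0) {
        abort(sprintf(
          "Scores must be 0 or 1; found %g at row %d, item %s",
          v[bad[1]], bad[1], item), class = "rtcump_validation_error")
      }
    }
  }
  df
}

#' Validate an in-memory response-time matrix
#'
#' Checks that a data frame already shaped as person-by-item (a `person_id`
#' column plus numeric item columns) satisfies the response-time contract:
#' strictly positive where present, unique ids.
#'
#' @param df A data frame with `person_id` plus numeric item columns.
#' @return The validated tibble (invisibly identical content).
#' @export
as_rt_matrix <- function(df) {
  as_matrix_common(df, "rt")
}

#' Validate an in-memory scored-response matrix
#'
#' @inheritParams as_rt_matrix
#' @return The validated tibble; values must be in {0, 1, NA}.
#' @export
as_score_matrix <- function(df) {
  as_matrix_common(df, "score")
}

as_matrix_common <- function(df, value_kind) {
  df <- as_tibble(df)
  if (!"person_id" %in% names(df)) {
    df <- dplyr::bind_cols(
      tibble(person_id = as.character(seq_len(nrow(df)))), df)
  }
  df$person_id <- as.character(df$person_id)
  if (anyDuplicated(df$person_id)) {
    abort("Person ids must be unique.", class = "rtcump_validation_error")
  }
  items <- setdiff(names(df), "person_id")
  for (item in items) {
    if (!is.numeric(df[[item]])) {
      abort(sprintf("Item column %s is not numeric.", item),
            class = "rtcump_parse_error")
    }
  }
  validate_matrix(df[c("person_id", items)], value_kind)
}

#' Align a response-time / score matrix pair
#'
#' Matches rows (persons) and columns (items) by identifier. Persons or items
#' present in only one of the two inputs are dropped with a warning that
#' counts them; the row and column order of the response-time matrix is
#' preserved. Aligning an already-aligned pair is a no-op.
#'
#' @param rt Response-time matrix (tibble from [read_rt_matrix()] or
#'   [as_rt_matrix()]).
#' @param score Score matrix, same shape contract.
#' @return A list with elements `rt` and `score`, dimension-matched.
#' @export
align_pair <- function(rt, score) {
  rt <- as_rt_matrix(rt)
  score <- as_score_matrix(score)
  items_rt <- setdiff(names(rt), "person_id")
  items_sc <- setdiff(names(score), "person_id")
  items <- intersect(items_rt, items_sc)
  persons <- intersect(rt$person_id, score$person_id)
  if (length(items) == 0L) {
    abort("No overlapping items between the two matrices.",
          class = "rtcump_alignment_error")
  }
  if (length(persons) == 0L) {
    abort("No overlapping persons between the two matrices.",
          class = "rtcump_alignment_error")
  }
  d_items <- length(union(items_rt, items_sc)) - length(items)
  d_persons <- length(union(rt$person_id, score$person_id)) - length(persons)
  if (d_items > 0) {
    warn(sprintf("%d item(s) present in only one input dropped.", d_items))
  }
  if (d_persons > 0) {
    warn(sprintf("%d person(s) present in only one input dropped.", d_persons))
  }
  rt2 <- rt[rt$person_id %in% persons, c("person_id", items)]
  score2 <- score[match(rt2$person_id, score$person_id), c("person_id", items)]
  list(rt = rt2, score = score2)
}

matrix_to_long <- function(df, value_name) {
  tidyr::pivot_longer(df, -"person_id",
                      names_to = "item_id", values_to = value_name)
}

format_num_cols <- function(df, cols, digits = 6) {
  for (cl in cols) {
    df[[cl]] <- ifelse(is.na(df[[cl]]), NA_character_,
                       formatC(df[[cl]], format = "f", digits = digits))
  }
  df
}

#' Write the item threshold table
#'
#' Writes one row per item with columns `item_id, n_used, p_correct, g,
#' cump_threshold, cump_status, mean_rt, sd_rt, mean_plus_1sd`; floating
#' values at six decimal places.
#'
#' @param thresholds Tibble of item thresholds (see [cump_analysis()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  cols <- c("item_id", "n_used", "p_correct", "g", "cump_threshold",
            "cump_status", "mean_rt", "sd_rt", "mean_plus_1sd")
  missing_cols <- setdiff(cols, names(thresholds))
  if (length(missing_cols) > 0) {
    abort(sprintf("Threshold table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "rtcump_validation_error")
  }
  out <- format_num_cols(thresholds[cols],
                         c("p_correct", "g", "cump_threshold",
                           "mean_rt", "sd_rt", "mean_plus_1sd"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write per-item CUMP curves in tidy form
#'
#' Columns: `item_id, time, cum_correct, cum_total, cump`.
#'
#' @param curves Tidy curve tibble (see [cump_analysis()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  cols <- c("item_id", "time", "cum_correct", "cum_total", "cump")
  out <- format_num_cols(curves[cols], c("time", "cump"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write the person flag table
#'
#' Columns: `person_id, n_items_used, n_aberrant, prop_aberrant, n_fast,
#' n_slow, flag` — one row per respondent.
#'
#' @param flags Flag tibble (see [flag_sample()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flags <- function(flags, path) {
  cols <- c("person_id", "n_items_used", "n_aberrant", "prop_aberrant",
            "n_fast", "n_slow", "flag")
  out <- format_num_cols(flags[cols], "prop_aberrant")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
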