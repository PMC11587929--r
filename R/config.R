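#' Analysis configuration
#'
#' Bundles every tunable of the threshold and flagging pipeline. Defaults
#' follow the conventions of the rapid-guessing literature: a chance level of
#' 0.25 (four-option multiple choice), a flag band of 1.3 sample standard
#' deviations around the item reference time, and a flag when half or more of
#' a person's usable items fall outside the band.
#'
#' @param g Chance probability of a correct response under blind guessing,
#'   in (0, 1). 1/(number of options) for multiple choice; default 0.25.
#' @param lower_limit Lower clipping limit for CUMP thresholds, seconds >= 0.
#'   Also the sentinel value reported when an item's CUMP curve never drops
#'   to `g` (status `"no_crossing"`).
#' @param upper_limit Upper clipping limit for CUMP thresholds, seconds;
#'   `Inf` (default) leaves thresholds unclipped from above.
#' @param flag_sd_multiplier Width `k` of the aberrance band in units of the
#'   item's response-time standard deviation. Default 1.3, i.e. roughly the
#'   outer 10% of a normal distribution on each side.
#' @param flag_item_proportion Minimum proportion `p` of a person's usable
#'   items that must deviate for the person to be flagged, in (0, 1].
#'   Default 0.5.
#' @param sd_ddof Delta degrees of freedom for the item RT standard
#'   deviation: 1 (default) gives the sample SD, 0 the population SD.
#' @param center Reference time the flag band is centered on: `"mean"`
#'   (default, the item's mean RT) or `"cump"` (the item's CUMP threshold).
#'   See the methods vignette for why the mean is the default.
#' @param sided `"two"` (default) flags both unusually fast and unusually
#'   slow responses; `"fast"` counts only fast deviations, the pattern
#'   characteristic of rapid guessing.
#'
#' @return A list of class `"rt_config"`.
#' @examples
#' rt_config()
#' rt_config(g = 0.2, sided = "fast")
#' @export
rt_config <- function(g = 0.25,
                      lower_limit = 0,
                      upper_limit = Inf,
                      flag_sd_multiplier = 1.3,
                      flag_item_proportion = 0.5,
                      sd_ddof = 1,
                      center = c("mean", "cump"),
                      sided = c("two", "fast")) {
  center <- match.arg(center)
  sided <- match.arg(sided)
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g <= 0 || g >= 1) {
    abort("`g` must be a single number strictly between 0 and 1.",
          class = "rtcump_config_error")
  }
  if (!is.numeric(lower_limit) || lower_limit < 0) {
    abort("`lower_limit` must be >= 0 seconds.", class = "rtcump_config_error")
  }
  if (!is.numeric(upper_limit) || upper_limit <= lower_limit) {
    abort("`upper_limit` must exceed `lower_limit`.",
          class = "rtcump_config_error")
  }
  if (!is.numeric(flag_sd_multiplier) || flag_sd_multiplier <= 0) {
    abort("`flag_sd_multiplier` must be positive.",
          class = "rtcump_config_error")
  }
  if (!is.numeric(flag_item_proportion) || flag_item_proportion <= 0 ||
      flag_item_proportion > 1) {
    abort("`flag_item_proportion` must be in (0, 1].",
          class = "rtcump_config_error")
  }
  if (!sd_ddof %in% c(0, 1)) {
    abort("`sd_ddof` must be 0 or 1.", class = "rtcump_config_error")
  }
  structure(
    list(
      g = g,
      lower_limit = lower_limit,
      upper_limit = upper_limit,
      flag_sd_multiplier = flag_sd_multiplier,
      flag_item_proportion = flag_item_proportion,
      sd_ddof = sd_ddof,
      center = center,
      sided = sided
    ),
    class = "rt_config"
  )
}

#' @export
print.rt_config <- function(x, ...) {
  cat("<rt_config>\n")
  cat(sprintf("  chance level g ............. %.4g\n", x$g))
  cat(sprintf("  threshold limits ........... [%g, %g] s\n",
              x$lower_limit, x$upper_limit))
  cat(sprintf("  flag band .................. %g SD (%s-sided, center = %s)\n",
              x$flag_sd_multiplier, x$sided, x$center))
  cat(sprintf("  flag item proportion ....... %g\n", x$flag_item_proportion))
  cat(sprintf("  SD ddof .................... %d\n", as.integer(x$sd_ddof)))
  invisible(x)
}
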