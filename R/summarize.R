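#' Inverse-variance weighted mean of admixture dates
#'
#' Averages dates across populations with weights `1 / se^2`, the
#' minimum-variance combination of independent estimates. With
#' `use_corrected = TRUE` the bias-corrected date is used for members
#' that have one and the uncorrected date otherwise (simulation-based
#' corrections are unavailable for some sample sizes).
#'
#' @param data Tibble with columns `date` and `se` (generations), and
#'   optionally `date_corrected` (or `bias`, from which
#'   `date - bias` is computed).
#' @param use_corrected Average bias-corrected dates where available
#'   (default `FALSE`).
#' @return One-row tibble with `mean_date` (generations, unrounded),
#'   `se` (of the weighted mean) and `n_members`. Report-style output
#'   conventionally rounds `mean_date` to the nearest integer
#'   generation.
#' @examples
#' dates <- tibble::tibble(date = c(55, 45), se = c(3, 5))
#' inverse_variance_mean(dates)
#' @export
inverse_variance_mean <- function(data, use_corrected = FALSE) {
  if (!nrow(data)) abort("no member populations to average")
  stopifnot(all(c("date", "se") %in% names(data)))
  d <- data$date
  if (use_corrected) {
    corr <- if ("date_corrected" %in% names(data)) {
      data$date_corrected
    } else if ("bias" %in% names(data)) {
      data$date - data$bias
    } else {
      abort("use_corrected = TRUE needs a date_corrected or bias column")
    }
    d <- ifelse(is.na(corr), d, corr)
  }
  if (any(is.na(d) | is.na(data$se) | data$se <= 0)) {
    abort("every member needs a date and a positive se")
  }
  w <- 1 / data$se^2
  tibble(
    mean_date = sum(w * d) / sum(w),
    se = sqrt(1 / sum(w)),
    n_members = nrow(data)
  )
}

#' Convert generations to years
#'
#' @param generations Number of generations (>= 0).
#' @param years_per_generation Years per human generation (default 29).
#' @return Years.
#' @examples
#' generations_to_years(55) # ~1600 years
#' @export
generations_to_years <- function(generations, years_per_generation = 29) {
  if (any(generations < 0)) abort("generations must be >= 0")
  generations * years_per_generation
}

#' Published-style table of West Eurasian admixture estimates
#'
#' The package's bundled example table of per-population admixture
#' summaries (ancestry proportion, dated mixture event with standard
#' error, simulation bias and corrected date), with a regional grouping
#' column. Used by the worked examples and as input to
#' [inverse_variance_mean()].
#'
#' @return Tibble with columns `population`, `dataset`, `group`,
#'   `n_samples`, `ancestry_pct`, `ancestry_se_pct`, `date`, `se`,
#'   `bias`, `date_corrected`.
#' @export
west_eurasian_dates <- function() {
  path <- system.file("extdata", "west_eurasian_dates.tsv",
                      package = "admixdate", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    population = "c", dataset = "c", group = "c",
                    .default = "d"
                  ))
}

#' Regional inverse-variance date averages
#'
#' Applies [inverse_variance_mean()] within each level of a grouping
#' column.
#'
#' @param data Date table (e.g. [west_eurasian_dates()]).
#' @param group Name of the grouping column (default `"group"`).
#' @param use_corrected Passed to [inverse_variance_mean()].
#' @return Tibble with one row per group: group label, `mean_date`,
#'   `se`, `n_members`.
#' @export
regional_dates <- function(data, group = "group", use_corrected = FALSE) {
  data %>%
    filter(!is.na(.data[[group]])) %>%
    group_by(region = .data[[group]]) %>%
    dplyr::group_modify(~ inverse_variance_mean(.x, use_corrected = use_corrected)) %>%
    ungroup()
}
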