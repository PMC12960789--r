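#' Year-indexed annual series
#'
#' The universal data carrier of the package: a label- and unit-tagged numeric
#' vector with one value per consecutive calendar year, optionally stratified
#' by sex and age group. All exposures (litres of pure ethanol per capita aged
#' 15+, kilograms of tobacco per capita, per-capita health expenditure) and all
#' outcomes (cause-specific mortality rates per 100,000) travel through this
#' class.
#'
#' @param values numeric vector, one value per consecutive year, no internal
#'   gaps (`NA` is not allowed).
#' @param start_year integer calendar year of `values[1]`.
#' @param label short series name, e.g. `"alcohol"` or `"uadt"`.
#' @param unit free-text unit annotation, e.g. `"L ethanol per capita 15+"`.
#' @param sex one of `"male"`, `"female"`, `"all"`, `"n/a"`.
#' @param age_group one of `"30-49"`, `"50-69"`, `"70+"`, `"all"`, `"n/a"`.
#'
#' @return An object of class `annual_series`.
#' @examples
#' annual_series(c(9.1, 9.4, 9.8), 1960, label = "alcohol",
#'               unit = "L ethanol per capita 15+")
#' @export
annual_series <- function(values, start_year, label = "series", unit = "",
                          sex = c("n/a", "male", "female", "all"),
                          age_group = c("n/a", "30-49", "50-69", "70+", "all")) {
  sex <- match.arg(sex)
  age_group <- match.arg(age_group)
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("annual_series requires at least one value", call. = FALSE)
  if (anyNA(values))
    stop("annual_series values must not contain NA (internal gaps are an error)",
         call. = FALSE)
  start_year <- as.integer(start_year)
  if (is.na(start_year))
    stop("start_year must be an integer calendar year", call. = FALSE)
  structure(
    list(label = label, unit = unit, start_year = start_year,
         values = values, sex = sex, age_group = age_group),
    class = "annual_series"
  )
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> %s [%s] sex=%s age=%s, %d-%d (n=%d)\n",
              x$label, x$unit, x$sex, x$age_group,
              x$start_year, end_year(x), length(x$values)))
  print(stats::setNames(x$values, years(x)), ...)
  invisible(x)
}

#' @export
length.annual_series <- function(x) length(x$values)

#' Calendar years covered by a series
#' @param s an `annual_series`.
#' @return Integer vector of years, one per value.
#' @export
years <- function(s) {
  stopifnot(inherits(s, "annual_series"))
  seq.int(s$start_year, length.out = length(s$values))
}

#' @rdname years
#' @export
end_year <- function(s) {
  stopifnot(inherits(s, "annual_series"))
  s$start_year + length(s$values) - 1L
}

# internal: identity key within a dataset
series_key <- function(s) paste(s$label, s$sex, s$age_group, sep = "__")

# internal: replace values keeping metadata; optionally shift the start year
series_update <- function(s, values, shift = 0L, unit = s$unit) {
  annual_series(values, s$start_year + as.integer(shift),
                label = s$label, unit = unit, sex = s$sex,
                age_group = s$age_group)
}

#' Restrict a series to a year window
#'
#' @param s an `annual_series`.
#' @param from,to first and last calendar year to keep (inclusive); defaults
#'   keep the existing bounds.
#' @return A shorter `annual_series`.
#' @export
window_series <- function(s, from = s$start_year, to = end_year(s)) {
  stopifnot(inherits(s, "annual_series"))
  from <- max(as.integer(from), s$start_year)
  to <- min(as.integer(to), end_year(s))
  if (from > to)
    stop("requested window is empty", call. = FALSE)
  idx <- seq.int(from - s$start_year + 1L, to - s$start_year + 1L)
  series_update(s, s$values[idx], shift = from - s$start_year)
}

#' Align two series on their common year range
#'
#' Trims both inputs to the intersection of their year ranges; values are not
#' modified. The mortality registries start decades after the consumption
#' series, so nearly every exposure/outcome pair needs this before modelling.
#'
#' @param a,b `annual_series` objects with intersecting year ranges.
#' @return A list of the two trimmed series (same order as the inputs), both
#'   with identical `start_year` and length.
#' @examples
#' a <- annual_series(1:20, 1950); b <- annual_series(1:10, 1960)
#' al <- align(a, b)
#' al[[1]]$start_year  # 1960
#' @export
align <- function(a, b) {
  stopifnot(inherits(a, "annual_series"), inherits(b, "annual_series"))
  from <- max(a$start_year, b$start_year)
  to <- min(end_year(a), end_year(b))
  if (from > to)
    stop(sprintf("year ranges do not overlap (%d-%d vs %d-%d)",
                 a$start_year, end_year(a), b$start_year, end_year(b)),
         call. = FALSE)
  list(window_series(a, from, to), window_series(b, from, to))
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = years(x), value = x$values, label = x$label,
              sex = x$sex, age_group = x$age_group,
              stringsAsFactors = FALSE)
}
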