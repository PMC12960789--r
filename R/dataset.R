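#' Study dataset: a collection of annual series
#'
#' Bundles the exposure and outcome series of one study together with free-form
#' metadata. Series are keyed by `label__sex__age_group`, which must be unique.
#'
#' @param series list of [annual_series()] objects.
#' @param metadata named list of free-form text notes (sources,
#'   standardisation flags, ...).
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(series, metadata = list()) {
  stopifnot(is.list(series), length(series) > 0L)
  for (s in series)
    if (!inherits(s, "annual_series"))
      stop("all elements of `series` must be annual_series objects", call. = FALSE)
  keys <- vapply(series, series_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate series identity: ", keys[duplicated(keys)][1], call. = FALSE)
  names(series) <- keys
  structure(list(series = series, metadata = metadata), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d series\n", length(x$series)))
  for (s in x$series)
    cat(sprintf("  %-40s %d-%d (n=%d) [%s]\n", series_key(s),
                s$start_year, end_year(s), length(s$values), s$unit))
  invisible(x)
}

#' Look up one series by identity
#'
#' @param ds a `study_dataset`.
#' @param label series label.
#' @param sex,age_group stratum selectors.
#' @return The matching [annual_series()]; error if absent.
#' @export
get_series <- function(ds, label, sex = "n/a", age_group = "n/a") {
  stopifnot(inherits(ds, "study_dataset"))
  key <- paste(label, sex, age_group, sep = "__")
  s <- ds$series[[key]]
  if (is.null(s))
    stop("no series '", key, "' in dataset", call. = FALSE)
  s
}

# internal: parse "label__sex__age" column headers; bare labels are
# whole-population series
parse_series_header <- function(name) {
  parts <- strsplit(name, "__", fixed = TRUE)[[1]]
  sexes <- c("male", "female", "all", "n/a")
  ages <- c("30-49", "50-69", "70+", "all", "n/a")
  lab <- parts[1]
  sex <- if (length(parts) >= 2) parts[2] else "all"
  age <- if (length(parts) >= 3) parts[3] else "all"
  if (!sex %in% sexes) stop("unknown sex '", sex, "' in column '", name, "'",
                            call. = FALSE)
  if (!age %in% ages) stop("unknown age group '", age, "' in column '", name,
                           "'", call. = FALSE)
  list(label = lab, sex = sex, age_group = age)
}

#' Read a study dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with one header row, a `year` column
#' of consecutive (after sorting) integer years and one column per series.
#' Column names carry the series identity as `label__sex__age` (bare labels
#' are read as whole-population series). Missing cells at the top or bottom of
#' a column simply shorten that series — the registries start in different
#' years — but a missing cell with data on both sides is an internal gap and a
#' hard error: silently interpolating would corrupt the differenced model.
#'
#' @param path CSV file path.
#' @param units optional named character vector mapping series label to unit
#'   text.
#' @param metadata optional named list stored on the dataset.
#' @return A validated [study_dataset()].
#' @export
read_dataset <- function(path, units = character(), metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"year" %in% names(df))
    stop("dataset must have a 'year' column", call. = FALSE)
  yr <- df$year
  if (anyNA(suppressWarnings(as.integer(yr))) ||
      any(as.numeric(yr) != as.integer(yr)))
    stop("malformed year column: non-integer entries", call. = FALSE)
  yr <- as.integer(yr)
  if (anyDuplicated(yr)) stop("malformed year column: duplicate years",
                              call. = FALSE)
  o <- order(yr)
  yr <- yr[o]
  if (any(diff(yr) != 1L))
    stop("malformed year column: years are not consecutive", call. = FALSE)
  series <- list()
  for (col in setdiff(names(df), "year")) {
    v <- as.numeric(df[[col]])[o]
    present <- !is.na(v)
    if (!any(present)) next
    rng <- range(which(present))
    if (any(!present[rng[1]:rng[2]]))
      stop("internal gap in series '", col, "' at year ",
           yr[rng[1]:rng[2]][!present[rng[1]:rng[2]]][1], call. = FALSE)
    id <- parse_series_header(col)
    series[[length(series) + 1L]] <- annual_series(
      v[rng[1]:rng[2]], yr[rng[1]],
      label = id$label,
      unit = if (id$label %in% names(units)) units[[id$label]] else "",
      sex = id$sex, age_group = id$age_group)
  }
  if (length(series) == 0L) stop("no data columns in ", path, call. = FALSE)
  study_dataset(series, metadata)
}

#' Write a study dataset to CSV
#'
#' Inverse of [read_dataset()]: one row per year over the union of all series
#' ranges, empty cells where a series does not cover a year. A write/read
#' round trip reproduces every year/value pair.
#'
#' @param ds a `study_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "study_dataset"))
  yrs <- seq.int(min(vapply(ds$series, `[[`, integer(1), "start_year")),
                 max(vapply(ds$series, end_year, integer(1))))
  out <- data.frame(year = yrs)
  for (s in ds$series) {
    col <- rep(NA_real_, length(yrs))
    col[match(years(s), yrs)] <- s$values
    out[[series_key(s)]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write coefficient and attributable-fraction report tables
#'
#' Emits the study's result tables: one coefficient row per fitted stratum
#' (estimate, 95% CI, p-value, ARIMA order, Q(10), R-squared) and, when
#' attributable-fraction results are supplied, an AAF table. Rows are ordered
#' by outcome label, then sex, then age group so repeated runs are
#' byte-identical. Both a CSV and an aligned plain-text rendering are written.
#'
#' @param fits named list (or list with `stratum` fields) of `arimax_fit`
#'   objects; see [fit_arimax()]. Each element must carry `stratum`, a list
#'   with `label`, `sex`, `age_group`.
#' @param aafs optional list of `aaf_result` objects, see [compute_aaf()].
#' @param path output stem; `<path>.csv` and `<path>.txt` are written, and
#'   `<path>_aaf.csv` when `aafs` is nonempty.
#' @return Data frame of the coefficient table, invisibly.
#' @export
write_report <- function(fits, aafs = list(), path) {
  if (length(fits) == 0L) stop("no results to report", call. = FALSE)
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "arimax_fit"))
    st <- f$stratum
    if (is.null(st)) st <- list(label = "outcome", sex = "n/a", age_group = "n/a")
    ci <- f$ci95[["alcohol"]]
    data.frame(outcome = st$label, sex = st$sex, age_group = st$age_group,
               estimate = f$beta_hat, ci_low = ci[1], ci_high = ci[2],
               p_value = f$p_values[["alcohol"]],
               arima = sprintf("%d,%d,%d", f$spec$p, f$spec$d, f$spec$q),
               q10_p = f$q10_p, r_squared = f$r_squared,
               n_obs = f$n_obs, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$outcome, tab$sex, tab$age_group), , drop = FALSE]
  rownames(tab) <- NULL
  utils::write.csv(format_report_numbers(tab), paste0(path, ".csv"),
                   row.names = FALSE)
  txt <- utils::capture.output(print(format_report_numbers(tab),
                                     row.names = FALSE))
  writeLines(txt, paste0(path, ".txt"))
  if (length(aafs) > 0L) {
    arows <- lapply(aafs, function(a) {
      stopifnot(inherits(a, "aaf_result"))
      data.frame(outcome = a$outcome, sex = a$sex,
                 aacp_litres = a$aacp_sex,
                 effect_pct_per_litre = a$effect_percent_per_litre,
                 aaf_percent = a$aaf_percent, stringsAsFactors = FALSE)
    })
    atab <- do.call(rbind, arows)
    atab <- atab[order(atab$outcome, atab$sex), , drop = FALSE]
    rownames(atab) <- NULL
    utils::write.csv(atab, paste0(path, "_aaf.csv"), row.names = FALSE)
  }
  invisible(tab)
}

# internal: round numeric report columns the way the tables print them
format_report_numbers <- function(tab) {
  for (col in c("estimate", "ci_low", "ci_high"))
    tab[[col]] <- round(tab[[col]], 3)
  for (col in c("p_value", "q10_p", "r_squared"))
    tab[[col]] <- round(tab[[col]], 3)
  tab
}
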