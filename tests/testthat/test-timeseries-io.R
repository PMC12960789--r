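test_that("annual_series validates its invariants", {
  s <- annual_series(c(1, 2, 3), 2000, label = "x")
  expect_identical(years(s), 2000:2002)
  expect_identical(end_year(s), 2002L)
  expect_error(annual_series(c(1, NA, 3), 2000), "NA")
  expect_error(annual_series(numeric(0), 2000), "at least one")
  expect_error(annual_series(1:3, 2000, sex = "other"))
})

test_that("align trims to the common year range and leaves values untouched", {
  a <- annual_series(seq_len(109), 1910, label = "alcohol")
  b <- annual_series(seq_len(69), 1950, label = "mortality")
  al <- align(a, b)
  expect_identical(al[[1]]$start_year, 1950L)
  expect_identical(al[[2]]$start_year, 1950L)
  expect_identical(length(al[[1]]$values), length(al[[2]]$values))
  expect_identical(al[[1]]$values, a$values[41:109])
  expect_identical(al[[2]]$values, b$values)

  # identity
  al2 <- align(a, a)
  expect_identical(al2[[1]]$values, a$values)

  # idempotent and commutative in the returned range
  al3 <- align(al[[1]], al[[2]])
  expect_identical(al3[[1]]$values, al[[1]]$values)
  rev <- align(b, a)
  expect_identical(rev[[1]]$start_year, al[[1]]$start_year)
  expect_identical(rev[[2]]$values, al[[1]]$values)

  expect_error(align(annual_series(1:11, 1900), annual_series(1:11, 1950)),
               "overlap")
})

test_that("read_dataset parses well-formed files and differing start years", {
  path <- write_fixture_csv(data.frame(
    year = 2000:2004, alcohol = c(9, 9.5, 10, 10.2, 10.1),
    uadt__male__all = c(5, 5.1, 5.3, 5.2, 5.0)))
  ds <- read_dataset(path)
  expect_length(ds$series, 2)
  expect_identical(length(get_series(ds, "alcohol", "all", "all")$values), 5L)
  expect_identical(get_series(ds, "uadt", "male", "all")$sex, "male")

  # series starting in different years: edge NAs shorten, never error
  path2 <- write_fixture_csv(data.frame(
    year = 1960:1979,
    alcohol = rnorm(20, 10),
    liver__male__all = c(rep(NA, 8), rnorm(12, 2))))
  ds2 <- read_dataset(path2)
  expect_identical(get_series(ds2, "alcohol", "all", "all")$start_year, 1960L)
  expect_identical(get_series(ds2, "liver", "male", "all")$start_year, 1968L)
})

test_that("read_dataset rejects malformed files", {
  gap <- data.frame(year = 2000:2004, x = c(1, 2, NA, 4, 5))
  expect_error(read_dataset(write_fixture_csv(gap)), "internal gap.*2002")

  noyear <- data.frame(y = 2000:2004, x = 1:5)
  expect_error(read_dataset(write_fixture_csv(noyear)), "year")

  skipyear <- data.frame(year = c(2000, 2001, 2003, 2004), x = 1:4)
  expect_error(read_dataset(write_fixture_csv(skipyear)), "consecutive")

  expect_error(read_dataset(tempfile("missing-")), "not found")

  expect_error(
    study_dataset(list(annual_series(1:5, 2000, label = "a"),
                       annual_series(1:5, 2001, label = "a"))),
    "duplicate")
})

test_that("write/read round trip reproduces every year/value pair", {
  set.seed(17)
  ds <- study_dataset(list(
    annual_series(round(runif(30, 5, 15), 6), 1950, label = "alcohol",
                  sex = "all", age_group = "n/a"),
    annual_series(round(runif(20, 1, 9), 6), 1960, label = "uadt",
                  sex = "female", age_group = "50-69")))
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  for (key in names(ds$series)) {
    expect_identical(back$series[[key]]$start_year, ds$series[[key]]$start_year)
    expect_equal(back$series[[key]]$values, ds$series[[key]]$values)
  }
})

test_that("write_report emits ordered coefficient rows and an AAF table", {
  f1 <- fixture_fit(seed = 5, label = "uadt", sex = "male")
  f2 <- fixture_fit(seed = 6, label = "uadt", sex = "female")
  aaf <- compute_aaf(12.6, 3.6, sex = "male", outcome = "uadt")
  stem <- tempfile("report-")
  tab <- write_report(list(f2, f1), list(aaf), stem)  # deliberately unordered
  expect_true(file.exists(paste0(stem, ".csv")))
  expect_true(file.exists(paste0(stem, ".txt")))
  expect_true(file.exists(paste0(stem, "_aaf.csv")))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$sex, c("female", "male"))  # stable ordering
  got <- utils::read.csv(paste0(stem, ".csv"))
  expect_identical(got$arima[1], "0,1,1")
  expect_equal(got$estimate[1], round(f2$beta_hat, 3))

  expect_error(write_report(list(), list(), stem), "no results")
})
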