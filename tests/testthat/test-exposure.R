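# Exposure engine: burn-in behaviour, prescription thresholds, window
# lapses, and equivalence with a brute-force rescan oracle.

simple_links <- function(fams = "F1", parents = "P1") {
  data.table::data.table(family_id = fams, parent_id = parents,
                         child_id = NA_character_,
                         link_start = as.Date(NA), link_end = as.Date(NA))
}

tl_of <- function(diag = NULL, rx = NULL, links = simple_links(),
                  start = "1997-01-01", end = "2018-12-31") {
  d <- if (is.null(diag))
    data.frame(person_id = character(), date = as.Date(character()),
               code = character()) else diag
  p <- if (is.null(rx))
    data.frame(person_id = character(), date = as.Date(character()),
               atc_code = character()) else rx
  build_exposure_timeline(default_taxonomy(), d, p, links, start, end)
}

test_that("a burn-in diagnosis makes the family exposed at study entry", {
  tl <- tl_of(diag = data.frame(person_id = "P1", date = as.Date("1995-06-01"),
                                code = "I10"))
  expect_true(exposure_at(tl, "F1", "Hypertension", as.Date("1997-01-01")))
  # and, being an ever window, for the remainder of the study
  expect_true(exposure_at(tl, "F1", "Hypertension", as.Date("2018-12-01")))
})

test_that("ever windows are monotone; earlier months are unexposed", {
  tl <- tl_of(diag = data.frame(person_id = "P1", date = as.Date("2005-03-10"),
                                code = "G40"))
  months <- seq(as.Date("1997-01-01"), as.Date("2018-12-01"), by = "month")
  state <- exposure_at(tl, rep("F1", length(months)), "Epilepsy", months)
  expect_false(any(state[months < as.Date("2005-04-01")]))
  expect_true(all(state[months >= as.Date("2005-04-01")]))
  expect_true(all(diff(state) >= 0))  # monotone non-decreasing
})

test_that("prescription thresholds: 4 analgesics qualify, 3 do not", {
  mk <- function(n) data.frame(
    person_id = "P1",
    date = as.Date("2005-01-15") + seq_len(n) * 20,
    atc_code = "N02BE")
  at <- as.Date("2005-12-01")
  expect_false(exposure_at(tl_of(rx = mk(3)), "F1", "Painful condition", at))
  expect_true(exposure_at(tl_of(rx = mk(4)), "F1", "Painful condition", at))
})

test_that("a single statin prescription does not qualify dyslipidemia", {
  one <- data.frame(person_id = "P1", date = as.Date("2005-05-01"),
                    atc_code = "C10AA")
  two <- rbind(one, data.frame(person_id = "P1", date = as.Date("2005-08-01"),
                               atc_code = "C10AA"))
  at <- as.Date("2005-12-01")
  expect_false(exposure_at(tl_of(rx = one), "F1", "Dyslipidemia", at))
  expect_true(exposure_at(tl_of(rx = two), "F1", "Dyslipidemia", at))
})

test_that("last_2y exposure lapses after the window passes", {
  tl <- tl_of(diag = data.frame(person_id = "P1", date = as.Date("2003-02-10"),
                                code = "E78"))
  expect_true(exposure_at(tl, "F1", "Dyslipidemia", as.Date("2003-06-01")))
  # 25 months later the window has lapsed
  expect_false(exposure_at(tl, "F1", "Dyslipidemia", as.Date("2005-04-01")))
  # oracle agreement at the boundary months
  months <- seq(as.Date("2003-01-01"), as.Date("2006-01-01"), by = "month")
  got <- exposure_at(tl, rep("F1", length(months)), "Dyslipidemia", months)
  want <- vapply(months, function(mm)
    oracle_exposed(mm, "last_2y", 0, as.Date("2003-02-10"), NULL,
                   as.Date("1994-01-01")), logical(1))
  expect_identical(got, want)
})

test_that("family exposure is the OR over linked parents", {
  links2 <- simple_links(fams = c("F1", "F1"), parents = c("P1", "P2"))
  d <- data.frame(person_id = "P1", date = as.Date("2000-05-01"), code = "I48")
  tl1 <- tl_of(diag = d)
  tl2 <- tl_of(diag = d, links = links2)  # second parent with no events
  months <- seq(as.Date("1997-01-01"), as.Date("2018-12-01"), by = "month")
  s1 <- exposure_at(tl1, rep("F1", length(months)), "Atrial fibrillation", months)
  s2 <- exposure_at(tl2, rep("F1", length(months)), "Atrial fibrillation", months)
  expect_identical(s1, s2)
})

test_that("guardianship link bounds clamp a parent's contribution", {
  links <- data.table::data.table(
    family_id = "F1", parent_id = "P1", child_id = NA_character_,
    link_start = as.Date(NA), link_end = as.Date("2005-06-30"))
  tl <- build_exposure_timeline(
    default_taxonomy(),
    data.frame(person_id = "P1", date = as.Date("2000-01-10"), code = "I10"),
    data.frame(person_id = character(), date = as.Date(character()),
               atc_code = character()),
    links, "1997-01-01", "2018-12-31")
  expect_true(exposure_at(tl, "F1", "Hypertension", as.Date("2005-06-01")))
  expect_false(exposure_at(tl, "F1", "Hypertension", as.Date("2005-08-01")))
})

test_that("events before the read-in start warn and are ignored", {
  expect_warning(
    tl <- tl_of(diag = data.frame(person_id = "P1",
                                  date = as.Date("1990-01-01"), code = "I10")),
    "read-in")
  expect_false(exposure_at(tl, "F1", "Hypertension", as.Date("1997-01-01")))
})

test_that("exposure_at rejects unknown families and categories", {
  tl <- tl_of()
  expect_error(exposure_at(tl, "F1", "Nonsense", as.Date("2000-01-01")),
               "unknown category")
  expect_error(exposure_at(tl, "F9", "Hypertension", as.Date("2000-01-01")),
               "unknown family")
})

test_that("timeline equals the brute-force rescan oracle on random streams", {
  set.seed(31)
  tax <- default_taxonomy()
  cats <- tax$categories
  start <- as.Date("1997-01-01"); end <- as.Date("2006-12-31")
  read_in <- as.Date("1994-01-01")
  months <- seq(start, as.Date("2006-12-01"), by = "month")
  for (rep in 1:5) {
    # one parent, random codes across streams
    nd <- sample(5:15, 1)
    dcode <- sample(c("I10", "E78", "C50", "G43", "R10", "Q80", "S72"),
                    nd, TRUE)
    ddate <- read_in + sample.int(as.integer(end - read_in), nd)
    nr <- sample(3:10, 1)
    rcode <- sample(c("N02BE", "C10AA", "H03"), nr, TRUE)
    rdate <- read_in + sample.int(as.integer(end - read_in), nr)
    tl <- build_exposure_timeline(
      tax, data.frame(person_id = "P1", date = ddate, code = dcode),
      data.frame(person_id = "P1", date = rdate, atc_code = rcode),
      simple_links(), start, end)
    for (cat_name in c("Hypertension", "Dyslipidemia", "Cancer", "Migraine",
                       "Unspecific symptoms, two years back",
                       "Unspecific symptoms, ever", "Other",
                       "Painful condition", "Thyroid disorder")) {
      row <- cats[cats$category == cat_name, ]
      stream <- switch(cat_name,
                       `Unspecific symptoms, two years back` = "UNSPECIFIC",
                       `Unspecific symptoms, ever` = "UNSPECIFIC",
                       Other = "OTHER", cat_name)
      dmatch <- classify_code(tax, dcode, "icd") == stream
      rmatch <- !is.na(classify_code(tax, rcode, "atc")) &
        classify_code(tax, rcode, "atc") == cat_name
      got <- exposure_at(tl, rep("F1", length(months)), cat_name, months)
      want <- vapply(months, function(mm)
        oracle_exposed(mm, row$window, row$min_rx,
                       ddate[dmatch], rdate[rmatch], read_in), logical(1))
      expect_identical(got, want)
    }
  }
})

test_that("timeline export writes the exposed long format", {
  tl <- tl_of(diag = data.frame(person_id = "P1",
                                date = as.Date("2000-01-10"), code = "I10"))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_timeline(tl, f)
  x <- utils::read.delim(f)
  expect_true(all(c("family_id", "category", "month", "exposed") %in% names(x)))
  expect_true(all(x$exposed))
  expect_true("Hypertension" %in% x$category)
})
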