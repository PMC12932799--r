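toy_record <- function(scientificName = "Apis mellifera",
                       decimalLatitude = 0.5, decimalLongitude = 0.5,
                       countryCode = "FR",
                       basisOfRecord = "PRESERVED_SPECIMEN",
                       occurrenceStatus = "present", license = "CC0",
                       year = 2000L, speciesKey = scientificName) {
  tibble::tibble(
    scientificName = scientificName, decimalLatitude = decimalLatitude,
    decimalLongitude = decimalLongitude, countryCode = countryCode,
    basisOfRecord = basisOfRecord, occurrenceStatus = occurrenceStatus,
    license = license, year = year, speciesKey = speciesKey
  )
}

toy_checklist <- tibble::tibble(
  species = c("Apis mellifera", "Apis mellifera"),
  countryCode = c("FR", "DE")
)
# FR occupies longitude [0, 1), DE [1, 2)
toy_resolver <- rect_country_resolver(c("FR", "DE"))

test_that("single records trip exactly the rules they violate", {
  expect_identical(
    flag_record(toy_record(), toy_checklist, toy_resolver), character(0))
  expect_identical(
    flag_record(toy_record(occurrenceStatus = "absent"), toy_checklist,
                toy_resolver),
    "ABSENCE")
  expect_identical(
    flag_record(toy_record(scientificName = "Apis", speciesKey = NA),
                toy_checklist, toy_resolver),
    "INVALID_BINOMIAL")
  # coordinates resolve to FR but the record claims DE, and the species
  # is on neither checklist
  rec <- toy_record(scientificName = "Bombus terrestris",
                    countryCode = "DE", decimalLongitude = 0.4)
  expect_setequal(flag_record(rec, toy_checklist, toy_resolver),
                  c("COUNTRY_MISMATCH", "OFF_CHECKLIST"))
})

test_that("missing fields retain conservatively", {
  # no coordinates: the mismatch rule cannot be evaluated
  rec <- toy_record(decimalLatitude = NA, decimalLongitude = NA)
  expect_identical(flag_record(rec, toy_checklist, toy_resolver),
                   character(0))
  # missing license and basis do not flag; missing status is not absence
  rec <- toy_record(license = NA, basisOfRecord = NA,
                    occurrenceStatus = NA)
  expect_identical(flag_record(rec, toy_checklist, toy_resolver),
                   character(0))
  # coordinates the resolver cannot place do not flag
  rec <- toy_record(decimalLatitude = 45, decimalLongitude = 100)
  expect_identical(flag_record(rec, toy_checklist, toy_resolver),
                   character(0))
})

test_that("malformed coordinates error on flagging, are reported on cleaning", {
  bad <- toy_record(decimalLatitude = 95)
  expect_error(flag_record(bad, toy_checklist, toy_resolver), "malformed")
  recs <- dplyr::bind_rows(toy_record(), bad)
  expect_warning(out <- clean_dataset(recs, toy_checklist, toy_resolver),
                 "malformed")
  expect_equal(out$report$malformed, 1)
  expect_equal(out$report$retained, 1)
  expect_equal(out$report$input, 2)
})

test_that("cleaning removes exactly the planted defects, idempotently", {
  fx <- make_dirty_fixture(n = 400, rate = 0.03)
  out <- clean_dataset(fx$occurrences, fx$checklist, fx$resolver)

  truth_clean <- lengths(fx$occurrences$.defects) == 0
  expect_equal(out$report$retained, sum(truth_clean))
  expect_identical(out$records$.defects,
                   fx$occurrences$.defects[truth_clean])

  # per-rule tallies match the planted labels; union removal means the
  # tallies can sum to more than the removed count
  planted <- table(factor(unlist(fx$occurrences$.defects),
                          levels = cleaning_rules()))
  expect_equal(as.vector(out$report$per_rule), as.vector(planted))
  expect_gte(sum(out$report$per_rule), out$report$flagged)

  again <- clean_dataset(out$records, fx$checklist, fx$resolver)
  expect_identical(again$records, out$records)
  expect_equal(again$report$retained, again$report$input)
})

test_that("adding a record never evicts another (monotonicity)", {
  fx <- make_dirty_fixture(n = 60, rate = 0.05)
  base <- clean_dataset(fx$occurrences[-1, ], fx$checklist, fx$resolver)
  full <- clean_dataset(fx$occurrences, fx$checklist, fx$resolver)
  key <- function(d) paste(d$scientificName, d$decimalLatitude,
                           d$decimalLongitude, d$year)
  expect_true(all(key(base$records) %in% key(full$records)))
})

test_that("disabling one rule re-admits exactly its sole-flag records", {
  fx <- make_dirty_fixture(n = 500, rate = 0.04)
  all_rules <- clean_dataset(fx$occurrences, fx$checklist, fx$resolver)
  cfg <- cleaning_config(rules = setdiff(cleaning_rules(), "ABSENCE"))
  no_absence <- clean_dataset(fx$occurrences, fx$checklist, fx$resolver,
                              config = cfg)
  only_absence <- vapply(fx$occurrences$.defects,
                         function(d) identical(d, "ABSENCE"), logical(1))
  expect_equal(no_absence$report$retained,
               all_rules$report$retained + sum(only_absence))
})

test_that("flag summaries reconcile and round-trip through JSON", {
  empty <- clean_dataset(toy_record()[0, ], toy_checklist, toy_resolver)
  expect_equal(summarize_flags(empty$report, json = FALSE)$removed, 0)

  fx <- make_dirty_fixture(n = 100, rate = 0.05)
  rep <- clean_dataset(fx$occurrences, fx$checklist, fx$resolver)$report
  js <- summarize_flags(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$removed, rep$input - rep$retained)
  expect_equal(parsed$retained + parsed$flagged + parsed$malformed,
               parsed$input)
  expect_equal(unlist(parsed$per_rule), rep$per_rule)
  expect_identical(as.character(js),
                   as.character(summarize_flags(rep)))
})
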