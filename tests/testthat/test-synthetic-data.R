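test_that("communities are normalised, labelled, and seed-reproducible", {
  com1 <- generate_community(100, seed = 1)
  expect_equal(sum(com1$species$p), 1, tolerance = 1e-9)
  expect_true(all(com1$species$p > 0))
  expect_equal(nrow(com1$species), 100)
  expect_true(all(com1$species$region %in% com1$regions))

  com2 <- generate_community(100, seed = 1)
  expect_identical(com1, com2)

  single <- generate_community(1, seed = 5)
  expect_equal(single$species$p, 1)

  expect_error(generate_community(0), "positive integer")
  expect_error(generate_community(10, sdlog = -1), "invalid")
})

test_that("power-law communities have the requested rank-abundance slope", {
  com <- generate_community(500, shape = "powerlaw", exponent = 1.37,
                            seed = 2)
  p <- sort(com$species$p, decreasing = TRUE)
  slope <- unname(coef(lm(log(p) ~ log(seq_along(p))))[2])
  expect_lt(abs(slope - (-1.37)), 0.15)
})

test_that("planted contamination drives retention exactly", {
  com <- generate_community(30, seed = 1)
  chk <- generate_checklist(com, seed = 2)
  res <- community_resolver(com)

  clean <- sample_occurrences(com, 200, contamination_spec(), seed = 3)
  out <- clean_dataset(clean, chk, res)
  expect_equal(out$report$retained, 200)

  all_absent <- sample_occurrences(com, 50,
                                   contamination_spec(rate_absence = 1),
                                   seed = 4)
  out <- clean_dataset(all_absent, chk, res)
  expect_equal(out$report$retained, 0)

  spec <- contamination_spec(0.02, 0.02, 0.02, 0.02, 0.02, 0.02)
  occ <- sample_occurrences(com, 1000, spec, seed = 7)
  planted_dirty <- sum(lengths(occ$.defects) > 0)
  out <- clean_dataset(occ, chk, res)
  expect_equal(out$report$retained, 1000 - planted_dirty)
})

test_that("occurrence sampling honours exclusions and reproduces by seed", {
  com <- generate_community(40, seed = 1)
  chk <- generate_checklist(com, zero_occurrence_fraction = 0.25, seed = 2)
  zero <- attr(chk, "zero_occurrence_species")
  expect_length(zero, 10)
  expect_equal(sum(chk$zeroOccurrence), 10)

  occ <- sample_occurrences(com, 500, seed = 3, exclude_species = zero)
  expect_false(any(occ$scientificName %in% zero))
  occ2 <- sample_occurrences(com, 500, seed = 3, exclude_species = zero)
  expect_identical(occ, occ2)
  expect_error(sample_occurrences(com, 10,
                                  exclude_species = com$species$species),
               "sampleable")
})

test_that("synthetic taxonomies plant verifiable orthographic variants", {
  tax <- generate_taxonomy(15, synonyms_per_species = 2,
                           variant_rate = 0.6, seed = 3)
  syn <- tax[tax$status == "synonym", ]
  expect_gt(nrow(syn), 0)

  # variants share acceptedId and authorYear with their parent and sit
  # within two edits of it after normalisation
  variants <- syn[duplicated(syn$clusterTruth), ]
  for (i in seq_len(nrow(variants))) {
    parent <- syn[syn$taxonId == variants$clusterTruth[i], ]
    expect_equal(variants$acceptedId[i], parent$acceptedId)
    expect_equal(variants$authorYear[i], parent$authorYear)
    d <- osa_distance(
      tolower(normalize_epithet(variants$name[i])$name),
      tolower(normalize_epithet(parent$name)$name)
    )
    expect_lte(d, 2)
  }

  expect_identical(tax, generate_taxonomy(15, synonyms_per_species = 2,
                                          variant_rate = 0.6, seed = 3))

  novar <- generate_taxonomy(20, synonyms_per_species = 1.5,
                             variant_rate = 0, seed = 4)
  dd <- dedup_synonyms(novar)
  expect_true(all(dd$kept))

  expect_error(generate_taxonomy(10, variant_rate = 1.5), "variant_rate")
  expect_error(generate_taxonomy(10, year_range = c(2000, 1900)),
               "year_range")
})

test_that("literature size tables follow the generating power law", {
  expect_true(all(generate_literature_sizes(1.37, 200, cap = 1,
                                            seed = 1)$nSpecimens == 1))

  n <- 20000
  lit <- generate_literature_sizes(1.37, n, cap = 100, seed = 2)
  p1 <- 1 / sum((1:100)^(-1.37))
  obs <- mean(lit$nSpecimens == 1)
  mcse <- sqrt(p1 * (1 - p1) / n)
  expect_lt(abs(obs - p1), 3 * mcse)

  expect_error(generate_literature_sizes(1.37, 10, cap = 0), "cap")
  expect_error(generate_literature_sizes(-1, 10, cap = 5), "exponent")
})

test_that("occurrence files round-trip through CSV losslessly", {
  com <- generate_community(20, seed = 1)
  occ <- sample_occurrences(com, 80,
                            contamination_spec(rate_absence = 0.1),
                            seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  truth <- withr::local_tempfile(fileext = ".json")
  write_occurrences(occ, csv, truth_path = truth)
  back <- read_occurrences(csv)
  expect_equal(as.data.frame(back),
               as.data.frame(occ[, setdiff(names(occ), ".defects")]))
  sidecar <- jsonlite::read_json(truth, simplifyVector = TRUE)
  expect_equal(lengths(sidecar$defects), lengths(occ$.defects))
})
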