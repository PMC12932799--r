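# Synthetic-data generators: communities with known richness, dirty
# occurrence files with planted defects, taxonomies with planted
# orthographic variants, checklists with guaranteed zero-occurrence
# species, and literature sample-size tables from a known power law.
# Every generator keeps its ground truth alongside the output so
# downstream stages can be tested against exact oracles.

SYNTH_GENUS <- "Simulapis"

# deterministic base-26 epithet for species index i ("aaaa", "aaab", ...)
epithet_code <- function(i, width = 4L) {
  vapply(i, function(k) {
    k <- k - 1L
    ch <- character(width)
    for (j in seq(width, 1L)) {
      ch[j] <- letters[k %% 26L + 1L]
      k <- k %/% 26L
    }
    paste(ch, collapse = "")
  }, character(1))
}

#' Generate a synthetic community with known true richness
#'
#' Creates a community of `s_true` species with relative abundances drawn
#' from either a lognormal species-abundance distribution (the default,
#' `meanlog = 0`, `sdlog = 1.5`, which yields realistic singleton- and
#' doubleton-rich samples) or a deterministic power-law rank-abundance
#' curve. Each species is assigned to exactly one synthetic region
#' (a toy two-letter country code); regions stand in for countries without
#' any polygon geometry.
#'
#' @param s_true Number of species in the community (positive integer).
#' @param shape `"lognormal"` or `"powerlaw"`.
#' @param meanlog,sdlog Lognormal parameters (used when
#'   `shape = "lognormal"`).
#' @param exponent Rank-abundance exponent; species of rank r gets
#'   probability proportional to `r^-exponent` (used when
#'   `shape = "powerlaw"`).
#' @param regions Character vector of region (country) codes species are
#'   assigned to uniformly at random.
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @return An object of class `synthetic_community`: a list with
#'   `species` (a tibble with columns `species`, `p`, `region`),
#'   `true_richness`, `regions`, and `shape`.
#' @examples
#' com <- generate_community(50, seed = 1)
#' com$true_richness
#' @export
generate_community <- function(s_true,
                               shape = c("lognormal", "powerlaw"),
                               meanlog = 0, sdlog = 1.5, exponent = 1.37,
                               regions = c("AA", "AB", "AC"),
                               seed = 1) {
  shape <- match.arg(shape)
  if (!is.numeric(s_true) || length(s_true) != 1 || s_true < 1 ||
      s_true != round(s_true)) {
    stop("`s_true` must be a positive integer")
  }
  if (shape == "lognormal" && (!is.finite(sdlog) || sdlog < 0)) {
    stop("invalid lognormal parameters")
  }
  if (shape == "powerlaw" && (!is.finite(exponent) || exponent <= 0)) {
    stop("invalid power-law exponent")
  }
  if (length(regions) < 1) stop("at least one region is required")
  s_true <- as.integer(s_true)

  with_seed(seed, {
    w <- switch(shape,
      lognormal = rlnorm(s_true, meanlog = meanlog, sdlog = sdlog),
      powerlaw  = seq_len(s_true)^(-exponent)
    )
    p <- w / sum(w)
    reg <- sample(regions, s_true, replace = TRUE)
    structure(
      list(
        species = tibble::tibble(
          species = paste(SYNTH_GENUS, epithet_code(seq_len(s_true))),
          p = p,
          region = reg
        ),
        true_richness = s_true,
        regions = regions,
        shape = shape
      ),
      class = "synthetic_community"
    )
  })
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("Synthetic community:", x$true_richness, "species,",
      length(x$regions), "regions,", x$shape, "abundances\n")
  invisible(x)
}

#' Contamination rates for planted occurrence-record defects
#'
#' One rate per cleaning rule, each the independent per-record probability
#' of planting that defect. A record may carry several defects (union
#' semantics, matching removal on any flag).
#'
#' @param rate_invalid_binomial,rate_bad_basis,rate_country_mismatch,rate_absence,rate_bad_license,rate_off_checklist
#'   Fractions in \[0, 1\].
#' @return A `contamination_spec` object (named list of rates).
#' @examples
#' contamination_spec(rate_absence = 0.05)
#' @export
contamination_spec <- function(rate_invalid_binomial = 0,
                               rate_bad_basis = 0,
                               rate_country_mismatch = 0,
                               rate_absence = 0,
                               rate_bad_license = 0,
                               rate_off_checklist = 0) {
  rates <- c(
    INVALID_BINOMIAL = rate_invalid_binomial,
    BAD_BASIS = rate_bad_basis,
    COUNTRY_MISMATCH = rate_country_mismatch,
    ABSENCE = rate_absence,
    BAD_LICENSE = rate_bad_license,
    OFF_CHECKLIST = rate_off_checklist
  )
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("all contamination rates must lie in [0, 1]")
  }
  structure(as.list(rates), class = "contamination_spec")
}

# longitude band [idx - 1, idx) per country code; latitude in [0, 1]
region_codes <- function(community) c(community$regions, "ZZ")

#' Toy rectangular coordinate-to-country resolver
#'
#' Returns a resolver function mapping coordinates to country codes under a
#' toy geography in which country `codes[k]` occupies the longitude band
#' `[k - 1, k)` at latitudes `[0, 1]`. Coordinates outside every band
#' resolve to `NA`. This fulfils the resolver contract of
#' [clean_dataset()] without any polygon data; real analyses supply their
#' own resolver.
#'
#' @param codes Character vector of country codes, in band order.
#' @return A function `f(lat, lon)` returning a character vector of codes.
#' @examples
#' res <- rect_country_resolver(c("AA", "AB"))
#' res(0.5, 1.2) # "AB"
#' @export
rect_country_resolver <- function(codes) {
  force(codes)
  function(lat, lon) {
    idx <- floor(lon) + 1
    ok <- !is.na(lat) & !is.na(lon) &
      lat >= 0 & lat <= 1 & idx >= 1 & idx <= length(codes)
    out <- rep(NA_character_, length(lon))
    out[ok] <- codes[idx[ok]]
    out
  }
}

#' Resolver matching a synthetic community's toy geography
#'
#' @param community A [generate_community()] object.
#' @return A resolver function as produced by [rect_country_resolver()],
#'   covering the community's regions plus the reserved off-checklist
#'   region `"ZZ"`.
#' @export
community_resolver <- function(community) {
  rect_country_resolver(region_codes(community))
}

band_coords <- function(code, codes, k) {
  idx <- match(code, codes)
  list(lon = idx - 1 + runif(k), lat = runif(k))
}

#' Sample synthetic occurrence records with planted defects
#'
#' Draws `n` records from a synthetic community, species chosen according
#' to the community's relative abundances, then independently plants each
#' of the six record defects per record at the rates in `contamination`.
#' Clean records pass all six cleaning rules by construction; dirty records
#' fail exactly the planted rules. The planted defect labels are kept in
#' the `.defects` list-column, giving downstream tests an exact oracle.
#'
#' @param community A [generate_community()] object.
#' @param n Number of records (positive integer).
#' @param contamination A [contamination_spec()].
#' @param seed Integer seed.
#' @param exclude_species Species names guaranteed to receive no records
#'   (used to honour a checklist's zero-occurrence set).
#' @return A tibble of Darwin Core style occurrence records with columns
#'   `scientificName`, `decimalLatitude`, `decimalLongitude`,
#'   `countryCode`, `basisOfRecord`, `occurrenceStatus`, `license`,
#'   `year`, `speciesKey`, and `.defects` (list of planted rule ids).
#' @examples
#' com <- generate_community(20, seed = 1)
#' occ <- sample_occurrences(com, 100, contamination_spec(), seed = 2)
#' nrow(occ)
#' @export
sample_occurrences <- function(community, n,
                               contamination = contamination_spec(),
                               seed = 1, exclude_species = NULL) {
  stopifnot(inherits(community, "synthetic_community"),
            inherits(contamination, "contamination_spec"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  sp <- community$species
  keep <- !(sp$species %in% exclude_species)
  if (!any(keep)) stop("community has no sampleable species")
  codes <- region_codes(community)

  with_seed(seed, {
    idx_pool <- which(keep)
    p <- sp$p[idx_pool] / sum(sp$p[idx_pool])
    idx <- idx_pool[sample.int(length(idx_pool), n, replace = TRUE, prob = p)]

    rec <- tibble::tibble(
      scientificName = sp$species[idx],
      countryCode = sp$region[idx],
      basisOfRecord = "PRESERVED_SPECIMEN",
      occurrenceStatus = "present",
      license = sample(c("CC0", "CC-BY", "CC-BY-NC"), n, replace = TRUE),
      year = sample(1950:2020, n, replace = TRUE),
      speciesKey = sp$species[idx]
    )
    band <- match(rec$countryCode, codes)
    rec$decimalLongitude <- band - 1 + runif(n)
    rec$decimalLatitude <- runif(n)

    defects <- replicate(n, character(0), simplify = FALSE)
    plant <- function(rule) runif(n) < contamination[[rule]]

    hit <- plant("OFF_CHECKLIST")
    if (any(hit)) {
      rec$countryCode[hit] <- "ZZ"
      zz <- band_coords("ZZ", codes, sum(hit))
      rec$decimalLongitude[hit] <- zz$lon
      rec$decimalLatitude[hit] <- zz$lat
    }
    for (i in which(hit)) defects[[i]] <- c(defects[[i]], "OFF_CHECKLIST")

    hit <- plant("COUNTRY_MISMATCH")
    for (i in which(hit)) {
      other <- setdiff(codes, rec$countryCode[i])
      tgt <- if (length(other) == 1) other else sample(other, 1)
      xy <- band_coords(tgt, codes, 1)
      rec$decimalLongitude[i] <- xy$lon
      rec$decimalLatitude[i] <- xy$lat
      defects[[i]] <- c(defects[[i]], "COUNTRY_MISMATCH")
    }

    hit <- plant("INVALID_BINOMIAL")
    rec$scientificName[hit] <- SYNTH_GENUS
    rec$speciesKey[hit] <- NA_character_
    for (i in which(hit)) defects[[i]] <- c(defects[[i]], "INVALID_BINOMIAL")

    hit <- plant("BAD_BASIS")
    rec$basisOfRecord[hit] <- "FOSSIL_SPECIMEN"
    for (i in which(hit)) defects[[i]] <- c(defects[[i]], "BAD_BASIS")

    hit <- plant("ABSENCE")
    rec$occurrenceStatus[hit] <- "absent"
    for (i in which(hit)) defects[[i]] <- c(defects[[i]], "ABSENCE")

    hit <- plant("BAD_LICENSE")
    rec$license[hit] <- "ALL_RIGHTS_RESERVED"
    for (i in which(hit)) defects[[i]] <- c(defects[[i]], "BAD_LICENSE")

    rec$.defects <- defects
    rec[, c("scientificName", "decimalLatitude", "decimalLongitude",
            "countryCode", "basisOfRecord", "occurrenceStatus", "license",
            "year", "speciesKey", ".defects")]
  })
}

# random epithet of length `len` from lowercase letters
random_epithet <- function(len) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# apply `k` random single-character edits (substitution, insertion,
# deletion, adjacent transposition); each edit moves OSA distance by <= 1
mutate_epithet <- function(x, k) {
  for (i in seq_len(k)) {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    nc <- length(ch)
    op <- sample(c("sub", "ins", "del", "swap"), 1)
    if (op == "del" && nc <= 4) op <- "ins"
    if (op == "swap" && nc < 2) op <- "sub"
    x <- switch(op,
      sub = {
        j <- sample.int(nc, 1)
        ch[j] <- sample(setdiff(letters, ch[j]), 1)
        paste(ch, collapse = "")
      },
      ins = {
        j <- sample.int(nc + 1, 1)
        paste(c(head(ch, j - 1), sample(letters, 1), ch[seq_len(nc) >= j]),
              collapse = "")
      },
      del = {
        j <- sample.int(nc, 1)
        paste(ch[-j], collapse = "")
      },
      swap = {
        j <- sample.int(nc - 1, 1)
        tmp <- ch[j]; ch[j] <- ch[j + 1]; ch[j + 1] <- tmp
        paste(ch, collapse = "")
      }
    )
  }
  x
}

#' Generate a synthetic taxonomy with planted orthographic variants
#'
#' Builds an accepted-species table plus synonyms; each synonym may spawn
#' one orthographic variant: a copy of its name at most two
#' single-character edits away, sharing the parent's accepted id and
#' author-year (and occasionally carrying a stray digit, which name
#' normalisation removes). Base names within an accepted-name group are
#' kept at optimal-string-alignment distance of at least 7 from each other
#' so planted clusters are unambiguous at deduplication threshold 2. The
#' planted cluster label is retained in `clusterTruth`.
#'
#' @param n_accepted Number of accepted species (positive integer).
#' @param synonyms_per_species Mean number of base synonyms per accepted
#'   species (Poisson rate, non-negative).
#' @param variant_rate Probability that a base synonym spawns an
#'   orthographic variant, in \[0, 1\].
#' @param year_range Inclusive integer interval of description years.
#' @param seed Integer seed.
#' @return A tibble with columns `taxonId`, `acceptedId`, `name`,
#'   `authorYear`, `descriptionYear`, `status` (`"accepted"` or
#'   `"synonym"`), `firstOccurrenceYear` (accepted names only, may be
#'   `NA`), and `clusterTruth` (planted cluster id; `NA` for accepted
#'   names).
#' @examples
#' tax <- generate_taxonomy(10, synonyms_per_species = 1, seed = 1)
#' table(tax$status)
#' @export
generate_taxonomy <- function(n_accepted, synonyms_per_species = 1,
                              variant_rate = 0.3,
                              year_range = c(1758, 2020), seed = 1) {
  if (!is.numeric(n_accepted) || n_accepted < 1 ||
      n_accepted != round(n_accepted)) {
    stop("`n_accepted` must be a positive integer")
  }
  if (synonyms_per_species < 0) stop("`synonyms_per_species` must be >= 0")
  if (variant_rate < 0 || variant_rate > 1) {
    stop("`variant_rate` must lie in [0, 1]")
  }
  if (year_range[1] > year_range[2]) stop("invalid `year_range`")
  authors <- c("Smith", "Latreille", "Cockerell", "Michener", "Friese")

  with_seed(seed, {
    rows <- vector("list", n_accepted)
    next_id <- 1L
    for (a in seq_len(n_accepted)) {
      acc_id <- next_id; next_id <- next_id + 1L
      yr <- sample(seq(year_range[1], year_range[2]), 1)
      ay <- paste0(sample(authors, 1), ", ", yr)
      ay_print <- if (runif(1) < 0.3) paste0("(", ay, ")") else ay
      group_names <- random_epithet(sample(8:12, 1))
      acc <- tibble::tibble(
        taxonId = acc_id, acceptedId = acc_id,
        name = paste(SYNTH_GENUS, group_names[1]),
        authorYear = ay_print, descriptionYear = yr,
        status = "accepted",
        firstOccurrenceYear = if (runif(1) < 0.9) {
          min(yr + sample(0:50, 1), year_range[2])
        } else NA_integer_,
        clusterTruth = NA_integer_
      )
      syn_rows <- list()
      n_syn <- rpois(1, synonyms_per_species)
      for (s in seq_len(n_syn)) {
        # keep base epithets well separated within the accepted-name group
        repeat {
          ep <- random_epithet(sample(8:12, 1))
          if (all(osa_distance(ep, group_names) >= 7)) break
        }
        group_names <- c(group_names, ep)
        syn_id <- next_id; next_id <- next_id + 1L
        syr <- sample(seq(year_range[1], year_range[2]), 1)
        say <- paste0(sample(authors, 1), ", ", syr)
        syn_rows[[length(syn_rows) + 1]] <- tibble::tibble(
          taxonId = syn_id, acceptedId = acc_id,
          name = paste(SYNTH_GENUS, ep),
          authorYear = say, descriptionYear = syr,
          status = "synonym", firstOccurrenceYear = NA_integer_,
          clusterTruth = syn_id
        )
        if (runif(1) < variant_rate) {
          # two random edits can exceed OSA distance 2 (OSA is not a
          # metric), so verify the planted variant and retry if needed
          repeat {
            var_ep <- mutate_epithet(ep, sample(1:2, 1))
            if (osa_distance(var_ep, ep) <= 2) break
          }
          if (runif(1) < 0.25) var_ep <- paste0(var_ep, sample(1:9, 1))
          var_id <- next_id; next_id <- next_id + 1L
          syn_rows[[length(syn_rows) + 1]] <- tibble::tibble(
            taxonId = var_id, acceptedId = acc_id,
            name = paste(SYNTH_GENUS, var_ep),
            authorYear = say, descriptionYear = syr,
            status = "synonym", firstOccurrenceYear = NA_integer_,
            clusterTruth = syn_id
          )
        }
      }
      rows[[a]] <- dplyr::bind_rows(c(list(acc), syn_rows))
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a country checklist with a guaranteed zero-occurrence subset
#'
#' The checklist holds every community species-region pair. A fraction of
#' species is flagged `zeroOccurrence`; pass these to
#' [sample_occurrences()] as `exclude_species` to guarantee they appear in
#' no generated occurrence file, emulating checklist species that lack any
#' occurrence records.
#'
#' @param community A [generate_community()] object.
#' @param zero_occurrence_fraction Fraction of species flagged as
#'   zero-occurrence, in \[0, 1\].
#' @param seed Integer seed.
#' @return A tibble with columns `species`, `countryCode`,
#'   `zeroOccurrence`; the zero-occurrence species names are also in
#'   `attr(, "zero_occurrence_species")`.
#' @examples
#' com <- generate_community(20, seed = 1)
#' chk <- generate_checklist(com, 0.25, seed = 2)
#' sum(chk$zeroOccurrence)
#' @export
generate_checklist <- function(community, zero_occurrence_fraction = 0,
                               seed = 1) {
  stopifnot(inherits(community, "synthetic_community"))
  if (zero_occurrence_fraction < 0 || zero_occurrence_fraction > 1) {
    stop("`zero_occurrence_fraction` must lie in [0, 1]")
  }
  sp <- community$species
  with_seed(seed, {
    n_zero <- round(zero_occurrence_fraction * nrow(sp))
    zero <- if (n_zero > 0) sample(sp$species, n_zero) else character(0)
    out <- tibble::tibble(
      species = sp$species,
      countryCode = sp$region,
      zeroOccurrence = sp$species %in% zero
    )
    attr(out, "zero_occurrence_species") <- zero
    out
  })
}

#' Generate a literature sample-size table from a known power law
#'
#' Draws per-species specimen sample sizes from the truncated discrete
#' power law `P(x) proportional to x^-exponent` on `1..cap`, emulating the
#' specimen counts reported for revised species in taxonomic literature.
#'
#' @param exponent Power-law exponent (positive; values above 1 give a
#'   singleton-dominated table).
#' @param n_species Number of species (rows) to draw.
#' @param cap Largest sample size in the support (positive integer).
#' @param seed Integer seed.
#' @return A tibble with columns `species` and `nSpecimens`.
#' @examples
#' lit <- generate_literature_sizes(1.37, 100, cap = 50, seed = 1)
#' head(lit)
#' @export
generate_literature_sizes <- function(exponent, n_species, cap, seed = 1) {
  if (!is.finite(exponent) || exponent <= 0) stop("invalid `exponent`")
  if (!is.numeric(cap) || cap < 1 || cap != round(cap)) {
    stop("`cap` must be a positive integer")
  }
  if (!is.numeric(n_species) || n_species < 1) {
    stop("`n_species` must be a positive integer")
  }
  with_seed(seed, {
    pr <- seq_len(cap)^(-exponent)
    tibble::tibble(
      species = paste(SYNTH_GENUS, epithet_code(seq_len(n_species))),
      nSpecimens = sample.int(cap, n_species, replace = TRUE, prob = pr)
    )
  })
}

#' Write and read occurrence CSV files
#'
#' Occurrence tables round-trip losslessly through RFC 4180 CSV with
#' Darwin Core term headers. The `.defects` ground-truth column is not a
#' Darwin Core term; it is written to a JSON sidecar instead when
#' `truth_path` is given.
#'
#' @param records Occurrence tibble as from [sample_occurrences()].
#' @param path CSV file path.
#' @param truth_path Optional path for the planted-defect JSON sidecar.
#' @return `write_occurrences()` returns `path` invisibly;
#'   `read_occurrences()` returns the occurrence tibble.
#' @export
write_occurrences <- function(records, path, truth_path = NULL) {
  out <- records[, setdiff(names(records), ".defects")]
  readr::write_csv(out, path, na = "")
  if (!is.null(truth_path) && ".defects" %in% names(records)) {
    jsonlite::write_json(
      list(defects = records$.defects),
      truth_path, auto_unbox = FALSE
    )
  }
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      scientificName = readr::col_character(),
      decimalLatitude = readr::col_double(),
      decimalLongitude = readr::col_double(),
      countryCode = readr::col_character(),
      basisOfRecord = readr::col_character(),
      occurrenceStatus = readr::col_character(),
      license = readr::col_character(),
      year = readr::col_integer(),
      speciesKey = readr::col_character()
    ),
    na = ""
  )
}
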