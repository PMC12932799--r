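# Six-rule occurrence-record filter applied before any richness
# estimation: invalid binomials, improper basis of record, coordinate /
# country-code mismatch, absence records, non-open licenses, and records
# outside their species' country checklist. A record is removed when it
# trips any rule (union semantics); per-rule tallies are reported
# separately.

CLEANING_RULES <- c("INVALID_BINOMIAL", "BAD_BASIS", "COUNTRY_MISMATCH",
                    "ABSENCE", "BAD_LICENSE", "OFF_CHECKLIST")

#' Configuration for the six cleaning rules
#'
#' The field's sources do not pin down the exact basis-of-record reject
#' set or license accept set, so both are explicit configuration with
#' defaults that follow common occurrence-cleaning practice. A rule
#' that cannot be evaluated because its fields are missing does not flag
#' (conservative retention); `ABSENCE` requires an explicit "absent".
#'
#' @param bad_basis Basis-of-record values to reject (case-insensitive).
#' @param ok_license Accepted open licenses; any other non-missing license
#'   is flagged.
#' @param rules Which rules are active; disable a rule by omitting it.
#' @return A `cleaning_config` object.
#' @examples
#' cleaning_config(rules = setdiff(cleaning_rules(), "BAD_LICENSE"))
#' @export
cleaning_config <- function(bad_basis = c("FOSSIL_SPECIMEN",
                                          "LIVING_SPECIMEN",
                                          "MATERIAL_CITATION", "UNKNOWN"),
                            ok_license = c("CC0", "CC-BY", "CC-BY-NC"),
                            rules = cleaning_rules()) {
  bad <- setdiff(rules, CLEANING_RULES)
  if (length(bad) > 0) {
    stop("unknown cleaning rule(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(bad_basis = toupper(bad_basis), ok_license = ok_license,
         rules = rules),
    class = "cleaning_config"
  )
}

#' @rdname cleaning_config
#' @export
cleaning_rules <- function() CLEANING_RULES

# A valid binomial is `Genus epithet`: after dropping infraspecific
# markers (and their trailing epithet), exactly two tokens, the first
# capitalised, both purely alphabetic (hyphens allowed in the epithet).
is_valid_binomial <- function(name) {
  vapply(name, function(x) {
    if (is.na(x)) return(FALSE)
    tok <- strsplit(trimws(x), "\\s+")[[1]]
    marker <- grepl("^(var|subsp|ssp|f|forma|subvar)\\.?$", tok,
                    ignore.case = TRUE)
    drop <- marker | c(FALSE, marker[-length(marker)])
    tok <- tok[!drop]
    length(tok) == 2 &&
      grepl("^[A-Z][a-z]+$", tok[1]) &&
      grepl("^[a-z][a-z-]*$", tok[2])
  }, logical(1), USE.NAMES = FALSE)
}

# canonical species identity: the matched speciesKey when the column
# exists (NA means matching failed and species-level rules cannot be
# evaluated), otherwise the verbatim scientific name
record_species <- function(records) {
  if ("speciesKey" %in% names(records)) records$speciesKey
  else records$scientificName
}

validate_coordinates <- function(records) {
  lat <- records$decimalLatitude
  lon <- records$decimalLongitude
  (!is.na(lat) & (lat < -90 | lat > 90)) |
    (!is.na(lon) & (lon < -180 | lon > 180))
}

flag_matrix <- function(records, checklist, country_resolver,
                        config = cleaning_config()) {
  n <- nrow(records)
  m <- matrix(FALSE, nrow = n, ncol = length(CLEANING_RULES),
              dimnames = list(NULL, CLEANING_RULES))
  if (n == 0) return(m)

  if ("INVALID_BINOMIAL" %in% config$rules) {
    m[, "INVALID_BINOMIAL"] <- !is_valid_binomial(records$scientificName)
  }
  if ("BAD_BASIS" %in% config$rules) {
    basis <- toupper(records$basisOfRecord)
    m[, "BAD_BASIS"] <- !is.na(basis) & basis %in% config$bad_basis
  }
  if ("COUNTRY_MISMATCH" %in% config$rules) {
    lat <- records$decimalLatitude
    lon <- records$decimalLongitude
    cc <- records$countryCode
    have <- !is.na(lat) & !is.na(lon) & !is.na(cc)
    if (any(have)) {
      resolved <- country_resolver(lat[have], lon[have])
      m[have, "COUNTRY_MISMATCH"] <- !is.na(resolved) & resolved != cc[have]
    }
  }
  if ("ABSENCE" %in% config$rules) {
    status <- tolower(records$occurrenceStatus)
    m[, "ABSENCE"] <- !is.na(status) & status == "absent"
  }
  if ("BAD_LICENSE" %in% config$rules) {
    lic <- records$license
    m[, "BAD_LICENSE"] <- !is.na(lic) & !(lic %in% config$ok_license)
  }
  if ("OFF_CHECKLIST" %in% config$rules) {
    sp <- record_species(records)
    cc <- records$countryCode
    have <- !is.na(sp) & !is.na(cc)
    key <- paste(sp, cc, sep = "\r")
    ok <- key %in% paste(checklist$species, checklist$countryCode,
                         sep = "\r")
    m[, "OFF_CHECKLIST"] <- have & !ok
  }
  m
}

#' Flag a single occurrence record against the six cleaning rules
#'
#' @param record A one-row occurrence data frame (Darwin Core style
#'   columns; see [sample_occurrences()] for the expected fields).
#' @param checklist Checklist table with columns `species`, `countryCode`.
#' @param country_resolver Function `f(lat, lon)` returning the country
#'   code containing each coordinate, or `NA` when unknown (see
#'   [rect_country_resolver()] for a toy implementation).
#' @param config A [cleaning_config()].
#' @return Character vector of tripped rule identifiers (empty when the
#'   record passes all active rules).
#' @examples
#' com <- generate_community(5, seed = 1)
#' occ <- sample_occurrences(com, 3, seed = 2)
#' chk <- generate_checklist(com, seed = 3)
#' flag_record(occ[1, ], chk, community_resolver(com))
#' @export
flag_record <- function(record, checklist, country_resolver,
                        config = cleaning_config()) {
  stopifnot(nrow(record) == 1)
  if (validate_coordinates(record)) {
    stop("malformed coordinates: latitude must lie in [-90, 90] and ",
         "longitude in [-180, 180]")
  }
  m <- flag_matrix(record, checklist, country_resolver, config)
  CLEANING_RULES[m[1, ]]
}

#' Filter an occurrence dataset with the six cleaning rules
#'
#' Removes every record that trips at least one active rule; a record with
#' several defects is removed once but counted in each rule's tally.
#' Records with malformed coordinates (outside the valid degree ranges)
#' cannot be evaluated reliably: they are excluded from the retained set,
#' counted in the report's `malformed` field, and reported with a warning
#' rather than silently dropped.
#'
#' @inheritParams flag_record
#' @param records Occurrence tibble.
#' @return A list with `records` (retained rows, input order preserved)
#'   and `report` (a `filter_report` with `input`, `retained`, `flagged`,
#'   `malformed`, and per-rule counts).
#' @examples
#' com <- generate_community(10, seed = 1)
#' occ <- sample_occurrences(com, 50, contamination_spec(rate_absence = 0.2),
#'                           seed = 2)
#' chk <- generate_checklist(com, seed = 3)
#' res <- clean_dataset(occ, chk, community_resolver(com))
#' res$report
#' @export
clean_dataset <- function(records, checklist, country_resolver,
                          config = cleaning_config()) {
  n <- nrow(records)
  if (n == 0) {
    report <- new_filter_report(0L, 0L, 0L, 0L,
                                setNames(integer(length(CLEANING_RULES)),
                                         CLEANING_RULES))
    return(list(records = records, report = report))
  }
  malformed <- validate_coordinates(records)
  if (any(malformed)) {
    warning(sum(malformed), " record(s) with malformed coordinates ",
            "excluded from cleaning and from the retained set")
  }
  ok_rows <- !malformed
  m <- matrix(FALSE, nrow = n, ncol = length(CLEANING_RULES),
              dimnames = list(NULL, CLEANING_RULES))
  m[ok_rows, ] <- flag_matrix(records[ok_rows, , drop = FALSE], checklist,
                              country_resolver, config)
  flagged <- rowSums(m) > 0
  keep <- ok_rows & !flagged
  report <- new_filter_report(
    input = n,
    retained = sum(keep),
    flagged = sum(flagged & ok_rows),
    malformed = sum(malformed),
    per_rule = colSums(m[ok_rows, , drop = FALSE])
  )
  list(records = records[keep, , drop = FALSE], report = report)
}

new_filter_report <- function(input, retained, flagged, malformed,
                              per_rule) {
  structure(
    list(input = as.integer(input), retained = as.integer(retained),
         flagged = as.integer(flagged), malformed = as.integer(malformed),
         per_rule = setNames(as.integer(per_rule), names(per_rule))),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Occurrence cleaning report\n")
  cat(sprintf("  input: %d  retained: %d  removed: %d (malformed: %d)\n",
              x$input, x$retained, x$input - x$retained, x$malformed))
  for (r in names(x$per_rule)) {
    cat(sprintf("  %-17s %d\n", r, x$per_rule[[r]]))
  }
  invisible(x)
}

#' Summarise a filter report as stable JSON
#'
#' @param report A `filter_report` from [clean_dataset()].
#' @param json Return a JSON string (`TRUE`, default) or the underlying
#'   list.
#' @return JSON text (or a list) with keys `input`, `retained`, `removed`,
#'   `flagged`, `malformed`, and `per_rule`; `retained + flagged +
#'   malformed == input` always reconciles.
#' @examples
#' rep <- clean_dataset(tibble::tibble(), tibble::tibble(), identity)$report
#' summarize_flags(rep)
#' @export
summarize_flags <- function(report, json = TRUE) {
  stopifnot(inherits(report, "filter_report"))
  out <- list(
    input = report$input,
    retained = report$retained,
    removed = report$input - report$retained,
    flagged = report$flagged,
    malformed = report$malformed,
    per_rule = as.list(report$per_rule)
  )
  if (!json) return(out)
  jsonlite::toJSON(out, auto_unbox = TRUE)
}
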