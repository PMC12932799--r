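# Orthographic-variant filtering of synonym lists and
# species-accumulation / description-rate analyses. Variants are
# alternative spellings of the same published name: within a group
# sharing the accepted id and (bracket-stripped) author-year, names
# within a small optimal-string-alignment distance are clustered via
# graph connected components and only the first of each cluster kept.

#' Normalise a taxon name and author-year for comparison
#'
#' Digits are stripped from names and brackets/parentheses from
#' author-years; internal whitespace is collapsed and ends trimmed. Case
#' is preserved (comparisons downstream are case-insensitive).
#'
#' @param name Character vector of taxon names.
#' @param authorYear Character vector of author-year strings (optional).
#' @return A tibble with columns `name` and `authorYear`.
#' @examples
#' normalize_epithet("vittatum 2", "(Smith, 1853)")
#' @export
normalize_epithet <- function(name, authorYear = NA_character_) {
  if (length(name) == 0 || any(is.na(name)) || any(trimws(name) == "")) {
    stop("`name` must be non-empty")
  }
  squish <- function(x) trimws(gsub("\\s+", " ", x))
  nm <- squish(gsub("[0-9]", "", name))
  if (any(nm == "")) stop("name is empty after normalisation")
  ay <- squish(gsub("[][(){}]", "", authorYear))
  tibble::tibble(name = nm, authorYear = ay)
}

# optimal string alignment (restricted Damerau-Levenshtein) distance:
# substitutions, insertions, deletions, and adjacent transpositions,
# each substring edited at most once
osa_one <- function(s, t) {
  a <- utf8ToInt(s)
  b <- utf8ToInt(t)
  n <- length(a)
  m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L,
                             d[i + 1, j] + 1L,
                             d[i, j] + cost)
      if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

#' Optimal string alignment distance
#'
#' Edit distance allowing substitutions, insertions, deletions, and
#' adjacent transpositions (each block edited at most once). Vectorised
#' with the usual recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @examples
#' osa_distance("vittatum", "vitatum") # 1
#' osa_distance("abcd", "abdc")        # 1 (transposition)
#' @export
osa_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  mapply(osa_one, a, b, USE.NAMES = FALSE)
}

#' Cluster orthographic variants within a pre-grouped name set
#'
#' Builds a graph with an edge between two names whenever the optimal
#' string alignment distance between their normalised, lower-cased forms
#' is at most `distance_threshold`; clusters are the connected
#' components, and each cluster's representative is its first member in
#' input order.
#'
#' @param names Character vector of names sharing an accepted id and
#'   normalised author-year.
#' @param distance_threshold Maximum distance joining two names
#'   (default 2).
#' @return A tibble with columns `name`, `cluster` (integer id numbered
#'   by first appearance), and `representative` (logical).
#' @examples
#' orthographic_clusters(c("vittatum", "vitatum", "concinna"))
#' @export
orthographic_clusters <- function(names, distance_threshold = 2) {
  if (length(names) == 0) stop("`names` must be non-empty")
  norm <- tolower(normalize_epithet(names)$name)
  k <- length(names)
  if (k == 1) {
    return(tibble::tibble(name = names, cluster = 1L,
                          representative = TRUE))
  }
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      adj[i, j] <- adj[j, i] <-
        osa_one(norm[i], norm[j]) <= distance_threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  # renumber clusters by first appearance so ids are input-order stable
  first <- match(unique(memb), memb)
  cluster <- match(memb, memb[sort(first)])
  tibble::tibble(
    name = names,
    cluster = as.integer(cluster),
    representative = !duplicated(cluster)
  )
}

#' Deduplicate orthographic variants in a synonym list
#'
#' Groups synonym rows by accepted id and normalised author-year, clusters
#' each group with [orthographic_clusters()], and keeps only the first
#' member of each cluster. Accepted names are never removed. Re-running on
#' the kept rows is the identity.
#'
#' @param taxonomy Taxonomy tibble with columns `acceptedId`, `name`,
#'   `authorYear`, `status` (see [generate_taxonomy()]).
#' @param distance_threshold Passed to [orthographic_clusters()].
#' @return The taxonomy with added columns `clusterId` (a string unique
#'   across groups; `NA` for accepted names) and `kept` (logical).
#' @examples
#' tax <- generate_taxonomy(5, synonyms_per_species = 2,
#'                          variant_rate = 0.5, seed = 3)
#' dd <- dedup_synonyms(tax)
#' sum(!dd$kept)
#' @export
dedup_synonyms <- function(taxonomy, distance_threshold = 2) {
  stopifnot(all(c("acceptedId", "name", "authorYear", "status") %in%
                  names(taxonomy)))
  out <- taxonomy
  out$clusterId <- NA_character_
  out$kept <- TRUE
  syn <- which(out$status == "synonym")
  if (length(syn) == 0) return(out)

  ay <- normalize_epithet(out$name[syn], out$authorYear[syn])$authorYear
  grp <- paste(out$acceptedId[syn], ay, sep = "|")
  for (g in unique(grp)) {
    rows <- syn[grp == g]
    cl <- orthographic_clusters(out$name[rows], distance_threshold)
    out$clusterId[rows] <- paste(g, cl$cluster, sep = "|")
    out$kept[rows] <- cl$representative
  }
  out
}

#' Species accumulation curves by description year
#'
#' Three cumulative series: `VALID_NAMES` (accepted names by description
#' year), `SYNONYMS` (synonym names by their original description year,
#' not the year of synonymisation), and `FIRST_OCCURRENCE` (accepted
#' species by the year of their first occurrence record, skipping missing
#' years).
#'
#' @param taxonomy Taxonomy tibble with columns `status`,
#'   `descriptionYear`, and optionally `firstOccurrenceYear` (synonyms
#'   should already be deduplicated).
#' @return A tibble with columns `series`, `year`, `cumulative`; within
#'   each series the cumulative counts are nondecreasing and end at the
#'   series total.
#' @examples
#' tax <- generate_taxonomy(20, seed = 1)
#' accumulation_curves(tax)
#' @export
accumulation_curves <- function(taxonomy) {
  cum_series <- function(years, id) {
    years <- sort(years[!is.na(years)])
    if (length(years) == 0) {
      return(tibble::tibble(series = character(0), year = integer(0),
                            cumulative = integer(0)))
    }
    yr <- unique(years)
    tibble::tibble(series = id, year = as.integer(yr),
                   cumulative = cumsum(tabulate(factor(years, levels = yr))))
  }
  acc <- taxonomy$status == "accepted"
  dplyr::bind_rows(
    cum_series(taxonomy$descriptionYear[acc], "VALID_NAMES"),
    cum_series(taxonomy$descriptionYear[!acc], "SYNONYMS"),
    if ("firstOccurrenceYear" %in% names(taxonomy)) {
      cum_series(taxonomy$firstOccurrenceYear[acc], "FIRST_OCCURRENCE")
    }
  )
}

#' Species description rate from an accumulation curve
#'
#' Ordinary least-squares slope of cumulative count versus year,
#' restricted to years at or after `start_year` (default 1960, the era of
#' approximately constant description effort).
#'
#' @param curve Accumulation tibble with columns `year`, `cumulative`
#'   (and optionally `series`).
#' @param start_year First year included in the regression.
#' @param series Which series to use when `curve` holds several.
#' @return The slope, in species per year.
#' @examples
#' curve <- tibble::tibble(year = 1960:1980,
#'                         cumulative = 100 + 117 * (0:20))
#' description_rate(curve)
#' @export
description_rate <- function(curve, start_year = 1960,
                             series = "VALID_NAMES") {
  if ("series" %in% names(curve) && length(unique(curve$series)) > 1) {
    curve <- curve[curve$series == series, , drop = FALSE]
  }
  sel <- curve$year >= start_year
  if (sum(sel) < 2) {
    stop("need at least 2 curve points at or after ", start_year)
  }
  unname(coef(lm(cumulative ~ year, data = curve[sel, ]))[2])
}
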