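# Per-region abundance assemblages and the literature sample-size curve.
# Checklist species without any occurrence record receive an imputed
# specimen count drawn from a fitted decaying power law truncated at the
# region's largest empirical per-species count.

#' Construct an abundance vector
#'
#' The estimator input: per-species specimen counts for one region, each
#' tagged with its provenance (`"EMPIRICAL"` from occurrence records or
#' `"CURVE_SAMPLED"` from the literature curve).
#'
#' @param counts Named vector of positive integer counts (names are
#'   species).
#' @param region Region label (country code, continent name, or
#'   `"GLOBAL"`).
#' @param provenance Per-species provenance tags, recycled if length 1.
#' @return An `abundance_vector` object.
#' @examples
#' abundance_vector(c(a = 3, b = 1), "AA")
#' @export
abundance_vector <- function(counts, region,
                             provenance = "EMPIRICAL") {
  counts <- unlist(counts)
  if (length(counts) > 0) {
    if (is.null(names(counts)) || anyNA(names(counts)) ||
        any(names(counts) == "")) {
      stop("`counts` must be named by species")
    }
    if (anyDuplicated(names(counts))) stop("duplicated species in `counts`")
    if (any(counts < 1) || any(counts != round(counts))) {
      stop("all counts must be positive integers")
    }
  }
  provenance <- rep_len(provenance, length(counts))
  if (!all(provenance %in% c("EMPIRICAL", "CURVE_SAMPLED"))) {
    stop("provenance must be EMPIRICAL or CURVE_SAMPLED")
  }
  structure(
    list(region = region,
         counts = setNames(as.integer(counts), names(counts)),
         provenance = setNames(provenance, names(counts))),
    class = "abundance_vector"
  )
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf(
    "Abundance vector [%s]: %d species, n = %d (%d curve-sampled)\n",
    x$region, length(x$counts), sum(x$counts),
    sum(x$provenance == "CURVE_SAMPLED")
  ))
  invisible(x)
}

#' @export
as.data.frame.abundance_vector <- function(x, ...) {
  data.frame(region = rep(x$region, length(x$counts)),
             species = names(x$counts),
             count = unname(x$counts),
             provenance = unname(x$provenance),
             stringsAsFactors = FALSE)
}

#' Build a per-region abundance vector from cleaned occurrence records
#'
#' Counts retained records per species within the requested region.
#' `"GLOBAL"` uses all records; a continent (any value of
#' `region_mapping$continent`) uses records from its member countries; any
#' other label is treated as a country code.
#'
#' @param records Cleaned occurrence tibble (output of [clean_dataset()]).
#' @param region Region label.
#' @param region_mapping Optional tibble with columns `countryCode`,
#'   `continent`.
#' @return An `abundance_vector` with all-`"EMPIRICAL"` provenance.
#' @examples
#' com <- generate_community(10, seed = 1)
#' occ <- sample_occurrences(com, 40, seed = 2)
#' build_abundance(occ, "GLOBAL")
#' @export
build_abundance <- function(records, region, region_mapping = NULL) {
  known <- c("GLOBAL", unique(records$countryCode))
  if (!is.null(region_mapping)) {
    known <- c(known, region_mapping$countryCode, region_mapping$continent)
  }
  if (!(region %in% known)) stop("unknown region label: ", region)

  sel <- if (region == "GLOBAL") {
    rep(TRUE, nrow(records))
  } else if (!is.null(region_mapping) &&
             region %in% region_mapping$continent) {
    members <- region_mapping$countryCode[region_mapping$continent == region]
    records$countryCode %in% members
  } else {
    !is.na(records$countryCode) & records$countryCode == region
  }
  sp <- record_species(records[sel, , drop = FALSE])
  counts <- table(sp)
  abundance_vector(setNames(as.integer(counts), names(counts)), region)
}

#' Construct a literature sample-size curve
#'
#' The decaying power law `y(x) = a * x^(1 - ln(b))` describing how many
#' species were revised from `x` specimens in the taxonomic literature;
#' `y(1) = a` is the expected number of single-specimen species. A proper
#' frequency curve decays, i.e. `1 - ln(b) < 0` (equivalently `b > e`).
#'
#' @param a Positive multiplier (the fitted singleton frequency).
#' @param b Positive inner constant; the power-law exponent is
#'   `1 - ln(b)`.
#' @param residual_standard_error Residual standard error of the fit
#'   (denominator `N - 2`), or `NA`.
#' @param cap Default truncation of the sampling support, or `NA` to defer
#'   to the sampling call.
#' @return A `literature_curve` object.
#' @examples
#' literature_curve(226.6, 10.7)
#' @export
literature_curve <- function(a, b, residual_standard_error = NA_real_,
                             cap = NA_integer_) {
  if (!is.finite(a) || a <= 0) stop("`a` must be positive")
  if (!is.finite(b) || b <= 0) stop("`b` must be positive")
  if (1 - log(b) >= 0) {
    warning("curve does not decay: 1 - ln(b) >= 0 (b <= e)")
  }
  structure(
    list(a = a, b = b, exponent = 1 - log(b),
         residual_standard_error = residual_standard_error,
         cap = cap),
    class = "literature_curve"
  )
}

#' @export
print.literature_curve <- function(x, ...) {
  cat(sprintf(
    "Literature curve: y(x) = %.4g * x^(1 - ln(%.4g)) = %.4g * x^%.4g\n",
    x$a, x$b, x$a, x$exponent))
  if (is.finite(x$residual_standard_error)) {
    cat(sprintf("  residual standard error: %.3g\n",
                x$residual_standard_error))
  }
  invisible(x)
}

#' Tabulate a size-frequency table from raw literature sample sizes
#'
#' @param sizes Table with column `nSpecimens` (as from
#'   [generate_literature_sizes()]) or a bare numeric vector of sizes.
#' @return Tibble with columns `x` (sample size) and `y` (number of
#'   species with that size); sizes never observed are omitted.
#' @examples
#' size_frequency(c(1, 1, 2, 5))
#' @export
size_frequency <- function(sizes) {
  v <- if (is.data.frame(sizes)) sizes$nSpecimens else sizes
  if (any(v < 1) || any(v != round(v))) {
    stop("sample sizes must be positive integers")
  }
  tab <- table(v)
  tibble::tibble(x = as.numeric(names(tab)), y = as.numeric(tab))
}

#' Fit the literature curve to a size-frequency table
#'
#' Nonlinear least squares on the untransformed frequencies for
#' `y(x) = a * x^(1 - ln(b))`, initialised from a log-log linear
#' regression of the positive frequencies. Fitting on the raw scale
#' matches selection by lowest residual standard error; the log-log start
#' keeps the optimiser in the right basin.
#'
#' @param size_frequency Tibble with columns `x` (>= 1) and `y` (>= 0),
#'   at least 3 distinct `x`.
#' @return A [literature_curve()] with fitted `a`, `b`, and residual
#'   standard error computed with denominator `N - 2`.
#' @examples
#' x <- 1:30
#' fit_literature_curve(tibble::tibble(x = x, y = 226.6 * x^(1 - log(10.7))))
#' @export
fit_literature_curve <- function(size_frequency) {
  x <- size_frequency$x
  y <- size_frequency$y
  if (length(unique(x)) < 3) {
    stop("need at least 3 distinct sample sizes to fit the curve")
  }
  if (any(x < 1) || any(y < 0)) stop("require x >= 1 and y >= 0")

  pos <- y > 0
  init <- lm(log(y[pos]) ~ log(x[pos]))
  a0 <- exp(unname(coef(init)[1]))
  b0 <- exp(1 - unname(coef(init)[2]))
  fit <- minpack.lm::nlsLM(
    y ~ a * x^(1 - log(b)),
    data = data.frame(x = x, y = y),
    start = list(a = a0, b = max(b0, 1e-3)),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  co <- coef(fit)
  rse <- sqrt(sum(resid(fit)^2) / (length(x) - 2))
  literature_curve(unname(co["a"]), unname(co["b"]),
                   residual_standard_error = rse)
}

#' Probability mass of the truncated literature-curve distribution
#'
#' @param curve A [literature_curve()].
#' @param cap Truncation point (positive integer).
#' @return Numeric vector of probabilities over sizes `1..cap`.
#' @examples
#' literature_pmf(literature_curve(226.6, 10.7), cap = 5)
#' @export
literature_pmf <- function(curve, cap) {
  stopifnot(inherits(curve, "literature_curve"))
  if (!is.numeric(cap) || length(cap) != 1 || cap < 1 ||
      cap != round(cap)) {
    stop("`cap` must be a positive integer")
  }
  w <- seq_len(cap)^curve$exponent
  w / sum(w)
}

#' Sample specimen counts from the literature curve
#'
#' Draws sizes from `{1..cap}` with probability proportional to
#' `y(x) = a * x^(1 - ln(b))` (the multiplier `a` cancels in the
#' normalisation). Uses the current RNG state; seed the caller for
#' reproducibility.
#'
#' @inheritParams literature_pmf
#' @param n Number of draws.
#' @return Integer vector of `n` sampled counts in `1..cap`.
#' @examples
#' set.seed(1)
#' sample_literature_count(literature_curve(226.6, 10.7), cap = 10, n = 5)
#' @export
sample_literature_count <- function(curve, cap, n = 1) {
  pr <- literature_pmf(curve, cap)
  sample.int(cap, n, replace = TRUE, prob = pr)
}

#' Augment an assemblage with curve-sampled counts for missing species
#'
#' Every checklist species absent from the empirical assemblage receives
#' one specimen count sampled from the literature curve truncated at the
#' region's largest empirical per-species count (the global maximum for a
#' global analysis). Empirical counts are never altered. Uses the current
#' RNG state; callers seed per iteration so each iteration resamples the
#' imputed counts afresh.
#'
#' @param empirical An [abundance_vector()] with empirical counts.
#' @param checklist_species Character vector of species on the region's
#'   checklist.
#' @param curve A [literature_curve()].
#' @param cap Optional truncation override; defaults to the maximum
#'   empirical count.
#' @param default_cap Fallback cap when the empirical vector is empty (a
#'   warning is emitted).
#' @return An `abundance_vector` containing the empirical counts plus one
#'   `"CURVE_SAMPLED"` count per missing checklist species.
#' @examples
#' av <- abundance_vector(c(a = 7, b = 2), "AA")
#' cv <- literature_curve(226.6, 10.7)
#' set.seed(1)
#' augment_assemblage(av, c("a", "b", "c"), cv)
#' @export
augment_assemblage <- function(empirical, checklist_species, curve,
                               cap = NULL, default_cap = 100) {
  stopifnot(inherits(empirical, "abundance_vector"),
            inherits(curve, "literature_curve"))
  missing <- setdiff(checklist_species, names(empirical$counts))
  if (length(missing) == 0) return(empirical)

  if (is.null(cap)) {
    if (length(empirical$counts) == 0) {
      warning("empty empirical assemblage: falling back to default cap ",
              default_cap)
      cap <- default_cap
    } else {
      cap <- max(empirical$counts)
    }
  }
  drawn <- sample_literature_count(curve, cap, n = length(missing))
  abundance_vector(
    c(empirical$counts, setNames(drawn, missing)),
    region = empirical$region,
    provenance = c(empirical$provenance,
                   setNames(rep("CURVE_SAMPLED", length(missing)), missing))
  )
}
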