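# The iterative resampling engine: the literature-curve augmentation is
# stochastic, so the whole augment-and-estimate step is repeated R times
# (default 100) and the component-wise medians of the point estimates and
# confidence bounds reported. Region exclusion rules and the taxonomic
# gap arithmetic live here too.

# round half away from zero (printed integer ranges use this convention)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Run the iterative augment-and-estimate resampling scheme
#'
#' Each iteration augments the empirical assemblage with fresh
#' curve-sampled counts for the checklist species lacking occurrences
#' ([augment_assemblage()]), estimates richness with a confidence
#' interval ([estimate_richness()]), and records the triple (point, lcl,
#' ucl). The summary takes component-wise medians over iterations.
#' Iteration `i` uses child seed `child_seed(seed, i)`, so the whole run
#' is reproducible from the master seed. When no checklist species is
#' missing the augmentation is deterministic, and the single estimate is
#' replicated across iterations.
#'
#' An iteration whose estimator fails is recorded as failed and excluded
#' from the medians with a warning; more than 50 percent failures is an
#' error.
#'
#' @param empirical An [abundance_vector()] of empirical counts.
#' @param checklist_species Species on the region's checklist.
#' @param curve A [literature_curve()].
#' @param method `"ichao1"` or `"inext"` (see [estimate_richness()]).
#' @param R Number of iterations (default 100).
#' @param seed Master seed.
#' @param B Bootstrap resamples per iteration.
#' @param level Confidence level.
#' @param cap,default_cap Passed to [augment_assemblage()].
#' @return An `iteration_summary` with fields `region`, `method`, `R`,
#'   `median_point`, `median_lcl`, `median_ucl`, `per_iteration` (tibble
#'   of `iter`, `point`, `lcl`, `ucl`, `failed`), `n_records`,
#'   `S_obs_empirical`, `S_checklist_only`, `n_failed`.
#' @examples
#' av <- abundance_vector(c(a = 4, b = 2, c = 1, d = 1), "AA")
#' cv <- literature_curve(226.6, 10.7)
#' run_iterations(av, c("a", "b", "c", "d", "e"), cv, R = 5, B = 20)
#' @export
run_iterations <- function(empirical, checklist_species, curve,
                           method = c("ichao1", "inext"), R = 100,
                           seed = 1, B = 200, level = 0.95, cap = NULL,
                           default_cap = 100) {
  method <- match.arg(method)
  stopifnot(inherits(empirical, "abundance_vector"))
  if (!is.numeric(R) || R < 1 || R != round(R)) {
    stop("`R` must be a positive integer")
  }
  missing_sp <- setdiff(checklist_species, names(empirical$counts))

  one <- function(i) {
    cs <- child_seed(seed, i)
    aug <- with_seed(cs, {
      augment_assemblage(empirical, checklist_species, curve,
                         cap = cap, default_cap = default_cap)
    })
    est <- estimate_richness(aug, method = method, B = B, level = level,
                             seed = child_seed(cs, 1))
    c(point = est$point, lcl = est$lcl, ucl = est$ucl)
  }

  if (length(missing_sp) == 0) {
    # no stochastic input: one deterministic estimate replicated R times
    res <- one(1)
    per <- tibble::tibble(
      iter = seq_len(R), point = res[["point"]], lcl = res[["lcl"]],
      ucl = res[["ucl"]], failed = FALSE
    )
  } else {
    rows <- lapply(seq_len(R), function(i) {
      tryCatch({
        res <- one(i)
        tibble::tibble(iter = i, point = res[["point"]],
                       lcl = res[["lcl"]], ucl = res[["ucl"]],
                       failed = FALSE)
      }, error = function(e) {
        tibble::tibble(iter = i, point = NA_real_, lcl = NA_real_,
                       ucl = NA_real_, failed = TRUE)
      })
    })
    per <- dplyr::bind_rows(rows)
  }

  n_failed <- sum(per$failed)
  if (n_failed > R / 2) {
    stop("more than half of the iterations failed (", n_failed, " of ",
         R, ")")
  }
  if (n_failed > 0) {
    warning(n_failed, " of ", R,
            " iterations failed and were excluded from the medians")
  }
  ok <- !per$failed
  structure(
    list(region = empirical$region, method = method, R = as.integer(R),
         median_point = median(per$point[ok]),
         median_lcl = median(per$lcl[ok]),
         median_ucl = median(per$ucl[ok]),
         per_iteration = per,
         n_records = sum(empirical$counts),
         S_obs_empirical = length(empirical$counts),
         S_checklist_only = length(missing_sp),
         n_failed = n_failed),
    class = "iteration_summary"
  )
}

#' @export
print.iteration_summary <- function(x, ...) {
  cat(sprintf(
    "Iteration summary [%s, %s, R = %d]: median %.1f (CI %.1f-%.1f)\n",
    x$region, x$method, x$R, x$median_point, x$median_lcl, x$median_ucl))
  cat(sprintf(
    "  n_records = %d, S_obs empirical = %d, checklist-only = %d%s\n",
    x$n_records, x$S_obs_empirical, x$S_checklist_only,
    if (x$n_failed > 0) paste0(", failed iterations = ", x$n_failed) else ""))
  invisible(x)
}

#' Region exclusion rules
#'
#' A region is excluded when its empirical record count is below
#' `min_records` (default 30), or when the median estimate diverges from
#' the observed richness by more than `fold_threshold`-fold (default 10,
#' the order-of-magnitude rule); the latter typically signals assemblages
#' where nearly every species is a singleton.
#'
#' @param summary An `iteration_summary`.
#' @param min_records Minimum empirical record count.
#' @param fold_threshold Maximum ratio of median estimate to total
#'   observed richness (empirical plus checklist-only species).
#' @return List with `keep` (logical) and `reason` (`NA`,
#'   `"SMALL_SAMPLE"`, or `"DIVERGENT"`).
#' @examples
#' av <- abundance_vector(c(a = 4, b = 2), "AA")
#' cv <- literature_curve(226.6, 10.7)
#' s <- run_iterations(av, c("a", "b"), cv, R = 2, B = 10)
#' exclude_region(s)
#' @export
exclude_region <- function(summary, min_records = 30,
                           fold_threshold = 10) {
  stopifnot(inherits(summary, "iteration_summary"))
  s_total <- summary$S_obs_empirical + summary$S_checklist_only
  if (s_total == 0 || summary$n_records < min_records) {
    return(list(keep = FALSE, reason = "SMALL_SAMPLE"))
  }
  if (summary$median_point / s_total > fold_threshold) {
    return(list(keep = FALSE, reason = "DIVERGENT"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Taxonomic gap report
#'
#' Converts a richness confidence interval into the taxonomic gap
#' (estimated minus described species), the percentage increase on the
#' described count, and the years needed to close the gap at a constant
#' description rate. Percentages and years are rounded half away from
#' zero to integers, matching how such ranges are conventionally printed.
#'
#' @param ci Numeric `c(low, high)` richness bounds (e.g. the median CI
#'   of an [run_iterations()] summary).
#' @param described Number of currently described (recognised) species.
#' @param rate Description rate in species/year (default 117, see
#'   [description_rate()]).
#' @return A `gap_report` with fields `described`, `rate`, `ci`, `gap`,
#'   `pct`, `years` (each a `c(low, high)` pair). Negative gaps are
#'   floored at zero with a warning.
#' @examples
#' gap_report(c(24705, 26164), described = 20934, rate = 117)
#' @export
gap_report <- function(ci, described, rate = 117) {
  if (length(ci) != 2 || ci[1] > ci[2]) {
    stop("`ci` must be c(low, high) with low <= high")
  }
  if (!is.numeric(described) || described < 1) {
    stop("`described` must be a positive integer")
  }
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive")
  gap <- unname(ci) - described
  if (any(gap < 0)) {
    warning("estimate below the described species count; gap floored at 0")
    gap <- pmax(gap, 0)
  }
  structure(
    list(described = described, rate = rate, ci = unname(ci),
         gap = gap,
         pct = round_half_up(100 * gap / described),
         years = round_half_up(gap / rate)),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf(
    paste0("Taxonomic gap: %.0f-%.0f species (+%.0f-%.0f%% on %.0f ",
           "described), %.0f-%.0f years at %.0f species/year\n"),
    x$gap[1], x$gap[2], x$pct[1], x$pct[2], x$described,
    x$years[1], x$years[2], x$rate))
  invisible(x)
}

#' Do two median confidence intervals overlap?
#'
#' Closed-interval convention: touching endpoints count as overlap. Both
#' arguments may be `iteration_summary` objects (which must describe the
#' same region) or bare numeric `c(lcl, ucl)` intervals.
#'
#' @param summary_a,summary_b Iteration summaries or length-2 numeric
#'   intervals.
#' @return `TRUE` iff the intervals intersect.
#' @examples
#' ci_overlap(c(10, 20), c(15, 25))
#' @export
ci_overlap <- function(summary_a, summary_b) {
  as_interval <- function(x) {
    if (inherits(x, "iteration_summary")) c(x$median_lcl, x$median_ucl)
    else if (is.numeric(x) && length(x) == 2) unname(x)
    else stop("expected an iteration summary or a length-2 interval")
  }
  if (inherits(summary_a, "iteration_summary") &&
      inherits(summary_b, "iteration_summary") &&
      !identical(summary_a$region, summary_b$region)) {
    stop("summaries describe different regions")
  }
  a <- as_interval(summary_a)
  b <- as_interval(summary_b)
  a[1] <= b[2] && b[1] <= a[2]
}
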