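# Nonparametric richness estimation from abundance frequency counts:
# Chao1, iChao1, analytic rarefaction/extrapolation of Hill number q = 0,
# a log-transformed confidence interval for Chao1, and a
# coverage-adjusted bootstrap interval for any of the estimators.

#' Frequency counts: the sufficient statistics of richness estimators
#'
#' Reduces an abundance vector to `(S_obs, n, f_1, f_2, ...)` where `f_k`
#' is the number of species observed exactly `k` times. All estimators in
#' this package are functions of this object alone.
#'
#' @param x An [abundance_vector()] or a bare vector of positive integer
#'   counts.
#' @return A `frequency_counts` object with fields `S_obs`, `n`, and `f`
#'   (integer vector, `f[k]` = number of species with count `k`).
#' @examples
#' frequency_counts(c(a = 1, b = 1, c = 2))
#' @export
frequency_counts <- function(x) {
  counts <- if (inherits(x, "abundance_vector")) x$counts else unlist(x)
  counts <- unname(counts)
  if (length(counts) > 0 &&
      (any(counts < 1) || any(counts != round(counts)))) {
    stop("all counts must be positive integers")
  }
  f <- if (length(counts) > 0) tabulate(counts) else integer(0)
  structure(
    list(S_obs = length(counts), n = as.integer(sum(counts)),
         f = as.integer(f)),
    class = "frequency_counts"
  )
}

#' @export
print.frequency_counts <- function(x, ...) {
  cat(sprintf("Frequency counts: S_obs = %d, n = %d, f1 = %d, f2 = %d\n",
              x$S_obs, x$n, f_k(x, 1), f_k(x, 2)))
  invisible(x)
}

#' @rdname frequency_counts
#' @param fc A `frequency_counts` object.
#' @param k Count class (positive integer), may be a vector.
#' @export
f_k <- function(fc, k) {
  out <- integer(length(k))
  ok <- k >= 1 & k <= length(fc$f)
  out[ok] <- fc$f[k[ok]]
  out
}

as_fc <- function(x) {
  if (inherits(x, "frequency_counts")) x else frequency_counts(x)
}

#' Chao1 lower-bound richness estimator
#'
#' `S_obs + f1^2 / (2 f2)` when doubletons are present; the
#' bias-corrected form `S_obs + f1 (f1 - 1) / 2` when `f2 = 0`. Always at
#' least `S_obs`.
#'
#' @param fc A [frequency_counts()] object (or anything coercible).
#' @return The Chao1 point estimate.
#' @examples
#' chao1(c(a = 1, b = 1, c = 2))
#' @export
chao1 <- function(fc) {
  fc <- as_fc(fc)
  f1 <- f_k(fc, 1)
  f2 <- f_k(fc, 2)
  if (f2 > 0) fc$S_obs + f1^2 / (2 * f2)
  else fc$S_obs + f1 * (f1 - 1) / 2
}

# analytic Chao1 variance (classical form for f2 > 0, bias-corrected
# form otherwise); used by the log-transformed interval
chao1_var <- function(fc) {
  fc <- as_fc(fc)
  f1 <- f_k(fc, 1)
  f2 <- f_k(fc, 2)
  if (f2 > 0) {
    r <- f1 / f2
    f2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else if (f1 > 0) {
    est <- chao1(fc)
    f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
  } else {
    0
  }
}

#' iChao1 improved lower-bound richness estimator
#'
#' Adds to Chao1 the nonnegative correction
#' `(f3 / (4 f4)) * max(f1 - f2 f3 / (2 f4), 0)` drawing on tripleton and
#' quadrupleton information; when `f4 = 0`, `f4 + 1` is substituted in
#' both occurrences (bias-corrected variant), and when `f3 = 0` the
#' correction vanishes. Always `>= chao1(fc) >= S_obs`.
#'
#' @inheritParams chao1
#' @return The iChao1 point estimate.
#' @examples
#' ichao1(c(a = 1, b = 1, c = 2, d = 3, e = 3, f = 4))
#' @export
ichao1 <- function(fc) {
  fc <- as_fc(fc)
  base <- chao1(fc)
  f3 <- f_k(fc, 3)
  if (f3 == 0) return(base)
  f1 <- f_k(fc, 1)
  f2 <- f_k(fc, 2)
  f4 <- f_k(fc, 4)
  if (f4 == 0) f4 <- f4 + 1
  base + (f3 / (4 * f4)) * max(f1 - f2 * f3 / (2 * f4), 0)
}

#' Rarefaction and extrapolation of species richness (Hill number q = 0)
#'
#' Expected species richness in a sample of size `m`. For `m <= n` the
#' analytic hypergeometric rarefaction
#' \deqn{\hat S(m) = S_{obs} - \sum_k f_k \binom{n-k}{m} / \binom{n}{m}}
#' (binomial coefficients evaluated in log space); for `m > n` the
#' standard extrapolation
#' \deqn{\hat S(n + m^*) = S_{obs} + \hat f_0 [1 - (1 - f_1 / (n \hat f_0
#' + f_1))^{m^*}]} with `f0_hat = chao1(fc) - S_obs`; when `f1 = 0` the
#' curve is flat beyond `n`.
#'
#' @inheritParams chao1
#' @param m Target sample size(s), non-negative integers.
#' @return Numeric vector of expected richness values, one per `m`.
#' @examples
#' rarefaction_extrapolation(c(a = 1, b = 1), m = 0:4)
#' @export
rarefaction_extrapolation <- function(fc, m) {
  fc <- as_fc(fc)
  if (any(m < 0) || any(m != round(m))) {
    stop("`m` must contain non-negative integers")
  }
  n <- fc$n
  S <- fc$S_obs
  f1 <- f_k(fc, 1)
  f0 <- chao1(fc) - S
  ks <- which(fc$f > 0)

  vapply(as.numeric(m), function(mi) {
    if (mi == 0) return(0)
    if (mi <= n) {
      # sum_k f_k * C(n - k, mi) / C(n, mi), log-space, zero when k > n - mi
      miss <- 0
      for (k in ks) {
        if (n - k >= mi) {
          miss <- miss + fc$f[k] * exp(lchoose(n - k, mi) - lchoose(n, mi))
        }
      }
      S - miss
    } else {
      if (f1 == 0 || f0 <= 0) return(as.numeric(S))
      S + f0 * (1 - (1 - f1 / (n * f0 + f1))^(mi - n))
    }
  }, numeric(1))
}

#' Log-transformed confidence interval for Chao1
#'
#' The standard log-transformed interval for Chao-type lower-bound
#' estimators: with `T = chao1 - S_obs`, analytic variance `V` and
#' `R = exp(z * sqrt(ln(1 + V / T^2)))`, the interval is
#' `(S_obs + T/R, S_obs + T*R)`, which never drops below `S_obs`. When
#' `T = 0` the interval degenerates to `(S_obs, S_obs)`.
#'
#' @inheritParams chao1
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lcl, ucl)`.
#' @examples
#' chao1_log_ci(c(a = 1, b = 1, c = 2, d = 5))
#' @export
chao1_log_ci <- function(fc, level = 0.95) {
  fc <- as_fc(fc)
  point <- chao1(fc)
  T <- point - fc$S_obs
  if (T <= 0) return(c(lcl = fc$S_obs, ucl = fc$S_obs))
  V <- chao1_var(fc)
  z <- qnorm(1 - (1 - level) / 2)
  R <- exp(z * sqrt(log(1 + V / T^2)))
  c(lcl = fc$S_obs + T / R, ucl = fc$S_obs + T * R)
}

# estimated sample coverage from singletons and doubletons
sample_coverage <- function(fc) {
  fc <- as_fc(fc)
  n <- fc$n
  f1 <- f_k(fc, 1)
  f2 <- f_k(fc, 2)
  if (n == 0) return(0)
  if (f1 == 0) return(1)
  if (n == 1) return(0)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}

estimator_fun <- function(estimator, m = NULL) {
  switch(estimator,
    chao1 = chao1,
    ichao1 = ichao1,
    rarefaction_extrapolation = {
      if (is.null(m)) stop("`m` is required for rarefaction_extrapolation")
      function(fc) rarefaction_extrapolation(fc, m)
    },
    stop("unknown estimator: ", estimator)
  )
}

#' Bootstrap confidence interval for a richness estimator
#'
#' Builds the coverage-adjusted bootstrap assemblage: detected species
#' keep probabilities proportional to their relative frequencies scaled
#' to the estimated sample coverage
#' `C_hat = 1 - (f1/n) * (n-1) f1 / ((n-1) f1 + 2 f2)`, and
#' `f0_hat = ceiling(chao1 - S_obs)` undetected species share the
#' remaining probability `1 - C_hat` equally. `B` multinomial resamples
#' of size `n` are drawn from this assemblage, the estimator applied to
#' each, and the interval formed as `point +/- z * SD(bootstrap
#' estimates)`, truncated below at `S_obs`.
#'
#' @param abundance An [abundance_vector()] or named vector of counts.
#' @param estimator One of `"ichao1"`, `"chao1"`,
#'   `"rarefaction_extrapolation"`.
#' @param m Target sample size (only for
#'   `estimator = "rarefaction_extrapolation"`).
#' @param B Number of bootstrap resamples (>= 2).
#' @param level Confidence level.
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @return List with `point`, `se`, `lcl`, `ucl`, `level`.
#' @examples
#' av <- abundance_vector(c(a = 1, b = 1, c = 2, d = 5), "AA")
#' bootstrap_ci(av, "chao1", B = 50, seed = 1)
#' @export
bootstrap_ci <- function(abundance, estimator = c("ichao1", "chao1",
                                                  "rarefaction_extrapolation"),
                         m = NULL, B = 200, level = 0.95, seed = 1) {
  estimator <- match.arg(estimator)
  if (!is.numeric(B) || B < 2) stop("`B` must be at least 2")
  counts <- if (inherits(abundance, "abundance_vector")) abundance$counts
            else unlist(abundance)
  fc <- frequency_counts(counts)
  if (fc$n < 1) stop("empty assemblage")
  stat <- estimator_fun(estimator, m)
  point <- stat(fc)

  Chat <- sample_coverage(fc)
  f0 <- ceiling(chao1(fc) - fc$S_obs)
  p <- counts / fc$n * Chat
  if (f0 > 0) p <- c(p, rep((1 - Chat) / f0, f0))

  boots <- with_seed(seed, {
    draws <- rmultinom(B, fc$n, p)
    apply(draws, 2, function(x) stat(frequency_counts(x[x > 0])))
  })
  se <- sd(boots)
  z <- qnorm(1 - (1 - level) / 2)
  list(point = point, se = se,
       lcl = max(fc$S_obs, point - z * se),
       ucl = point + z * se, level = level)
}

#' Estimate richness with a confidence interval
#'
#' The pipeline-facing wrapper. `method = "ichao1"` reports the iChao1
#' point with a bootstrap interval; `method = "inext"` reports the
#' asymptotic Hill-number q = 0 richness estimate (the Chao1 asymptote of
#' the rarefaction-extrapolation curve) with either a bootstrap
#' (`ci = "bootstrap"`) or log-transformed analytic (`ci = "log"`)
#' interval.
#'
#' @param abundance An [abundance_vector()] or named count vector.
#' @param method `"ichao1"` or `"inext"`.
#' @param ci Interval construction; `"log"` is only available for
#'   `method = "inext"`.
#' @param B Bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return A `richness_estimate` object with fields `method`, `S_obs`,
#'   `n`, `point`, `se`, `lcl`, `ucl`, `level`; always
#'   `S_obs <= lcl <= point <= ucl`.
#' @examples
#' av <- abundance_vector(c(a = 1, b = 1, c = 2, d = 5), "AA")
#' estimate_richness(av, "inext", ci = "log")
#' @export
estimate_richness <- function(abundance, method = c("ichao1", "inext"),
                              ci = c("bootstrap", "log"), B = 200,
                              level = 0.95, seed = 1) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  counts <- if (inherits(abundance, "abundance_vector")) abundance$counts
            else unlist(abundance)
  fc <- frequency_counts(counts)
  if (method == "ichao1" && ci == "log") {
    stop("the analytic log interval is only available for method = \"inext\"")
  }
  est <- if (ci == "log") {
    bounds <- chao1_log_ci(fc, level)
    list(point = chao1(fc), se = NA_real_,
         lcl = bounds[["lcl"]], ucl = bounds[["ucl"]], level = level)
  } else {
    bootstrap_ci(abundance,
                 estimator = if (method == "ichao1") "ichao1" else "chao1",
                 B = B, level = level, seed = seed)
  }
  structure(
    list(method = method, S_obs = fc$S_obs, n = fc$n,
         point = est$point, se = est$se,
         lcl = min(max(fc$S_obs, est$lcl), est$point), ucl = est$ucl,
         level = level),
    class = "richness_estimate"
  )
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf(
    "Richness estimate [%s]: %.1f (%.0f%% CI %.1f-%.1f), S_obs = %d, n = %d\n",
    x$method, x$point, 100 * x$level, x$lcl, x$ucl, x$S_obs, x$n))
  invisible(x)
}
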