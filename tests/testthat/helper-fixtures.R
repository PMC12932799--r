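# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

# counts vector with prescribed frequency counts: f = c(f1, f2, ...)
counts_from_f <- function(f) {
  rep(seq_along(f), times = f)
}

# a small planted-defect occurrence fixture plus everything needed to
# clean it: community, checklist, resolver
make_dirty_fixture <- function(n = 400, rate = 0.03, s_true = 40,
                               seed = 101) {
  com <- generate_community(s_true, seed = seed)
  chk <- generate_checklist(com, seed = seed + 1)
  spec <- contamination_spec(
    rate_invalid_binomial = rate, rate_bad_basis = rate,
    rate_country_mismatch = rate, rate_absence = rate,
    rate_bad_license = rate, rate_off_checklist = rate
  )
  occ <- sample_occurrences(com, n, spec, seed = seed + 2)
  list(community = com, checklist = chk, occurrences = occ,
       resolver = community_resolver(com))
}

# minimal iteration summary for exercising pure summary functions
make_summary <- function(n_records, S_obs, median_point,
                         S_checklist_only = 0, region = "AA") {
  structure(
    list(region = region, method = "ichao1", R = 1L,
         median_point = median_point, median_lcl = median_point,
         median_ucl = median_point,
         per_iteration = tibble::tibble(iter = 1L, point = median_point,
                                        lcl = median_point,
                                        ucl = median_point,
                                        failed = FALSE),
         n_records = n_records, S_obs_empirical = S_obs,
         S_checklist_only = S_checklist_only, n_failed = 0L),
    class = "iteration_summary"
  )
}

# Monte-Carlo rarefaction oracle: mean species count over `reps` random
# subsamples of size m drawn without replacement
mc_rarefaction <- function(counts, m, reps = 1e4) {
  labels <- rep(seq_along(counts), times = counts)
  rich <- replicate(reps, length(unique(sample(labels, m))))
  list(mean = mean(rich), mcse = sd(rich) / sqrt(reps))
}
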