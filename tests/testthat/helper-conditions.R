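# Shared condition ensembles for the stochastic acceptance checks.  Each
# condition is simulated once per test session (10 x 10 lattices, 5-seed
# ensembles, full 120-trial training + 300-trial testing) and cached.

.cond_cache <- new.env(parent = emptyenv())

acceptance_run <- function(name, seeds = 1:5, shape = 10L) {
  key <- name
  if (!is.null(.cond_cache[[key]])) return(.cond_cache[[key]])
  preset <- switch(name,
                   dbs_pos1 = ,
                   dbs_pos3 = ,
                   dbs_anti10 = "dbs",
                   name)
  over <- switch(name,
                 dbs_pos1 = list(dbs = list(position_preset = "pos1")),
                 dbs_pos3 = list(dbs = list(position_preset = "pos3")),
                 dbs_anti10 = list(dbs = list(position_preset = "pos2",
                                              antidromic_fraction = 0.10)),
                 list())
  cond <- bg_condition(preset, shape = shape, overrides = over)
  res <- run_condition(cond, plt_task(), seeds = seeds)
  assign(key, res, envir = .cond_cache)
  res
}

# Seed-ensemble check: the ensemble mean must lie within two ensemble
# standard deviations of the reference value.
expect_within_2sd <- function(per_seed, target) {
  m <- mean(per_seed)
  s <- sd(per_seed)
  expect_lte(abs(m - target), 2 * s + 1e-6,
             label = sprintf("|mean %.3f - target %.3f| (2 SD = %.3f)",
                             m, target, 2 * s))
}

per_seed_rt <- function(res, conflict = "LC", correct = TRUE) {
  vapply(res$runs, function(r) {
    d <- rt_by_conflict(r$test_log)
    row <- d[d$conflict == conflict & d$correct == correct, ]
    if (nrow(row)) row$mean_rt else NA_real_
  }, numeric(1))
}
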