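test_that("training-accuracy bins match a hand tally", {
  # all-correct log
  log <- script_log("train", rep(c("AB", "CD", "EF"), each = 10),
                    rep(c("A", "C", "E"), each = 10), correct = TRUE)
  bins <- training_accuracy_bins(log, plt_task(trials_per_pair = 10))
  expect_true(all(bins$accuracy == 1))
  expect_equal(nrow(bins), 15)
  expect_true(all(bins$n == 2))

  # alternating selections: every bin at 0.5
  log <- script_log("train", rep("AB", 40), rep(c("A", "B"), 20),
                    correct = rep(c(TRUE, FALSE), 20))
  bins <- training_accuracy_bins(log, plt_task())
  expect_true(all(bins$accuracy[bins$pair == "AB"] == 0.5))

  # scripted counts: first 8 trials 6 correct, last 8 trials 8 correct
  correct <- c(rep(TRUE, 6), FALSE, FALSE, rep(TRUE, 24), rep(TRUE, 8))
  log <- script_log("train", rep("AB", 40),
                    ifelse(correct, "A", "B"), correct = correct)
  bins <- training_accuracy_bins(log, plt_task())
  expect_equal(bins$accuracy[bins$bin == 1], 0.75)
  expect_equal(bins$accuracy[bins$bin == 5], 1)
})

test_that("a-priori selection probabilities and DRE behave as ratios", {
  sel <- c(rep("A", 32), rep("B", 8))
  log <- script_log("train", rep("AB", 40), sel)
  d <- compute_dre(log, task = plt_task())
  expect_equal(unname(d$p_select["A"]), 0.8)
  expect_equal(unname(d$p_select["B"]), 0.2)
  expect_equal(unname(d$dre["AB"]), 0.6)

  # antisymmetry: flipping the pair order flips the sign
  expect_equal(unname(d$dre["AB"]),
               -unname(compute_dre(log, pairs = "BA",
                                   task = plt_task())$dre))

  # equal selection probabilities give zero DRE
  log2 <- rbind(script_log("train", rep("BC", 20),
                           rep(c("B", "C"), 10)))
  d2 <- compute_dre(log2, task = plt_task())
  expect_equal(unname(d2$dre["BC"]), 0)
  # DRE always lies in [-1, 1]
  expect_true(all(abs(d$dre) <= 1, na.rm = TRUE))
})

test_that("testing accuracy is the first-card selection fraction", {
  log <- script_log("test", rep("AC", 20), c(rep("A", 16), rep("C", 4)))
  expect_equal(unname(testing_accuracy(log)["AC"]), 0.8)
  log0 <- script_log("test", rep("BD", 20), rep("D", 20))
  expect_equal(unname(testing_accuracy(log0)["BD"]), 0)
  log1 <- script_log("test", rep("CE", 20), rep("C", 20))
  expect_equal(unname(testing_accuracy(log1)["CE"]), 1)
})

test_that("choose-A / avoid-B percentages match hand counts", {
  a_pairs <- rep(c("AC", "AD", "AE", "AF"), each = 5)
  b_pairs <- rep(c("BC", "BD", "BE", "BF"), each = 5)
  # A always chosen, B always chosen
  log <- rbind(script_log("test", a_pairs, rep("A", 20)),
               script_log("test", b_pairs, rep("B", 20)))
  ca <- choice_avoidance(log)
  expect_equal(unname(ca["choose_A_pct"]), 100)
  expect_equal(unname(ca["avoid_B_pct"]), 0)

  # scripted mixture: A chosen 15/20; B avoided 12/20; AB rows excluded
  sel_a <- c(rep("A", 15), substr(a_pairs[16:20], 2, 2))
  sel_b <- c(rep("B", 8), substr(b_pairs[9:20], 2, 2))
  log <- rbind(script_log("test", a_pairs, sel_a),
               script_log("test", b_pairs, sel_b),
               script_log("test", rep("AB", 10), rep("B", 10)))
  ca <- choice_avoidance(log)
  expect_equal(unname(ca["choose_A_pct"]), 75)
  expect_equal(unname(ca["avoid_B_pct"]), 60)
})

test_that("RT summaries group by conflict and correctness", {
  log <- rbind(
    script_log("test", rep("BC", 4), rep("C", 4), correct = TRUE,
               rt = c(1000, 1200, 1400, 1600), conflict = "LC"),
    script_log("test", rep("AC", 2), rep("A", 2), correct = TRUE,
               rt = c(2000, 2200), conflict = "HC"),
    script_log("test", "AC", "C", correct = FALSE, rt = 500,
               conflict = "HC"))
  rt <- rt_by_conflict(log)
  lc <- rt[rt$conflict == "LC" & rt$correct, ]
  expect_equal(lc$mean_rt, 1300)
  expect_equal(lc$sd_rt, sd(c(1000, 1200, 1400, 1600)))
  hc_err <- rt[rt$conflict == "HC" & !rt$correct, ]
  expect_equal(hc_err$mean_rt, 500)
  expect_equal(hc_err$sd_rt, 0)  # single-trial group
  # empty groups are absent, not zero
  expect_false(any(rt$conflict == "LC" & !rt$correct))

  # censored trials are excluded by default but counted
  log$censored[1] <- TRUE
  rt2 <- rt_by_conflict(log)
  lc2 <- rt2[rt2$conflict == "LC" & rt2$correct, ]
  expect_equal(lc2$mean_rt, 1400)
  expect_equal(lc2$n_censored, 1)
  rt3 <- rt_by_conflict(log, include_censored = TRUE)
  expect_equal(rt3[rt3$conflict == "LC" & rt3$correct, "mean_rt"], 1300)
})

test_that("accuracy-DRE regression matches closed-form least squares", {
  # exact line: R = 1
  x <- seq(-0.8, 0.8, length.out = 15)
  fit <- fit_accuracy_vs_dre(x, 0.5 + 0.4 * x, order = 1)
  expect_equal(fit$R, 1)
  expect_equal(fit$coefficients, c(0.5, 0.4))

  # noisy 15-point set against the normal equations
  set.seed(77)
  y <- 0.5 + 0.4 * x + rnorm(15, 0, 0.08)
  fit <- fit_accuracy_vs_dre(x, y, order = 1)
  expect_equal(fit$coefficients, ref_ols(x, y, 1), tolerance = 1e-8)
  expect_equal(fit$R, abs(cor(x, y)))

  # higher orders agree with the closed form too
  y2 <- 0.5 + 0.3 * x - 0.6 * x^2 + rnorm(15, 0, 0.05)
  fit2 <- fit_accuracy_vs_dre(x, y2, order = 2)
  expect_equal(fit2$coefficients, ref_ols(x, y2, 2), tolerance = 1e-6)

  # R is invariant to affine rescaling of DRE
  fit3 <- fit_accuracy_vs_dre(0.3 * x + 5, y, order = 1)
  expect_equal(fit3$R, fit$R)

  # constant accuracies: degenerate fit flagged with R = 0
  fitc <- fit_accuracy_vs_dre(x, rep(0.7, 15), order = 1)
  expect_true(fitc$degenerate)
  expect_equal(fitc$R, 0)

  expect_error(fit_accuracy_vs_dre(x[1:2], y[1:2], order = 1),
               "at least")
})

test_that("ensemble aggregation is consistent with per-seed metrics", {
  cond <- tiny_condition(shape = 4L, race = list(t_max_ms = 300))
  task <- plt_task(trials_per_pair = 5, test_reps = 2)
  res <- run_condition(cond, task, seeds = 1:2)
  s <- res$summary
  expect_equal(s$n_seeds, 2)
  ca <- sapply(res$runs, function(r) choice_avoidance(r$test_log))
  expect_equal(s$choose_A_pct, mean(ca["choose_A_pct", ]))
  expect_equal(s$avoid_B_pct, mean(ca["avoid_B_pct", ]))
  expect_true(all(s$training_curve$accuracy >= 0 &
                    s$training_curve$accuracy <= 1))
  expect_true(all(abs(s$dre) <= 1))
})
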