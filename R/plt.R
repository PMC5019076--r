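#' Probabilistic learning task specification
#'
#' Six choices A..F with reward probabilities 0.8/0.2 (AB), 0.7/0.3 (CD)
#' and 0.6/0.4 (EF).  Training presents the three fixed pairs 40 times
#' each (120 trials) in shuffled order with +1/-1 Bernoulli feedback;
#' testing presents all 15 unordered pairs 20 times each with frozen
#' weights and no feedback.
#'
#' @param reward_probs named reward probabilities per choice.
#' @param trained_pairs the training pairs.
#' @param trials_per_pair training presentations per pair.
#' @param test_reps testing presentations per pair.
#' @param n_bins bins for the training-accuracy curve.
#' @param exclude_trained_pairs drop AB/CD/EF from the test schedule
#'   (default keeps all 15 pairs, tagging the trained ones).
#' @return A list of class `bg_task`.
#' @export
plt_task <- function(reward_probs = c(A = 0.8, B = 0.2, C = 0.7, D = 0.3,
                                      E = 0.6, F = 0.4),
                     trained_pairs = c("AB", "CD", "EF"),
                     trials_per_pair = 40, test_reps = 20, n_bins = 5,
                     exclude_trained_pairs = FALSE) {
  stopifnot(all(reward_probs >= 0 & reward_probs <= 1))
  structure(list(reward_probs = reward_probs,
                 trained_pairs = trained_pairs,
                 trials_per_pair = trials_per_pair,
                 test_reps = test_reps, n_bins = n_bins,
                 exclude_trained_pairs = exclude_trained_pairs),
            class = "bg_task")
}

#' All unordered pairs of the six choices, canonical (alphabetical) order
#' @param task a `bg_task`.
#' @return Character vector of 15 pairs.
#' @export
all_pairs <- function(task = plt_task()) {
  cards <- names(task$reward_probs)
  as.character(combn(cards, 2, paste0, collapse = ""))
}

#' Shuffled training schedule
#'
#' Exactly `trials_per_pair` occurrences of each trained pair, uniformly
#' shuffled.
#'
#' @param task a `bg_task`.
#' @return Character vector of pairs, one per trial.
#' @export
training_schedule <- function(task = plt_task()) {
  sample(rep(task$trained_pairs, each = task$trials_per_pair))
}

#' Draw the Bernoulli reward of a selected choice
#'
#' @param choice selected choice name.
#' @param task a `bg_task`.
#' @return +1 with the choice's reward probability, otherwise -1.
#' @export
draw_reward <- function(choice, task = plt_task()) {
  p <- unname(task$reward_probs[choice])
  if (length(p) != 1 || is.na(p))
    stop(sprintf("unknown choice '%s'", choice), call. = FALSE)
  if (runif(1) < p) 1 else -1
}

#' Conflict label of a stimulus pair
#'
#' High conflict (HC) when both choices lie on the same side of reward
#' probability 0.5 (win-win or lose-lose), low conflict (LC) otherwise.
#'
#' @param pair two-character pair, e.g. `"AC"`.
#' @param task a `bg_task`.
#' @return `"HC"` or `"LC"`.
#' @examples
#' classify_conflict("AC")  # HC: 0.8 vs 0.7
#' classify_conflict("BC")  # LC: 0.2 vs 0.7
#' @export
classify_conflict <- function(pair, task = plt_task()) {
  cards <- strsplit(pair, "")[[1]]
  p <- task$reward_probs[cards]
  if (any(is.na(p))) stop(sprintf("unknown pair '%s'", pair), call. = FALSE)
  if (all(p >= 0.5) || all(p < 0.5)) "HC" else "LC"
}

#' Simulate one decision trial of the spiking network
#'
#' Drives the striatum with the pair's D1/D2 Poisson rates, steps the
#' three coupled lattices together with the mutual-inhibition race until
#' a threshold crossing (or the censoring horizon `t_max_ms`), and
#' returns the selected choice and reaction time.  All neuronal state is
#' reset at trial start.
#'
#' @param cond a [bg_condition()].
#' @param pair the presented pair.
#' @param weights current cortico-striatal weights.
#' @param core optional pre-built core configuration (internal reuse).
#' @param collect optional list of extra recordings (`rasters`,
#'   `stn_pop`, `gpi_half_steps`, `vtrace`, `ztrace`).
#' @return A list with `selected` (choice name), `rt_ms`, `censored`,
#'   plus the raw core output in `raw`.
#' @export
run_trial <- function(cond, pair, weights, core = NULL, collect = list()) {
  if (is.null(core)) core <- .core_config(cond)
  drive <- msn_rates(weights, pair)
  cards <- drive$cards
  rates <- drive$rates
  if (identical(cond$side_assignment, "random") && runif(1) < 0.5) {
    cards <- rev(cards)
    rates <- rates[c(2, 1, 4, 3)]
  }
  if (any(rates * cond$dt / 1000 > 1))
    stop("striatal rate * dt exceeds one spike per step", call. = FALSE)
  col <- modifyList(list(rasters = FALSE, stn_pop = FALSE,
                         gpi_half_steps = FALSE, vtrace = FALSE,
                         ztrace = FALSE), collect)
  raw <- cpp_run_trial(core, rates, NULL, NULL, col)
  list(selected = cards[raw$choice], cards = cards,
       rt_ms = raw$rt_ms, censored = raw$censored, raw = raw)
}

.empty_log <- function() {
  data.frame(phase = character(), trial = integer(), pair = character(),
             first_card = character(), selected = character(),
             correct = logical(), reward = numeric(), delta = numeric(),
             delta_d1 = numeric(), delta_d2 = numeric(),
             rt_ms = numeric(), censored = logical(),
             conflict = character(), trained_pair = logical(),
             stringsAsFactors = FALSE)
}

.is_correct <- function(selected, pair, task) {
  cards <- strsplit(pair, "")[[1]]
  p <- task$reward_probs[cards]
  selected == cards[which.max(p)]
}

#' Run the training phase of the probabilistic learning task
#'
#' 120 trials (40 per trained pair, shuffled): on every trial the spiking
#' network selects a choice, a Bernoulli reward is drawn, the TD error is
#' computed and passed through the condition's dopamine policy, and the
#' selected choice's D1/D2 cortico-striatal weights are updated.
#'
#' @param cond a [bg_condition()].
#' @param task a [plt_task()].
#' @param seed integer seed; the full run is replayable from it.
#' @param weights optional initial weights (default: fresh uniform(0, 1)).
#' @return A list with the final `weights`, the trial `log`, and
#'   `weight_history` (121 x 12 matrix of wD1/wD2 trajectories, initial
#'   state first).
#' @export
run_training <- function(cond, task = plt_task(), seed = NULL,
                         weights = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- init_weights()
  core <- .core_config(cond)
  schedule <- training_schedule(task)
  log <- vector("list", length(schedule))
  hist <- matrix(NA_real_, length(schedule) + 1, 12,
                 dimnames = list(NULL, c(paste0("wD1_", LETTERS[1:6]),
                                         paste0("wD2_", LETTERS[1:6]))))
  hist[1, ] <- c(weights$wD1, weights$wD2)
  for (k in seq_along(schedule)) {
    pair <- schedule[k]
    res <- run_trial(cond, pair, weights, core = core)
    sel <- res$selected
    reward <- draw_reward(sel, task)
    delta <- td_error(reward, weights$wD1, sel)
    d_eff <- condition_delta(delta, cond$dopamine)
    weights <- update_weights(weights, d_eff, sel, cond$dopamine$eta,
                              mask = cond$update_mask,
                              presented = res$cards)
    hist[k + 1, ] <- c(weights$wD1, weights$wD2)
    log[[k]] <- data.frame(phase = "train", trial = k, pair = pair,
                           first_card = res$cards[1], selected = sel,
                           correct = .is_correct(sel, pair, task),
                           reward = reward, delta = delta,
                           delta_d1 = d_eff[["d1"]],
                           delta_d2 = d_eff[["d2"]], rt_ms = res$rt_ms,
                           censored = res$censored,
                           conflict = classify_conflict(pair, task),
                           trained_pair = TRUE, stringsAsFactors = FALSE)
  }
  list(weights = weights, log = do.call(rbind, log),
       weight_history = hist)
}

#' Run the testing phase with frozen weights
#'
#' Presents the 15 unordered pairs of A..F `test_reps` times each in
#' shuffled order.  No feedback is delivered and no weight update is
#' applied; the TD error is logged for inspection only.  The within-pair
#' presentation order (which card is "first") is randomized per trial and
#' logged.
#'
#' @inheritParams run_training
#' @param weights the trained (frozen) cortico-striatal weights.
#' @return The test-phase trial log.
#' @export
run_testing <- function(cond, task = plt_task(), weights, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  core <- .core_config(cond)
  pairs <- all_pairs(task)
  if (task$exclude_trained_pairs)
    pairs <- setdiff(pairs, task$trained_pairs)
  schedule <- sample(rep(pairs, each = task$test_reps))
  log <- vector("list", length(schedule))
  for (k in seq_along(schedule)) {
    pair <- schedule[k]
    res <- run_trial(cond, pair, weights, core = core)
    sel <- res$selected
    first <- if (runif(1) < 0.5) res$cards[1] else res$cards[2]
    delta <- td_error(1, weights$wD1, sel) - 1  # value term only, no reward
    log[[k]] <- data.frame(phase = "test", trial = k, pair = pair,
                           first_card = first, selected = sel,
                           correct = .is_correct(sel, pair, task),
                           reward = NA_real_, delta = delta,
                           delta_d1 = NA_real_, delta_d2 = NA_real_,
                           rt_ms = res$rt_ms, censored = res$censored,
                           conflict = classify_conflict(pair, task),
                           trained_pair = pair %in% task$trained_pairs,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, log)
}

#' Run one full seeded experiment (training + testing)
#'
#' @inheritParams run_training
#' @return A list with `weights`, `train_log`, `test_log`,
#'   `weight_history` and the `seed`.
#' @export
run_plt <- function(cond, task = plt_task(), seed = 1) {
  set.seed(seed)
  tr <- run_training(cond, task)
  te <- run_testing(cond, task, tr$weights)
  list(weights = tr$weights, train_log = tr$log, test_log = te,
       weight_history = tr$weight_history, seed = seed)
}

#' Run a condition over an ensemble of seeds
#'
#' Repeats the full train/test experiment once per seed and aggregates
#' the performance measures (see [task_results()]).
#'
#' @inheritParams run_training
#' @param seeds integer vector of seeds.
#' @param progress print one line per completed seed.
#' @return An object of class `bg_results`: `runs` (per-seed outputs),
#'   `summary` (aggregated [task_results()]), `condition`, `task`.
#' @export
run_condition <- function(cond, task = plt_task(), seeds = 1:10,
                          progress = FALSE) {
  runs <- lapply(seeds, function(s) {
    r <- run_plt(cond, task, seed = s)
    if (progress) message(sprintf("  [%s] seed %d done", cond$mode, s))
    r
  })
  structure(list(runs = runs, summary = task_results(runs, task),
                 condition = cond, task = task, seeds = seeds),
            class = "bg_results")
}

#' @export
print.bg_results <- function(x, ...) {
  s <- x$summary
  cat("<bg_results>", x$condition$mode, sprintf("(%d seeds)\n",
                                                length(x$runs)))
  cat(sprintf("  final-bin training accuracy: %s\n",
              paste(sprintf("%s=%.2f", names(s$final_bin_accuracy),
                            s$final_bin_accuracy), collapse = " ")))
  cat(sprintf("  choose-A %.1f%%, avoid-B %.1f%%\n",
              s$choose_A_pct, s$avoid_B_pct))
  lc <- mean_rt(s, "LC", TRUE)
  hc <- mean_rt(s, "HC", TRUE)
  if (!is.na(lc) && !is.na(hc))
    cat(sprintf("  LC-correct RT %.0f ms, HC-correct RT %.0f ms\n", lc, hc))
  cat(sprintf("  accuracy~DRE linear fit R = %.2f\n", s$dre_fit_R))
  invisible(x)
}
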