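#' Binned training-accuracy curve
#'
#' Splits each trained pair's 40 presentations into `n_bins` consecutive
#' equal bins and reports the fraction of presentations per bin on which
#' the higher-reward-probability card was chosen.
#'
#' @param log a training trial log from [run_training()].
#' @param task a [plt_task()].
#' @return A data.frame with `pair`, `bin`, `accuracy`, `n`.
#' @export
training_accuracy_bins <- function(log, task = plt_task()) {
  log <- log[log$phase == "train", ]
  out <- list()
  for (pair in task$trained_pairs) {
    rows <- log[log$pair == pair, ]
    m <- nrow(rows)
    if (m == 0) next
    bin <- ceiling(seq_len(m) / (m / task$n_bins))
    acc <- tapply(rows$correct, bin, mean)
    out[[pair]] <- data.frame(pair = pair,
                              bin = as.integer(names(acc)),
                              accuracy = as.numeric(acc),
                              n = as.integer(table(bin)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' A-priori selection probabilities and difference in reward expectation
#'
#' From the training log, `P(card) = (# selected) / (# presented)`.  The
#' DRE of a pair is the difference of its two cards' probabilities
#' (first minus second in the pair's written order), a signed measure of
#' how separable the two options became during training.
#'
#' @param log training trial log.
#' @param pairs pairs for which to compute DRE (default: all 15, in
#'   canonical order).
#' @param task a [plt_task()].
#' @return A list with `p_select` (named per-card probabilities) and
#'   `dre` (named per-pair values).
#' @export
compute_dre <- function(log, pairs = NULL, task = plt_task()) {
  log <- log[log$phase == "train", ]
  cards <- names(task$reward_probs)
  if (is.null(pairs)) pairs <- all_pairs(task)
  presented <- setNames(numeric(length(cards)), cards)
  selected <- presented
  for (card in cards) {
    presented[card] <- sum(grepl(card, log$pair, fixed = TRUE))
    selected[card] <- sum(log$selected == card)
  }
  p <- ifelse(presented > 0, selected / presented, NA_real_)
  names(p) <- cards
  dre <- vapply(pairs, function(pr) {
    cs <- strsplit(pr, "")[[1]]
    p[[cs[1]]] - p[[cs[2]]]
  }, numeric(1))
  list(p_select = p, dre = dre)
}

#' Per-pair testing accuracy
#'
#' Fraction of a pair's test presentations on which its first card (in
#' the pair's canonical written order) was selected.
#'
#' @param log test trial log.
#' @param task a [plt_task()].
#' @return Named numeric vector over the tested pairs.
#' @export
testing_accuracy <- function(log, task = plt_task()) {
  log <- log[log$phase == "test", ]
  pairs <- sort(unique(log$pair))
  vapply(setNames(pairs, pairs), function(pr) {
    rows <- log[log$pair == pr, ]
    first <- substr(pr, 1, 1)
    mean(rows$selected == first)
  }, numeric(1))
}

#' Choose-A and avoid-B accuracy
#'
#' Reward-learning and punishment-learning scores over the novel test
#' pairs: the percentage of A-containing presentations on which A was
#' selected, and of B-containing presentations on which B was *not*
#' selected.  The trained pair AB is excluded from both.
#'
#' @param log test trial log.
#' @return `c(choose_A_pct = , avoid_B_pct = )`.
#' @export
choice_avoidance <- function(log) {
  log <- log[log$phase == "test" & log$pair != "AB", ]
  a_rows <- log[grepl("A", log$pair, fixed = TRUE), ]
  b_rows <- log[grepl("B", log$pair, fixed = TRUE), ]
  c(choose_A_pct = 100 * mean(a_rows$selected == "A"),
    avoid_B_pct = 100 * mean(b_rows$selected != "B"))
}

#' Reaction-time summary by conflict and correctness
#'
#' Mean and standard deviation of reaction times grouped by conflict
#' label (LC/HC) and correctness.  Censored trials (no threshold
#' crossing before the horizon) are excluded by default and counted
#' separately; groups without trials are absent from the output rather
#' than reported as zero.
#'
#' @param log test trial log.
#' @param include_censored include censored trials at the horizon RT.
#' @return A data.frame with `conflict`, `correct`, `mean_rt`, `sd_rt`,
#'   `n`, `n_censored`.
#' @export
rt_by_conflict <- function(log, include_censored = FALSE) {
  log <- log[log$phase == "test", ]
  out <- list()
  for (conf in c("LC", "HC")) {
    for (corr in c(TRUE, FALSE)) {
      rows <- log[log$conflict == conf & log$correct == corr, ]
      n_cens <- sum(rows$censored)
      if (!include_censored) rows <- rows[!rows$censored, ]
      if (nrow(rows) == 0) next
      out[[paste(conf, corr)]] <- data.frame(
        conflict = conf, correct = corr, mean_rt = mean(rows$rt_ms),
        sd_rt = if (nrow(rows) > 1) sd(rows$rt_ms) else 0,
        n = nrow(rows), n_censored = n_cens)
    }
  }
  if (!length(out))
    return(data.frame(conflict = character(), correct = logical(),
                      mean_rt = numeric(), sd_rt = numeric(),
                      n = integer(), n_censored = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Least-squares polynomial fit of testing accuracy on DRE
#'
#' Fits accuracy as a polynomial in DRE of the requested order and
#' reports the goodness of fit R as the correlation between fitted and
#' observed accuracies (for order 1 this equals the absolute Pearson
#' correlation).  Degenerate inputs with zero variance in either
#' variable return `R = 0` with `degenerate = TRUE`.
#'
#' @param dre per-pair DRE values.
#' @param accuracy per-pair testing accuracies (same order).
#' @param order polynomial order (1, 2 or 5).
#' @return `list(coefficients, R, order, degenerate, fitted)`.
#' @export
fit_accuracy_vs_dre <- function(dre, accuracy, order = 1) {
  stopifnot(length(dre) == length(accuracy))
  ok <- is.finite(dre) & is.finite(accuracy)
  dre <- dre[ok]; accuracy <- accuracy[ok]
  if (length(dre) < order + 2)
    stop("fit_accuracy_vs_dre: need at least order + 2 points",
         call. = FALSE)
  if (sd(dre) == 0 || sd(accuracy) == 0) {
    return(list(coefficients = c(mean(accuracy), rep(0, order)), R = 0,
                order = order, degenerate = TRUE,
                fitted = rep(mean(accuracy), length(accuracy))))
  }
  fit <- lm(accuracy ~ poly(dre, order, raw = TRUE))
  fv <- fitted(fit)
  R <- if (sd(fv) == 0) 0 else cor(fv, accuracy)
  list(coefficients = unname(coef(fit)), R = R, order = order,
       degenerate = FALSE, fitted = unname(fv))
}

#' Aggregate performance measures over an ensemble of runs
#'
#' Combines per-seed train/test logs into the study's performance
#' measures: the binned training-accuracy curves (mean and standard
#' error over seeds), the final-bin selection probabilities P(A)/P(C)/
#' P(E), per-pair testing accuracy and DRE, choose-A/avoid-B
#' percentages, RT summaries by conflict and correctness, and the
#' accuracy-versus-DRE linear fit (per-seed R, averaged).
#'
#' @param runs list of per-seed outputs from [run_plt()].
#' @param task a [plt_task()].
#' @return A list of class `task_results`.
#' @export
task_results <- function(runs, task = plt_task()) {
  n_seeds <- length(runs)
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0

  bins <- lapply(runs, function(r) training_accuracy_bins(r$train_log, task))
  bin_df <- do.call(rbind, bins)
  curve <- do.call(rbind, lapply(split(bin_df, list(bin_df$pair,
                                                    bin_df$bin)),
                                 function(d) data.frame(
                                   pair = d$pair[1], bin = d$bin[1],
                                   accuracy = mean(d$accuracy),
                                   se = se(d$accuracy))))
  curve <- curve[order(curve$pair, curve$bin), ]
  rownames(curve) <- NULL

  final_bin <- sapply(task$trained_pairs, function(pr) {
    sapply(bins, function(b)
      b$accuracy[b$pair == pr & b$bin == task$n_bins])
  })
  final_bin <- rbind(final_bin)
  colnames(final_bin) <- substr(task$trained_pairs, 1, 1)
  final_acc <- colMeans(final_bin)

  ca <- t(sapply(runs, function(r) choice_avoidance(r$test_log)))
  dre_mat <- t(sapply(runs, function(r)
    compute_dre(r$train_log, task = task)$dre))
  acc_mat <- t(sapply(runs, function(r) testing_accuracy(r$test_log, task)))
  fit_R <- vapply(seq_len(n_seeds), function(i) {
    common <- intersect(colnames(dre_mat), colnames(acc_mat))
    fit_accuracy_vs_dre(dre_mat[i, common], acc_mat[i, common], 1)$R
  }, numeric(1))

  rts <- do.call(rbind, lapply(seq_along(runs), function(i) {
    d <- rt_by_conflict(runs[[i]]$test_log)
    if (nrow(d)) d$seed_idx <- i
    d
  }))
  rt_summary <- if (!is.null(rts) && nrow(rts)) {
    agg <- split(rts, list(rts$conflict, rts$correct), drop = TRUE)
    do.call(rbind, lapply(agg, function(d) data.frame(
      conflict = d$conflict[1], correct = d$correct[1],
      mean_rt = mean(d$mean_rt), sd_rt = mean(d$sd_rt),
      se_rt = se(d$mean_rt), n = sum(d$n))))
  } else data.frame(conflict = character(), correct = logical(),
                    mean_rt = numeric(), sd_rt = numeric(),
                    se_rt = numeric(), n = integer())
  rownames(rt_summary) <- NULL

  structure(list(
    n_seeds = n_seeds,
    training_curve = curve,
    final_bin_accuracy = final_acc,
    final_bin_accuracy_se = apply(final_bin, 2, se),
    final_bin_accuracy_per_seed = final_bin,
    testing_accuracy = colMeans(acc_mat),
    dre = colMeans(dre_mat),
    choose_A_pct = mean(ca[, "choose_A_pct"]),
    choose_A_se = se(ca[, "choose_A_pct"]),
    avoid_B_pct = mean(ca[, "avoid_B_pct"]),
    avoid_B_se = se(ca[, "avoid_B_pct"]),
    choose_avoid_per_seed = ca,
    rt_summary = rt_summary,
    dre_fit_R = mean(fit_R),
    dre_fit_R_per_seed = fit_R), class = "task_results")
}

#' Mean reaction time of one conflict/correctness cell across seeds
#'
#' @param results a `bg_results` or `task_results` object.
#' @param conflict `"LC"` or `"HC"`.
#' @param correct logical.
#' @return Mean RT in ms (NA when the cell is empty).
#' @export
mean_rt <- function(results, conflict = "LC", correct = TRUE) {
  s <- if (inherits(results, "bg_results")) results$summary else results
  d <- s$rt_summary
  row <- d[d$conflict == conflict & d$correct == correct, ]
  if (nrow(row) == 0) NA_real_ else row$mean_rt
}
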