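#' Initialize cortico-striatal weights
#'
#' Each of the six choices A..F carries a D1 and a D2 weight, initialized
#' from a uniform distribution over (0, 1).
#'
#' @return `list(wD1, wD2)` of named numeric vectors over A..F.
#' @export
init_weights <- function() {
  cards <- LETTERS[1:6]
  list(wD1 = setNames(runif(6), cards), wD2 = setNames(runif(6), cards))
}

#' Temporal-difference error of a trial
#'
#' The value of the trial is the D1 cortico-striatal weight of the selected
#' choice, the outcome is the delivered reward (+1/-1), and the TD error —
#' the model's stand-in for phasic dopamine — is their difference
#' `delta = Re - V`.
#'
#' @param reward delivered reward, +1 or -1.
#' @param wD1 named D1 weight vector over the six choices.
#' @param selection binary selection vector over the six choices (exactly
#'   one 1), or the name of the selected choice.
#' @return `delta`, a single number.
#' @examples
#' td_error(+1, c(A = 0.3, B = 0, C = 0, D = 0, E = 0, F = 0), "A")  # 0.7
#' @export
td_error <- function(reward, wD1, selection) {
  if (is.character(selection)) {
    sel <- selection
    if (length(sel) != 1 || !sel %in% names(wD1))
      stop("td_error: exactly one valid choice must be selected",
           call. = FALSE)
  } else {
    if (sum(selection != 0) != 1)
      stop("td_error: selection vector must contain exactly one selection",
           call. = FALSE)
    sel <- names(wD1)[which(selection != 0)]
  }
  if (!reward %in% c(-1, 1))
    stop("td_error: reward must be +1 or -1", call. = FALSE)
  as.numeric(reward - wD1[[sel]])
}

#' Condition-specific dopamine handling of the TD error
#'
#' Applies the dopamine policy of the simulated condition to the raw TD
#' error and returns the effective error for the D1 and D2 update
#' channels:
#'
#' * `NORMAL` — no clamp, both channels receive `delta`.
#' * `PD_OFF` — dopaminergic cell loss: both channels receive
#'   `min(delta, da_ceil)` (ceiling -0.1).
#' * `PD_ON_LDOPA` — medication adds `delta_med` (+2) to the clamped
#'   error on both channels.
#' * `PD_ON_DAA` — the dopamine agonist acts on D2 receptors only: the
#'   D2 channel receives the medicated error, the D1 channel stays at the
#'   PD clamp.
#'
#' The DBS condition uses the `PD_OFF` policy.
#'
#' @param delta raw TD error.
#' @param policy dopamine policy list with `mode`, `da_ceil`, `delta_med`
#'   (e.g. `cond$dopamine`).
#' @return Named vector `c(d1 = , d2 = )` of effective errors.
#' @examples
#' condition_delta(0.7, list(mode = "PD_OFF", da_ceil = -0.1, delta_med = 2))
#' @export
condition_delta <- function(delta, policy) {
  clamped <- min(delta, policy$da_ceil)
  medicated <- clamped + policy$delta_med
  switch(policy$mode,
         NORMAL = c(d1 = delta, d2 = delta),
         PD_OFF = c(d1 = clamped, d2 = clamped),
         PD_ON_LDOPA = c(d1 = medicated, d2 = medicated),
         PD_ON_DAA = c(d1 = clamped, d2 = medicated),
         stop(sprintf("unknown dopamine mode '%s'", policy$mode),
              call. = FALSE))
}

#' Update the cortico-striatal weights after a trial
#'
#' The D1 weight of the credited choice moves with the effective TD error
#' and the D2 weight against it: `wD1 <- wD1 + eta * delta_d1`,
#' `wD2 <- wD2 - eta * delta_d2`.  By default only the selected choice is
#' credited; `mask = "input"` applies the update to both presented choices
#' (the literal reading of the update rule).  Weights are not clipped.
#'
#' @param weights `list(wD1, wD2)` as from [init_weights()].
#' @param delta_eff effective error pair from [condition_delta()].
#' @param selected name of the selected choice.
#' @param eta learning rate (> 0).
#' @param mask `"selected"` or `"input"`.
#' @param presented both presented choices (required for `mask = "input"`).
#' @return The updated weights list.
#' @export
update_weights <- function(weights, delta_eff, selected, eta = 0.1,
                           mask = c("selected", "input"), presented = NULL) {
  mask <- match.arg(mask)
  if (eta < 0) stop("update_weights: eta must be >= 0", call. = FALSE)
  targets <- if (mask == "selected") selected else {
    if (is.null(presented))
      stop("update_weights: mask = 'input' requires 'presented'",
           call. = FALSE)
    presented
  }
  weights$wD1[targets] <- weights$wD1[targets] + eta * delta_eff[["d1"]]
  weights$wD2[targets] <- weights$wD2[targets] - eta * delta_eff[["d2"]]
  weights
}
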