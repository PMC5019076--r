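#' Normalized, reversed GPi drive of the two choices
#'
#' Converts cumulative GPi spiking into the race-model input: for choice k,
#' `f'_k` is the cumulative spike count of that choice's lattice half
#' divided by (neurons in the half x elapsed time), `f_max` the highest
#' cumulative per-neuron rate over all GPi neurons, and the drive is the
#' reversed ratio `f_k = (f_max - f'_k) / f_max`, so lower GPi activity
#' yields a higher drive.  A silent lattice (`f_max = 0`) gives zero drive
#' to both choices.
#'
#' @param cum_counts cumulative spike count per GPi neuron (vector or
#'   matrix), or a steps x neurons 0/1 raster.
#' @param partition half label (1 or 2) per neuron; must cover the lattice.
#' @param t elapsed time, ms (> 0).
#' @return A list with `f_prime` (per-choice mean rates, spikes/ms),
#'   `f_max` and `f` (the drives, in `[0, 1]`).
#' @export
gpi_choice_drive <- function(cum_counts, partition, t) {
  if (t <= 0) stop("gpi_choice_drive: t must be positive", call. = FALSE)
  if (is.matrix(cum_counts) && nrow(cum_counts) > 1 &&
      length(partition) == ncol(cum_counts) &&
      length(partition) != length(cum_counts))
    cum_counts <- colSums(cum_counts)  # raster -> per-neuron totals
  cum <- as.numeric(cum_counts)
  part <- as.integer(partition)
  if (length(part) != length(cum) || !all(part %in% c(1L, 2L)))
    stop("gpi_choice_drive: partition must label every neuron 1 or 2",
         call. = FALSE)
  if (!any(part == 1L) || !any(part == 2L))
    stop("gpi_choice_drive: each half must contain at least one neuron",
         call. = FALSE)
  f_prime <- c(sum(cum[part == 1L]) / sum(part == 1L),
               sum(cum[part == 2L]) / sum(part == 2L)) / t
  f_max <- max(cum) / t
  f <- if (f_max > 0) (f_max - f_prime) / f_max else c(0, 0)
  list(f_prime = f_prime, f_max = f_max, f = f)
}

#' One explicit-Euler step of the mutual-inhibition race
#'
#' Integrates `dz1/dt = -z1 + f1 - z2` and `dz2/dt = -z2 + f2 - z1`
#' (time in units of the race time constant).  Negative integrator values
#' are clipped at zero; the first integrator to reach the threshold is the
#' selected choice, with a fair-coin tie-break on simultaneous crossing.
#'
#' @param state `list(z = c(z1, z2), crossed = NA_integer_, t = 0)`.
#' @param drive per-choice drives `c(f1, f2)` from [gpi_choice_drive()].
#' @param dt_race step in race-time units (> 0).
#' @param threshold crossing threshold (0.25).
#' @param clip_negative clip z at zero (default); `FALSE` restores the
#'   literal unclipped equations.
#' @return The updated state; `crossed` holds the winning index once set,
#'   and `t` counts elapsed race time.
#' @export
race_step <- function(state, drive, dt_race, threshold = 0.25,
                      clip_negative = TRUE) {
  if (dt_race <= 0) stop("race_step: dt_race must be positive", call. = FALSE)
  z <- state$z
  zn <- c(z[1] + dt_race * (-z[1] + drive[1] - z[2]),
          z[2] + dt_race * (-z[2] + drive[2] - z[1]))
  if (clip_negative) zn <- pmax(zn, 0)
  state$z <- zn
  state$t <- state$t + dt_race
  if (is.na(state$crossed)) {
    over <- which(zn >= threshold)
    if (length(over) == 2) state$crossed <- sample(1:2, 1)
    else if (length(over) == 1) state$crossed <- over
  }
  state
}

#' Run the race on a frozen drive series
#'
#' Integrates the mutual-inhibition race over a recorded sequence of
#' drives and reports the selected choice and crossing time.  Used to
#' re-run decisions on stored rasters; live trials run the same dynamics
#' inside the compiled network loop.
#'
#' @param drives a steps x 2 matrix of per-step drives.
#' @param dt_ms network step, ms.
#' @param tau_ms race time constant, ms (maps network time onto the unit
#'   time constant of the race equations).
#' @param threshold crossing threshold.
#' @return `list(choice, rt_ms, censored, z)`.
#' @export
run_race <- function(drives, dt_ms, tau_ms, threshold = 0.25) {
  state <- list(z = c(0, 0), crossed = NA_integer_, t = 0)
  for (k in seq_len(nrow(drives))) {
    state <- race_step(state, drives[k, ], dt_ms / tau_ms, threshold)
    if (!is.na(state$crossed))
      return(list(choice = state$crossed, rt_ms = k * dt_ms,
                  censored = FALSE, z = state$z))
  }
  z <- state$z
  choice <- if (z[1] > z[2]) 1L else if (z[2] > z[1]) 2L else sample(1:2, 1)
  list(choice = choice, rt_ms = nrow(drives) * dt_ms, censored = TRUE,
       z = z)
}
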