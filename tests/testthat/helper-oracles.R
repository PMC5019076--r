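# Independent reference implementations used as oracles.  These are kept
# deliberately plain (scalar loops, closed forms) and separate from the
# package's own code paths.

# Scalar forward-Euler integration of the two-variable quadratic
# integrate-and-fire neuron.  `I` may be a scalar or per-step vector.
ref_izh <- function(p, I, dt, steps, v0 = p$c, u0 = p$b * p$c) {
  if (length(I) == 1) I <- rep(I, steps)
  v <- numeric(steps)
  u <- numeric(steps)
  spikes <- 0L
  vv <- v0
  uu <- u0
  for (k in seq_len(steps)) {
    vn <- vv + dt * (0.04 * vv * vv + 5 * vv + 140 - uu + I[k])
    un <- uu + dt * p$a * (p$b * vv - uu)
    if (vn >= p$v_peak) {
      vn <- p$c
      un <- un + p$d
      spikes <- spikes + 1L
    }
    vv <- vn
    uu <- un
    v[k] <- vv
    u[k] <- uu
  }
  list(v = v, u = u, n_spikes = spikes)
}

# Brute-force enumeration of lattice-disc neighbour counts for an interior
# neuron: offsets (k, l) != (0, 0) with k^2 + l^2 <= r^2.
ref_disc_count <- function(radius) {
  span <- ceiling(radius)
  ct <- 0L
  for (k in -span:span)
    for (l in -span:span)
      if (!(k == 0 && l == 0) && k^2 + l^2 <= radius^2) ct <- ct + 1L
  ct
}

# Closed-form ordinary least squares through the normal equations.
ref_ols <- function(x, y, order = 1) {
  X <- outer(x, 0:order, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Crossing time of the winning integrator of the mutual-inhibition race
# under constant drives, from the closed-form solution of the linear
# system (valid while both integrators stay non-negative):
#   sum  s(t) = (F/2) (1 - exp(-2t)),  diff d(t) = df * t
ref_race_crossing <- function(f1, f2, threshold = 0.25) {
  stopifnot(f1 > f2)
  z1 <- function(t) (f1 + f2) / 4 * (1 - exp(-2 * t)) + (f1 - f2) / 2 * t
  uniroot(function(t) z1(t) - threshold, c(1e-9, 50))$root
}

# A tiny scripted test log in the package's trial-log layout.
script_log <- function(phase, pair, selected, correct = NA, rt = 1000,
                       conflict = "LC", censored = FALSE, first = NULL) {
  n <- max(lengths(list(pair, selected, rt)))
  data.frame(phase = phase, trial = seq_len(n), pair = pair,
             first_card = if (is.null(first)) substr(pair, 1, 1) else first,
             selected = selected,
             correct = if (all(is.na(correct))) NA else correct,
             reward = NA_real_, delta = NA_real_, delta_d1 = NA_real_,
             delta_d2 = NA_real_, rt_ms = rt, censored = censored,
             conflict = conflict, trained_pair = pair %in% c("AB", "CD", "EF"),
             stringsAsFactors = FALSE)
}

# Small fast condition used across tests.  Baseline jitter is switched
# off so compiled and reference trajectories can be compared exactly;
# tests of the stochastic behaviour use bg_condition() directly.
tiny_condition <- function(preset = "normal", shape = 4L, ...) {
  bg_condition(preset, shape = shape,
               overrides = list(baseline = list(jitter = 0)), ...)
}
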