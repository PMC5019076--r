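#' Map a cortico-striatal weight to a striatal firing rate
#'
#' Striatal medium spiny neurons fire irregularly in the 2-40 Hz range;
#' the learned cortico-striatal weight of a presented choice is normalized
#' linearly from `[w_min, w_max]` onto that range, clamped at both ends.
#'
#' @param w weight value(s).
#' @param w_min,w_max normalization bounds (`w_max > w_min`).
#' @param rate_min,rate_max target rate range, Hz.
#' @return Firing rate(s) in Hz.
#' @examples
#' weight_to_rate(0.5, 0, 1)  # midpoint -> 21 Hz
#' @export
weight_to_rate <- function(w, w_min, w_max, rate_min = 2, rate_max = 40) {
  if (w_max <= w_min)
    stop("weight_to_rate: w_max must exceed w_min", call. = FALSE)
  r <- rate_min + (rate_max - rate_min) * (w - w_min) / (w_max - w_min)
  pmin(pmax(r, rate_min), rate_max)
}

#' Striatal drive for one presented pair
#'
#' Computes the D1 and D2 Poisson rates of the two lattice halves for a
#' trial.  Each channel is normalized to the 2-40 Hz band by the running
#' min/max across all six choices' weights at trial start.  The
#' normalization span has a floor (`span_min`, default 2, the natural
#' scale of the +/-1 reward signal): when the six weights lie closer
#' together than the floor, the map keeps a fixed gain of
#' 38 / `span_min` Hz per weight unit centred on the running midpoint,
#' so small (noise-level) weight differences translate into
#' proportionally small rate differences instead of being stretched to
#' the full band.  All six weights exactly equal degenerates to the
#' midpoint rate (21 Hz).  The half assignment is canonical: the
#' alphabetically first card of the pair drives half 1 (upper rows), the
#' other card half 2.
#'
#' @param weights cortico-striatal weights, a list with named vectors
#'   `wD1` and `wD2` over choices A..F (see [init_weights()]).
#' @param pair two-character pair, e.g. `"AB"`.
#' @param span_min floor on the normalization span, weight units.
#' @return A list with `cards` (half 1, half 2) and `rates`
#'   `c(d1_h1, d1_h2, d2_h1, d2_h2)` in Hz.
#' @export
msn_rates <- function(weights, pair, span_min = 2) {
  cards <- sort(strsplit(pair, "")[[1]])
  if (length(cards) != 2 || !all(cards %in% names(weights$wD1)))
    stop(sprintf("invalid stimulus pair '%s'", pair), call. = FALSE)
  chan_rate <- function(w, card) {
    lo <- min(w); hi <- max(w)
    if (hi - lo < span_min) {
      mid <- (hi + lo) / 2
      lo <- mid - span_min / 2
      hi <- mid + span_min / 2
    }
    weight_to_rate(w[[card]], lo, hi)
  }
  rates <- c(chan_rate(weights$wD1, cards[1]),
             chan_rate(weights$wD1, cards[2]),
             chan_rate(weights$wD2, cards[1]),
             chan_rate(weights$wD2, cards[2]))
  list(cards = cards, rates = rates)
}

#' Generate one step of D1/D2 MSN Poisson spike fields
#'
#' Every neuron in a lattice half fires independently with probability
#' `rate * dt / 1000`; the D1 and D2 fields are drawn independently.  The
#' draw order matches the compiled simulation core (all D1 neurons in
#' column-major order, then all D2), so fields replay identically under a
#' fixed seed.
#'
#' @param rates numeric vector `c(d1_h1, d1_h2, d2_h1, d2_h2)` in Hz.
#' @param shape lattice side length (halves split the rows).
#' @param dt step, ms; `rate * dt` must not exceed 1000 (probability 1).
#' @return `list(d1, d2)` of logical `shape x shape` matrices.
#' @export
generate_msn_spikes <- function(rates, shape, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  p <- rates * dt / 1000
  if (any(p > 1))
    stop("generate_msn_spikes: rate * dt exceeds one spike per step; dt too coarse",
         call. = FALSE)
  n <- as.integer(shape)
  half <- ifelse(rep(seq_len(n), n) <= n %/% 2, 1L, 2L)
  d1 <- matrix(runif(n * n) < p[half], n, n)
  d2 <- matrix(runif(n * n) < p[2 + half], n, n)
  list(d1 = d1, d2 = d2)
}
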