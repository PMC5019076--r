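#' Izhikevich neuron parameters
#'
#' Bundles the four parameters of the two-variable Izhikevich model
#' (`dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`) together
#' with the spike cutoff `v_peak` (+30 mV).  When `v` reaches `v_peak` the
#' neuron is reset: `v <- c`, `u <- u + d`.
#'
#' @param a recovery time scale (1/ms); must be positive.
#' @param b recovery sensitivity (dimensionless).
#' @param c reset potential (mV); must lie below `v_peak`.
#' @param d recovery increment added at each spike (mV).
#' @param v_peak spike cutoff voltage (mV), +30 by default.
#' @return An object of class `izh_params`.
#' @examples
#' izh_params(a = 0.1, b = 0.2, c = -65, d = 2)
#' @export
izh_params <- function(a, b, c, d, v_peak = 30) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (a <= 0) stop("izh_params: 'a' must be positive", call. = FALSE)
  if (c >= v_peak) stop("izh_params: reset 'c' must be below v_peak",
                        call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak),
            class = "izh_params")
}

#' Build a 2D lattice of Izhikevich neurons
#'
#' Creates the state of one nucleus: an `shape x shape` grid of neurons at
#' rest (`v = c`, `u = b * c`) with no spikes pending.
#'
#' @param name nucleus label, one of `"STN"`, `"GPe"`, `"GPi"`.
#' @param shape lattice side length (the nucleus is `shape x shape`).
#' @param params an [izh_params()] object.
#' @return An object of class `nucleus_lattice` with matrices `v`, `u` and
#'   logical matrix `spiked`.
#' @export
build_lattice <- function(name, shape, params) {
  name <- match.arg(name, c("STN", "GPe", "GPi"))
  if (!is.numeric(shape) || length(shape) != 1 || shape < 1 ||
      shape != round(shape))
    stop("build_lattice: 'shape' must be a positive integer", call. = FALSE)
  if (!inherits(params, "izh_params"))
    stop("build_lattice: 'params' must be an izh_params object",
         call. = FALSE)
  n <- as.integer(shape)
  v <- matrix(params$c, n, n)
  structure(list(name = name, shape = n, v = v, u = params$b * v,
                 spiked = matrix(FALSE, n, n), params = params),
            class = "nucleus_lattice")
}

#' One forward-Euler step of the Izhikevich dynamics
#'
#' Vectorized single-step update.  `v` and `u` are advanced simultaneously
#' from the previous state; the spike reset (`v <- c`, `u <- u + d`) is
#' applied after the update, so post-step `v` never exceeds `v_peak`.
#'
#' @param v membrane potential(s), mV.
#' @param u recovery variable(s).
#' @param I total input current(s), pA (same shape as `v`).
#' @param params an [izh_params()] object.
#' @param dt integration step, ms.
#' @param name nucleus label used in divergence error messages.
#' @return `list(v, u, spiked)` with `spiked` logical.
#' @export
izhikevich_step <- function(v, u, I, params, dt, name = "neuron") {
  if (dt <= 0) stop("izhikevich_step: dt must be positive", call. = FALSE)
  vn <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
  un <- u + dt * params$a * (params$b * v - u)
  if (any(!is.finite(vn)) || any(!is.finite(un)))
    stop(sprintf("numerical divergence in %s", name), call. = FALSE)
  spiked <- vn >= params$v_peak
  vn[spiked] <- params$c
  un[spiked] <- un[spiked] + params$d
  list(v = vn, u = un, spiked = spiked)
}
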