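.validate_dbs <- function(dbs) {
  if (dbs$amplitude_pA < 0) stop("DBS amplitude must be >= 0", call. = FALSE)
  if (dbs$sigma <= 0) stop("DBS sigma must be positive", call. = FALSE)
  if (dbs$antidromic_fraction < 0 || dbs$antidromic_fraction > 1)
    stop("antidromic fraction must lie in [0, 1]", call. = FALSE)
  if (!dbs$pulse_mode %in% c("charge_equivalent", "full_amplitude"))
    stop("pulse_mode must be 'charge_equivalent' or 'full_amplitude'",
         call. = FALSE)
  invisible(dbs)
}

#' DBS electrode configuration
#'
#' Describes the stimulation current: a 130 Hz monophasic pulse train with
#' Gaussian spatial fall-off `A * exp(-((i - i_c)^2 + (j - j_c)^2) / sigma^2)`
#' over the STN lattice, optionally routed in part to GPe (antidromic
#' activation).  `center` and `sigma` are expressed on the reference
#' 50 x 50 lattice and are rescaled proportionally when the model is run at
#' another lattice size.
#'
#' @param amplitude_pA pulse amplitude A (pA).
#' @param sigma Gaussian spread, lattice units of the reference lattice.
#' @param center electrode centre `c(i_c, j_c)` on the reference lattice,
#'   or a position preset name (`"pos1"` = (13, 13) upper half, `"pos2"` =
#'   (25, 25) centre, `"pos3"` = (38, 38) lower half).
#' @param frequency_hz pulse train frequency (Hz).
#' @param pulse_width_us pulse duration (microseconds).
#' @param antidromic_fraction fraction p of the current field delivered to
#'   GPe (antidromic activation); the remaining 1 - p drives STN.
#' @param pulse_mode how a 100 us pulse shorter than the integration step is
#'   delivered: `"charge_equivalent"` scales the amplitude by
#'   `pulse_width / dt` on one step (preserves injected charge),
#'   `"full_amplitude"` applies A for a whole step.
#' @param ref_shape lattice size on which `center`/`sigma` are expressed.
#' @return A validated list of class `dbs_config`.
#' @export
dbs_config <- function(amplitude_pA = 220, sigma = 5, center = "pos2",
                       frequency_hz = 130, pulse_width_us = 100,
                       antidromic_fraction = 0,
                       pulse_mode = "full_amplitude", ref_shape = 50L) {
  preset <- NULL
  if (is.character(center)) {
    preset <- match.arg(center, names(.bg_positions))
    center <- .bg_positions[[preset]]
  }
  cfg <- structure(list(amplitude_pA = amplitude_pA, sigma = sigma,
                        center = center, frequency_hz = frequency_hz,
                        pulse_width_us = pulse_width_us,
                        antidromic_fraction = antidromic_fraction,
                        pulse_mode = pulse_mode,
                        position_preset = preset, ref_shape = ref_shape),
                   class = "dbs_config")
  .validate_dbs(cfg)
  cfg
}

# Rescale centre and sigma from the reference lattice to `shape`.
.dbs_geometry <- function(dbs, shape) {
  ref <- if (is.null(dbs$ref_shape)) 50L else dbs$ref_shape
  sc <- if (ref > 1) (shape - 1) / (ref - 1) else 1
  center <- 1 + (dbs$center - 1) * sc
  sigma <- dbs$sigma * shape / ref
  if (any(center < 1 | center > shape))
    stop("DBS electrode centre lies outside the lattice", call. = FALSE)
  list(center = center, sigma = sigma)
}

#' Spatiotemporal DBS current field
#'
#' Evaluates the stimulation current received by every lattice neuron at
#' time `t`: during a pulse window of the pulse train, neuron (i, j)
#' receives `A * exp(-((i - i_c)^2 + (j - j_c)^2) / sigma^2)`; between
#' pulses the field is zero everywhere.  The pulse is monophasic
#' (non-negative).
#'
#' @param config a DBS configuration (list with the fields of
#'   [dbs_config()]).
#' @param lattice_shape side length of the (square) lattice.
#' @param t time since stimulation onset, ms.
#' @return A `lattice_shape x lattice_shape` matrix of currents (pA).
#' @examples
#' f <- dbs_field(dbs_config(center = c(25, 25)), 50, t = 0)
#' f[25, 25]  # exactly the pulse amplitude at the electrode centre
#' @export
dbs_field <- function(config, lattice_shape, t) {
  if (t < 0) stop("dbs_field: t must be >= 0", call. = FALSE)
  period <- 1000 / config$frequency_hz
  width_ms <- config$pulse_width_us / 1000
  phase <- t %% period
  if (phase >= width_ms)
    return(matrix(0, lattice_shape, lattice_shape))
  dbs_spatial_field(config, lattice_shape)
}

#' @rdname dbs_field
#' @export
dbs_spatial_field <- function(config, lattice_shape) {
  g <- .dbs_geometry(config, lattice_shape)
  i <- matrix(seq_len(lattice_shape), lattice_shape, lattice_shape)
  j <- t(i)
  d2 <- (i - g$center[1])^2 + (j - g$center[2])^2
  config$amplitude_pA * exp(-d2 / g$sigma^2)
}

# Field as injected by the integrator: one step per pulse, amplitude scaled
# per pulse_mode so that a 100 us pulse keeps its charge at dt = 0.5 ms.
dbs_injected_field <- function(config, lattice_shape, dt) {
  f <- dbs_spatial_field(config, lattice_shape)
  if (identical(config$pulse_mode, "full_amplitude")) return(f)
  f * (config$pulse_width_us / 1000) / dt
}

#' Split the DBS field between STN and GPe (antidromic activation)
#'
#' A fraction `p` of the stimulation current is delivered to GPe neurons
#' (modelling antidromic activation of GPe afferents) and the remaining
#' `1 - p` to STN; the sum is conserved elementwise.
#'
#' @param field current field matrix from [dbs_field()].
#' @param p antidromic fraction in `[0, 1]`.
#' @return `list(stn = (1 - p) * field, gpe = p * field)`.
#' @export
antidromic_split <- function(field, p) {
  if (p < 0 || p > 1) stop("antidromic fraction must lie in [0, 1]",
                           call. = FALSE)
  list(stn = (1 - p) * field, gpe = p * field)
}
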