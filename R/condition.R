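#' @rdname bg_condition
#' @format NULL
.bg_base_condition <- function() {
  list(
    mode = "normal",
    shape = 50L,
    dt = 0.5,
    params = list(
      # STN: slow recovery, burst-capable; GPe/GPi: fast tonic firing.
      stn = list(a = 0.005, b = 0.265, c = -65, d = 2, v_peak = 30),
      gpe = list(a = 0.1, b = 0.2, c = -65, d = 2, v_peak = 30),
      gpi = list(a = 0.1, b = 0.2, c = -65, d = 2, v_peak = 30)),
    weights = list(
      w_sg = 0.91,        # STN -> GPe (glutamatergic, one-to-one)
      w_gs = 18,          # GPe -> STN (GABAergic, one-to-one)
      w_strd1_gpi = 4,    # D1 MSN -> GPi (GABAergic)
      w_strd2_gpe = 4,    # D2 MSN -> GPe (GABAergic)
      w_stn_gpi = 1.5,    # STN -> GPi (glutamatergic)
      w_lat_stn = 0.5,    # lateral excitation within STN, per neighbour
      w_lat_gpe = 0.5),   # lateral inhibition within GPe, per neighbour
    radii = list(r_s = 1.4, r_g = 1.6, r_stn_gpi = 1.6),
    tau_syn = list(glut = 5, gaba = 10),
    baseline = list(stn = 6, gpe = 5.5, gpi = 1.4, jitter = 0.4),
    dopamine = list(mode = "NORMAL", da_ceil = -0.1, delta_med = 2,
                    eta = 0.1),
    dbs = NULL,
    race = list(threshold = 0.25, tau_ms = 2600, t_max_ms = 3000),
    update_mask = "selected",
    side_assignment = "canonical")
}

.bg_presets <- function() {
  list(
    normal = list(),
    pd_off = list(mode = "pd_off",
                  weights = list(w_strd1_gpi = 3, w_stn_gpi = 2),
                  dopamine = list(mode = "PD_OFF")),
    pd_on_ldopa = list(mode = "pd_on_ldopa",
                       dopamine = list(mode = "PD_ON_LDOPA")),
    pd_on_daa = list(mode = "pd_on_daa",
                     dopamine = list(mode = "PD_ON_DAA")),
    dbs = list(mode = "dbs",
               weights = list(w_strd1_gpi = 3, w_stn_gpi = 2),
               dopamine = list(mode = "PD_OFF"),
               dbs = list(amplitude_pA = 220, sigma = 5,
                          center = c(25, 25), frequency_hz = 130,
                          pulse_width_us = 100, antidromic_fraction = 0,
                          pulse_mode = "full_amplitude",
                          position_preset = "pos2")),
    condt1 = list(mode = "condt1",
                  weights = list(w_strd1_gpi = 3, w_stn_gpi = 2),
                  dopamine = list(mode = "PD_OFF"),
                  radii = list(r_s = 3.3, r_g = 0.7)),
    condt2 = list(mode = "condt2",
                  weights = list(w_strd1_gpi = 3, w_stn_gpi = 2),
                  dopamine = list(mode = "PD_OFF"),
                  radii = list(r_s = 1.43, r_g = 1.7)))
}

#' Electrode position presets (coordinates on the reference 50 x 50 lattice)
#' @keywords internal
.bg_positions <- list(pos1 = c(13, 13), pos2 = c(25, 25), pos3 = c(38, 38))

# Recursively merge `over` into `base`, refusing keys absent from `base`.
.merge_config <- function(base, over, path = "") {
  for (key in names(over)) {
    full <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base))
      stop(sprintf("unknown configuration key '%s'", full), call. = FALSE)
    if (is.list(base[[key]]) && !is.null(base[[key]]) &&
        is.list(over[[key]])) {
      base[[key]] <- .merge_config(base[[key]], over[[key]], full)
    } else {
      base[[key]] <- over[[key]]
    }
  }
  base
}

#' Experimental condition configuration
#'
#' Builds the complete parameterization of one experimental condition:
#' synaptic weights, lateral connectivity radii, dopamine (TD error)
#' handling, optional DBS electrode settings, integration step and race
#' parameters.  Presets reproduce the model's five conditions plus the two
#' lateral-connectivity variants:
#'
#' * `normal`: direct pathway strong (`w_strd1_gpi = 4`), `w_stn_gpi = 1.5`,
#'   desynchronizing radii `r_s = 1.4`, `r_g = 1.6`, no dopamine clamp.
#' * `pd_off`: `w_strd1_gpi = 3`, `w_stn_gpi = 2`, TD error clamped at
#'   the ceiling -0.1 (dopaminergic cell loss).
#' * `pd_on_ldopa`: normal weights; clamped TD error plus medication
#'   (+2) applied to both the D1 and D2 update channels.
#' * `pd_on_daa`: normal weights; medication applied to the D2 channel
#'   only (dopamine agonist).
#' * `dbs`: PD weights and clamp, plus 130 Hz / 100 us Gaussian
#'   stimulation of STN (sigma 5, 220 pA, centre (25, 25)).
#' * `condt1` / `condt2`: PD OFF with altered lateral radii
#'   (`r_s = 3.3, r_g = 0.7` and `r_s = 1.43, r_g = 1.7`).
#'
#' @param preset preset name.
#' @param overrides named list of overrides merged recursively into the
#'   preset; unknown keys are rejected.
#' @param ... additional top-level overrides (alternative to `overrides`).
#' @return An object of class `bg_condition`.
#' @examples
#' cond <- bg_condition("normal", shape = 10L)
#' cond$weights$w_strd1_gpi
#' @export
bg_condition <- function(preset = c("normal", "pd_off", "pd_on_ldopa",
                                    "pd_on_daa", "dbs", "condt1", "condt2"),
                         overrides = list(), ...) {
  preset <- match.arg(preset)
  cfg <- .merge_config(.bg_base_condition(), .bg_presets()[[preset]])
  dots <- list(...)
  if (length(dots)) cfg <- .merge_config(cfg, dots)
  if (length(overrides)) cfg <- .merge_config(cfg, overrides)
  # resolve an electrode position preset into lattice coordinates
  if (!is.null(cfg$dbs) && !is.null(cfg$dbs$position_preset) &&
      is.null(overrides$dbs$center) && is.null(dots$dbs$center)) {
    cfg$dbs$center <- .bg_positions[[cfg$dbs$position_preset]]
  }
  cfg <- structure(cfg, class = "bg_condition")
  validate_condition(cfg)
  cfg
}

#' Validate a condition configuration
#'
#' @param cond a `bg_condition` object.
#' @return `cond`, invisibly, after checking invariants.
#' @export
validate_condition <- function(cond) {
  stopifnot(inherits(cond, "bg_condition"))
  if (cond$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (cond$shape < 2 || cond$shape %% 2 != 0)
    stop("shape must be an even integer >= 2 (halves must partition the lattice)",
         call. = FALSE)
  if (cond$radii$r_s < 0 || cond$radii$r_g < 0 ||
      cond$radii$r_stn_gpi < 0)
    stop("connectivity radii must be >= 0", call. = FALSE)
  if (!cond$dopamine$mode %in%
      c("NORMAL", "PD_OFF", "PD_ON_LDOPA", "PD_ON_DAA"))
    stop(sprintf("unknown dopamine mode '%s'", cond$dopamine$mode),
         call. = FALSE)
  if (cond$dopamine$eta < 0) stop("eta must be non-negative", call. = FALSE)
  if (!is.null(cond$dbs)) .validate_dbs(cond$dbs)
  for (p in cond$params)
    do.call(izh_params, p)  # runs the parameter invariant checks
  invisible(cond)
}

#' @export
print.bg_condition <- function(x, ...) {
  cat("<bg_condition>", x$mode, "\n")
  cat(sprintf("  lattice %dx%d, dt %.2f ms\n", x$shape, x$shape, x$dt))
  w <- x$weights
  cat(sprintf("  w_strd1_gpi=%g w_stn_gpi=%g w_sg=%g w_gs=%g r_s=%g r_g=%g\n",
              w$w_strd1_gpi, w$w_stn_gpi, w$w_sg, w$w_gs,
              x$radii$r_s, x$radii$r_g))
  cat(sprintf("  dopamine %s (ceil %g, med %g, eta %g)\n",
              x$dopamine$mode, x$dopamine$da_ceil, x$dopamine$delta_med,
              x$dopamine$eta))
  if (!is.null(x$dbs))
    cat(sprintf("  DBS %g pA, sigma %g, centre (%g, %g), %g Hz, antidromic %g\n",
                x$dbs$amplitude_pA, x$dbs$sigma, x$dbs$center[1],
                x$dbs$center[2], x$dbs$frequency_hz,
                x$dbs$antidromic_fraction))
  invisible(x)
}

#' Read / write condition configurations as YAML
#'
#' `load_condition()` accepts either a preset name or a path to a YAML file
#' containing a `preset` key plus overrides.  `write_condition()`
#' serializes the resolved configuration; the pair round-trips unchanged.
#'
#' @param source preset name or path to a YAML file.
#' @param cond a `bg_condition` object.
#' @param path output file path.
#' @return `load_condition()` returns a `bg_condition`.
#' @export
load_condition <- function(source) {
  if (source %in% names(.bg_presets())) return(bg_condition(source))
  if (!file.exists(source))
    stop(sprintf("'%s' is neither a preset nor a file", source),
         call. = FALSE)
  cfg <- yaml::read_yaml(source)
  if (!is.null(cfg$preset)) {
    preset <- cfg$preset
    cfg$preset <- NULL
    if (!is.null(cfg$dbs$center)) cfg$dbs$center <- as.numeric(cfg$dbs$center)
    return(bg_condition(preset, overrides = cfg))
  }
  cond <- structure(.merge_config(.bg_base_condition(), cfg),
                    class = "bg_condition")
  validate_condition(cond)
  cond
}

#' @rdname load_condition
#' @export
write_condition <- function(cond, path) {
  stopifnot(inherits(cond, "bg_condition"))
  yaml::write_yaml(unclass(cond), path)
  invisible(path)
}

# Flattened configuration consumed by the C++ core.
.core_config <- function(cond, race_enabled = TRUE, n_steps = NULL) {
  n <- as.integer(cond$shape)
  N <- n * n
  rows <- rep(seq_len(n), n)        # column-major row index per neuron
  half <- ifelse(rows <= n %/% 2, 1L, 2L)
  cn_s <- build_connectivity(n, cond$radii$r_s)
  cn_g <- build_connectivity(n, cond$radii$r_g)
  cn_gi <- build_connectivity(n, cond$radii$r_stn_gpi, include_self = TRUE)
  dbs_on <- !is.null(cond$dbs)
  if (dbs_on) {
    field <- dbs_injected_field(cond$dbs, n, cond$dt)
    split <- antidromic_split(field, cond$dbs$antidromic_fraction)
    dbs_stn <- as.numeric(split$stn)
    dbs_gpe <- as.numeric(split$gpe)
    period <- 1000 / cond$dbs$frequency_hz
  } else {
    dbs_stn <- dbs_gpe <- numeric(N)
    period <- 1
  }
  max_steps <- if (is.null(n_steps))
    as.integer(ceiling(cond$race$t_max_ms / cond$dt)) else as.integer(n_steps)
  list(n = n, dt = cond$dt, half = half,
       stn = cond$params$stn, gpe = cond$params$gpe, gpi = cond$params$gpi,
       w_sg = cond$weights$w_sg, w_gs = cond$weights$w_gs,
       w_strd1 = cond$weights$w_strd1_gpi,
       w_strd2 = cond$weights$w_strd2_gpe,
       w_stn_gpi = cond$weights$w_stn_gpi,
       w_lat_stn = cond$weights$w_lat_stn,
       w_lat_gpe = cond$weights$w_lat_gpe,
       dec_glut = exp(-cond$dt / cond$tau_syn$glut),
       dec_gaba = exp(-cond$dt / cond$tau_syn$gaba),
       bg_stn = cond$baseline$stn, bg_gpe = cond$baseline$gpe,
       bg_gpi = cond$baseline$gpi, bg_jitter = cond$baseline$jitter,
       nb_s_ptr = cn_s$ptr, nb_s_idx = cn_s$idx,
       nb_g_ptr = cn_g$ptr, nb_g_idx = cn_g$idx,
       nb_gi_ptr = cn_gi$ptr, nb_gi_idx = cn_gi$idx,
       dbs_on = dbs_on, dbs_stn = dbs_stn, dbs_gpe = dbs_gpe,
       dbs_period_ms = period,
       race_enabled = race_enabled,
       threshold = cond$race$threshold, tau_race_ms = cond$race$tau_ms,
       max_steps = max_steps)
}
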