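#' Initialize the three-nucleus network state
#'
#' Builds STN, GPe and GPi lattices at rest together with zeroed synaptic
#' traces.  This pure-R state is the reference implementation used for
#' verification; production simulations run the equivalent compiled loop
#' (see [run_trial()]).
#'
#' @param cond a [bg_condition()] object.
#' @return A list of class `bg_network` with one entry per nucleus plus the
#'   synaptic trace matrices and the resolved neighbour maps.
#' @export
network_state <- function(cond) {
  n <- cond$shape
  zeros <- function() matrix(0, n, n)
  structure(list(
    shape = n,
    stn = build_lattice("STN", n, do.call(izh_params, cond$params$stn)),
    gpe = build_lattice("GPe", n, do.call(izh_params, cond$params$gpe)),
    gpi = build_lattice("GPi", n, do.call(izh_params, cond$params$gpi)),
    traces = list(stn_gaba = zeros(), stn_lat = zeros(),
                  gpe_glut = zeros(), gpe_d2 = zeros(), gpe_lat = zeros(),
                  gpi_glut = zeros(), gpi_d1 = zeros()),
    nb_s = build_connectivity(n, cond$radii$r_s)$neighbors,
    nb_g = build_connectivity(n, cond$radii$r_g)$neighbors,
    nb_gi = build_connectivity(n, cond$radii$r_stn_gpi,
                               include_self = TRUE)$neighbors,
    step = 0L), class = "bg_network")
}

# Scatter one weight unit from every spiking neuron onto its neighbours.
.lateral_input <- function(spiked, neighbors, n) {
  out <- numeric(n * n)
  for (i in which(as.vector(spiked)))
    out[neighbors[[i]]] <- out[neighbors[[i]]] + 1
  matrix(out, n, n)
}

#' Advance the coupled network by one integration step
#'
#' Reference (pure R) implementation of the network update: synaptic traces
#' decay exponentially and accumulate weighted afferent spikes — striatal
#' D1/D2 Poisson spikes (current step) onto GPi/GPe, and the previous
#' step's STN/GPe spikes through the one-to-one STN<->GPe loop, the
#' lateral within-nucleus maps, and the STN->GPi projection — after which
#' every lattice takes one Izhikevich Euler step with
#' `I = baseline + excitatory - inhibitory + DBS`.
#'
#' @param state a `bg_network` from [network_state()].
#' @param cond the condition configuration.
#' @param d1_spikes,d2_spikes logical/0-1 matrices of striatal MSN spikes
#'   for this step (shape must match the lattices).
#' @param dbs_stn,dbs_gpe optional current matrices added to STN/GPe this
#'   step (e.g. a DBS pulse); defaults to none.
#' @return The updated `bg_network`.
#' @export
step_network <- function(state, cond, d1_spikes, d2_spikes,
                         dbs_stn = NULL, dbs_gpe = NULL) {
  n <- state$shape
  if (!all(dim(d1_spikes) == c(n, n)) || !all(dim(d2_spikes) == c(n, n)))
    stop("step_network: MSN spike fields must match the lattice shape",
         call. = FALSE)
  w <- cond$weights
  dec_glut <- exp(-cond$dt / cond$tau_syn$glut)
  dec_gaba <- exp(-cond$dt / cond$tau_syn$gaba)
  tr <- state$traces

  tr$stn_gaba <- tr$stn_gaba * dec_gaba
  tr$stn_lat  <- tr$stn_lat * dec_glut
  tr$gpe_glut <- tr$gpe_glut * dec_glut
  tr$gpe_d2   <- tr$gpe_d2 * dec_gaba
  tr$gpe_lat  <- tr$gpe_lat * dec_gaba
  tr$gpi_glut <- tr$gpi_glut * dec_glut
  tr$gpi_d1   <- tr$gpi_d1 * dec_gaba

  tr$gpi_d1 <- tr$gpi_d1 + w$w_strd1_gpi * (d1_spikes != 0)
  tr$gpe_d2 <- tr$gpe_d2 + w$w_strd2_gpe * (d2_spikes != 0)

  stn_prev <- state$stn$spiked
  gpe_prev <- state$gpe$spiked
  tr$gpe_glut <- tr$gpe_glut + w$w_sg * stn_prev
  tr$gpi_glut <- tr$gpi_glut +
    w$w_stn_gpi * .lateral_input(stn_prev, state$nb_gi, n)
  tr$stn_gaba <- tr$stn_gaba + w$w_gs * gpe_prev
  tr$stn_lat <- tr$stn_lat +
    w$w_lat_stn * .lateral_input(stn_prev, state$nb_s, n)
  tr$gpe_lat <- tr$gpe_lat +
    w$w_lat_gpe * .lateral_input(gpe_prev, state$nb_g, n)

  I_stn <- cond$baseline$stn + tr$stn_lat - tr$stn_gaba
  I_gpe <- cond$baseline$gpe + tr$gpe_glut - tr$gpe_d2 - tr$gpe_lat
  I_gpi <- cond$baseline$gpi + tr$gpi_glut - tr$gpi_d1
  if (!is.null(dbs_stn)) I_stn <- I_stn + dbs_stn
  if (!is.null(dbs_gpe)) I_gpe <- I_gpe + dbs_gpe

  state$step <- state$step + 1L
  for (nuc in c("stn", "gpe", "gpi")) {
    I <- switch(nuc, stn = I_stn, gpe = I_gpe, gpi = I_gpi)
    lat <- state[[nuc]]
    res <- izhikevich_step(lat$v, lat$u, I, lat$params, cond$dt,
                           name = sprintf("%s at step %d", lat$name,
                                          state$step))
    lat$v <- res$v
    lat$u <- res$u
    lat$spiked <- res$spiked
    state[[nuc]] <- lat
  }
  state$traces <- tr
  state
}

#' Windowed, normalized population activity
#'
#' Bins a spike raster into windows of `window_ms`, computes the mean
#' number of spikes per neuron in each window and normalizes by the
#' maximum over the trace (used e.g. to compare STN activity across
#' electrode positions over the first 600 ms of stimulation).
#'
#' @param raster a steps x neurons 0/1 matrix, or a vector of per-step
#'   population spike counts (then `n_neurons` must be given).
#' @param window_ms window length, ms (> 0).
#' @param dt integration step of the raster, ms.
#' @param n_neurons number of neurons when `raster` is a count vector.
#' @return A data.frame with `time_ms` (window end) and `activity`
#'   (normalized mean firing); zero rows for an empty raster.
#' @export
population_activity <- function(raster, window_ms, dt = 0.5,
                                n_neurons = NULL) {
  if (window_ms <= 0) stop("window_ms must be positive", call. = FALSE)
  if (is.matrix(raster)) {
    counts <- rowSums(raster)
    n_neurons <- ncol(raster)
  } else {
    counts <- as.numeric(raster)
    if (is.null(n_neurons))
      stop("n_neurons is required for a count-vector raster", call. = FALSE)
  }
  if (length(counts) == 0 || n_neurons == 0)
    return(data.frame(time_ms = numeric(0), activity = numeric(0)))
  steps_per_win <- max(1L, round(window_ms / dt))
  win <- (seq_along(counts) - 1L) %/% steps_per_win
  sums <- tapply(counts, win, sum) / n_neurons
  peak <- max(sums)
  if (peak > 0) sums <- sums / peak
  data.frame(time_ms = (as.integer(names(sums)) + 1) * steps_per_win * dt,
             activity = as.numeric(sums))
}

#' Long-format spike raster table
#'
#' Converts the rasters collected by [run_trial()] (with
#' `collect = list(rasters = TRUE)`) into a delimited-friendly table with
#' one row per spike: step, nucleus, row, col.
#'
#' @param raw the `raw` element of a [run_trial()] result.
#' @param shape lattice side length used for the run.
#' @return A data.frame with columns `step`, `nucleus`, `row`, `col`.
#' @export
raster_table <- function(raw, shape) {
  out <- list()
  for (nuc in c("stn", "gpe", "gpi")) {
    ras <- raw[[paste0(nuc, "_raster")]]
    if (is.null(ras)) next
    hit <- which(ras == 1, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    idx <- hit[, 2] - 1L
    out[[nuc]] <- data.frame(step = hit[, 1],
                             nucleus = toupper(nuc),
                             row = (idx %% shape) + 1L,
                             col = (idx %/% shape) + 1L)
  }
  if (!length(out))
    return(data.frame(step = integer(), nucleus = character(),
                      row = integer(), col = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$step), ]
}
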