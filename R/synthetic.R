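# Seeded generators emulating the event structure and ERP statistics of the
# paradigm families the decoder targets: oddball spellers (matrix and RSVP
# layouts, P300-like target component on top of a common visual evoked
# response), lateralized visual attention (identical evoked response in both
# conditions plus a small mirrored contralateral-ipsilateral difference,
# N2pc-like), and imbalanced binary single-trial potentials (ErrP-like).
# All randomness flows through the single seed in `sim_params`.

#' Gaussian-windowed ERP deflection
#'
#' A single ERP component time course: a Gaussian bump whose peak latency is
#' snapped to the sample grid so the peak sample is `round(latency * fs)`
#' and the peak value equals `amplitude` exactly.
#'
#' @param latency peak latency in seconds (within the epoch).
#' @param width Gaussian standard deviation in seconds (> 0).
#' @param amplitude peak amplitude (arbitrary units; 0 gives a zero vector).
#' @param m number of samples in the epoch.
#' @param fs sampling rate in Hz.
#' @return numeric vector of length `m`.
#' @export
erp_waveform <- function(latency, width, amplitude, m, fs) {
  if (width <= 0) stop("`width` must be positive")
  if (latency < 0 || latency > (m - 1) / fs)
    stop("`latency` must lie within the epoch")
  t <- (seq_len(m) - 1) / fs
  peak <- round_hafz(latency * fs) / fs
  amplitude * exp(-0.5 * ((t - peak) / width)^2)
}

# Smooth unimodal topography over the channel axis, unit peak.
topo_gauss <- function(n_channels, center, width) {
  x <- (seq_len(n_channels) - 0.5) / n_channels
  v <- exp(-0.5 * ((x - center) / width)^2)
  v / max(v)
}

# Antisymmetric (left-minus-right mirrored) topography: first half positive,
# second half the mirror image negated.
topo_lateral <- function(n_channels, center = 0.5, width = 0.35) {
  h <- n_channels %/% 2
  half <- topo_gauss(h, center, width)
  v <- c(half, -rev(half))
  if (n_channels %% 2 == 1L) v <- append(v, 0, after = h)
  v
}

#' Simulation parameters
#'
#' Bundles every knob of the synthetic generators, with defaults chosen to
#' resemble desk-scale versions of the classic paradigms: an 8-channel
#' 6 x 6 matrix speller (36 classes, 10 sequences of 15 repetition blocks),
#' 50 Hz epochs of 0.8 s, a common occipital visual-evoked component on
#' every event plus a target-conditional central P300-like component, AR(1)
#' temporally correlated channel noise plus white sensor noise.
#'
#' @param layout `"matrix"`, `"rsvp"`, `"lateralized"` or `"binary"`.
#' @param n_channels number of channels.
#' @param n_rows,n_cols matrix-speller grid (classes = `n_rows * n_cols`).
#' @param n_classes class count for the RSVP layout.
#' @param n_sequences number of trials/sequences.
#' @param n_repetitions repetition blocks per sequence.
#' @param fs sampling rate (Hz).
#' @param epoch_s epoch length in seconds (`m = round(epoch_s * fs)`).
#' @param erp optional list of ERP components overriding the layout
#'   defaults; each component is a list with `latency`, `width`,
#'   `amplitude`, `topography` (length `n_channels`) and `condition`
#'   (`"both"`, `"target"`, `"lateralized"` or `"minority"`).
#' @param amplitude_jitter standard deviation of the multiplicative
#'   epoch-to-epoch gain of every ERP component (`gain = max(0, 1 + sd*z)`),
#'   emulating the trial-to-trial amplitude variability of real ERPs.
#' @param noise_ar AR(1) coefficient of the channel noise.
#' @param noise_ar_sd marginal standard deviation of the AR(1) noise.
#' @param noise_sensor_sd standard deviation of the white sensor noise.
#' @param snr_scale multiplies all component amplitudes.
#' @param minority_fraction minority-class fraction for the binary layout.
#' @param n_epochs epoch count for the binary layout.
#' @param noiseless convenience switch zeroing both noise sources.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(layout = c("matrix", "rsvp", "lateralized", "binary"),
                       n_channels = 8, n_rows = 6, n_cols = 6,
                       n_classes = 10, n_sequences = 10, n_repetitions = 15,
                       fs = 50, epoch_s = 0.8, erp = NULL,
                       amplitude_jitter = 0.3,
                       noise_ar = 0.9, noise_ar_sd = 1.0,
                       noise_sensor_sd = 0.5, snr_scale = 1,
                       minority_fraction = 0.2, n_epochs = 500,
                       noiseless = FALSE, seed = 1L) {
  layout <- match.arg(layout)
  if (noiseless) { noise_ar_sd <- 0; noise_sensor_sd <- 0 }
  if (minority_fraction <= 0 || minority_fraction >= 1)
    stop("`minority_fraction` must lie in (0, 1)")
  m <- round_hafz(epoch_s * fs)
  if (is.null(erp)) erp <- default_components(layout, n_channels)
  for (cmp in erp) {
    if (length(cmp$topography) != n_channels)
      stop("component topography length must equal `n_channels`")
    if (!all(is.finite(cmp$amplitude))) stop("component amplitude must be finite")
  }
  structure(list(layout = layout, n_channels = n_channels, n_rows = n_rows,
                 n_cols = n_cols, n_classes = n_classes,
                 n_sequences = n_sequences, n_repetitions = n_repetitions,
                 fs = fs, m = m, erp = erp,
                 amplitude_jitter = amplitude_jitter, noise_ar = noise_ar,
                 noise_ar_sd = noise_ar_sd, noise_sensor_sd = noise_sensor_sd,
                 snr_scale = snr_scale, minority_fraction = minority_fraction,
                 n_epochs = n_epochs, seed = as.integer(seed)),
            class = "sim_params")
}

default_components <- function(layout, n_channels) {
  occ <- topo_gauss(n_channels, 0.85, 0.15)   # occipital, visual evoked
  cen <- topo_gauss(n_channels, 0.50, 0.20)   # centro-parietal, P300-like
  fcz <- topo_gauss(n_channels, 0.30, 0.18)   # fronto-central, ErrP-like
  switch(layout,
    matrix = ,
    rsvp = list(
      list(latency = 0.12, width = 0.04, amplitude = 1.2, topography = occ,
           condition = "both"),
      list(latency = 0.35, width = 0.09, amplitude = 1.2, topography = cen,
           condition = "target")),
    lateralized = list(
      list(latency = 0.15, width = 0.05, amplitude = 1.2, topography = occ,
           condition = "both"),
      list(latency = 0.20, width = 0.05, amplitude = 0.25,
           topography = topo_lateral(n_channels), condition = "lateralized")),
    binary = list(
      list(latency = 0.25, width = 0.06, amplitude = 1.0, topography = cen,
           condition = "both"),
      list(latency = 0.35, width = 0.06, amplitude = 1.0, topography = fcz,
           condition = "minority")))
}

# One d1 x m signal block per ERP component, with its condition tag.
component_blocks <- function(params) {
  lapply(params$erp, function(cmp) {
    w <- erp_waveform(cmp$latency, cmp$width,
                      cmp$amplitude * params$snr_scale, params$m, params$fs)
    list(block = outer(cmp$topography, w), condition = cmp$condition)
  })
}

# AR(1) channel noise (stationary marginal sd `ar_sd`) plus white noise,
# for all E epochs at once; columns of the AR recursion are channel x epoch
# series, each started from its stationary distribution.
sim_noise <- function(params, E) {
  d1 <- params$n_channels; m <- params$m
  out <- array(0, c(d1, m, E))
  if (params$noise_ar_sd > 0) {
    innov_sd <- params$noise_ar_sd * sqrt(1 - params$noise_ar^2)
    e <- matrix(stats::rnorm(m * d1 * E, sd = innov_sd), nrow = m)
    e[1, ] <- stats::rnorm(d1 * E, sd = params$noise_ar_sd)
    ar <- stats::filter(e, params$noise_ar, method = "recursive")
    out <- out + aperm(array(as.numeric(ar), c(m, d1, E)), c(2L, 1L, 3L))
  }
  if (params$noise_sensor_sd > 0)
    out <- out + array(stats::rnorm(d1 * m * E, sd = params$noise_sensor_sd),
                       c(d1, m, E))
  out
}

# gate: E x 3 numeric multipliers for the target / lateralized / minority
# condition blocks ("both" is always on). Each component is additionally
# scaled per epoch by a nonnegative random gain (trial-to-trial ERP
# amplitude variability).
assemble_sim <- function(params, stim, trgt_per_event, seqID, gate) {
  E <- nrow(stim)
  comps <- component_blocks(params)
  gains <- matrix(pmax(0, 1 + params$amplitude_jitter *
                         stats::rnorm(E * length(comps))), E)
  dat <- sim_noise(params, E)
  gate_of <- function(e, cond)
    switch(cond, both = 1, target = gate[e, 1],
           lateralized = gate[e, 2], minority = gate[e, 3])
  for (e in seq_len(E)) {
    for (ci in seq_along(comps)) {
      g <- gate_of(e, comps[[ci]]$condition)
      if (g != 0)
        dat[, , e] <- dat[, , e] + (g * gains[e, ci]) * comps[[ci]]$block
    }
  }
  epochs <- epoch_array(dat, params$fs)
  events <- event_table(stim, trgt_per_event, seqID)
  attr(events, "n_repetitions") <- params$n_repetitions
  list(epochs = epochs, events = events)
}

sim_truth <- function(params, ...) {
  c(list(topographies = lapply(params$erp, `[[`, "topography"),
         conditions = vapply(params$erp, `[[`, "", "condition")),
    list(...))
}

#' Simulate a speller session
#'
#' Matrix layout: each repetition block is a random permutation of all row
#' and column flashes of an `n_rows x n_cols` character grid, so every event
#' highlights several classes simultaneously (`stimID` rows). RSVP layout:
#' each repetition block presents every class once, focally, in random
#' order. Target epochs carry the target-conditional component(s) on top of
#' the common evoked component present in every epoch.
#'
#' @param params a [sim_params] with layout `"matrix"` or `"rsvp"`.
#' @return list with `epochs` ([epoch_array]), `events` ([event_table],
#'   carrying attribute `n_repetitions`) and `truth` (targets per sequence
#'   and the planted topographies).
#' @export
simulate_speller <- function(params = sim_params()) {
  stopifnot(params$layout %in% c("matrix", "rsvp"))
  with_seed(params$seed, {
    if (params$layout == "matrix") {
      C <- params$n_rows * params$n_cols
      grid <- matrix(seq_len(C), params$n_rows, params$n_cols, byrow = TRUE)
      flash_sets <- c(lapply(seq_len(params$n_rows), function(i) grid[i, ]),
                      lapply(seq_len(params$n_cols), function(j) grid[, j]))
    } else {
      C <- params$n_classes
      flash_sets <- as.list(seq_len(C))
    }
    nf <- length(flash_sets)
    q <- max(lengths(flash_sets))
    E <- params$n_sequences * params$n_repetitions * nf
    targets <- sample.int(C, params$n_sequences, replace = TRUE)
    stim <- matrix(0L, E, q)
    seqID <- rep(seq_len(params$n_sequences),
                 each = params$n_repetitions * nf)
    trgt <- targets[seqID]
    gate <- matrix(0, E, 3L)
    e <- 0L
    for (s in seq_len(params$n_sequences)) {
      for (r in seq_len(params$n_repetitions)) {
        for (fl in sample.int(nf)) {
          e <- e + 1L
          set <- flash_sets[[fl]]
          stim[e, seq_along(set)] <- set
          gate[e, 1L] <- as.numeric(targets[s] %in% set)
        }
      }
    }
    sim <- assemble_sim(params, stim, trgt, seqID, gate)
    c(sim, list(truth = sim_truth(params, targets = targets)))
  })
}

#' Simulate a lateralized (visual spatial attention) session
#'
#' Two classes; each repetition block presents both stimulus configurations
#' once in random order. Every epoch carries the same common evoked
#' component; a small antisymmetric (laterally mirrored) component flips
#' sign between the attended (`stimID == trgtID`) and unattended
#' configuration, so only contrastive decoding (the difference wave) can
#' separate the classes.
#'
#' @param params a [sim_params] with layout `"lateralized"`.
#' @return as [simulate_speller].
#' @export
simulate_lateralized <- function(params = sim_params(layout = "lateralized",
                                                     n_sequences = 24,
                                                     n_repetitions = 10)) {
  stopifnot(params$layout == "lateralized")
  with_seed(params$seed, {
    ns <- params$n_sequences; nr <- params$n_repetitions
    E <- ns * nr * 2L
    targets <- sample(c(1L, 2L), ns, replace = TRUE)
    stim <- integer(E)
    e <- 0L
    for (s in seq_len(ns)) for (r in seq_len(nr))
      for (cl in sample(c(1L, 2L))) { e <- e + 1L; stim[e] <- cl }
    seqID <- rep(seq_len(ns), each = nr * 2L)
    trgt <- targets[seqID]
    gate <- cbind(0, ifelse(stim == trgt, 1, -1), 0)
    sim <- assemble_sim(params, matrix(stim, ncol = 1L), trgt, seqID, gate)
    c(sim, list(truth = sim_truth(params, targets = targets)))
  })
}

#' Simulate imbalanced binary single-trial potentials
#'
#' Single-event decoding without sequence structure: each epoch is labeled
#' class 1 (minority, e.g. erroneous feedback) or class 2. The class counts
#' follow `minority_fraction` exactly (deterministic allocation; randomness
#' only orders the epochs), the minority class carries an additional
#' fronto-central component, and `trgtID` is empty as required for binary
#' mode.
#'
#' @param params a [sim_params] with layout `"binary"`.
#' @return as [simulate_speller]; `events$trgtID` is `NULL` and `seqID`
#'   numbers the epochs.
#' @export
simulate_binary <- function(params = sim_params(layout = "binary",
                                                epoch_s = 0.6,
                                                n_repetitions = 1)) {
  stopifnot(params$layout == "binary")
  n <- params$n_epochs
  n1 <- round(params$minority_fraction * n)
  if (n1 < 2L || n - n1 < 2L)
    stop("need at least 2 epochs per class")
  with_seed(params$seed, {
    labels <- sample(c(rep(1L, n1), rep(2L, n - n1)))
    gate <- cbind(0, 0, as.numeric(labels == 1L))
    params$n_repetitions <- 1L
    sim <- assemble_sim(params, matrix(labels, ncol = 1L), NULL,
                        seq_len(n), gate)
    c(sim, list(truth = sim_truth(params, labels = labels)))
  })
}
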