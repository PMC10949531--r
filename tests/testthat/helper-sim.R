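# Small, fast simulation settings shared across test files. All fixtures are
# generated in code with fixed seeds.

small_speller <- function(seed = 1, ...) {
  simulate_speller(sim_params(n_sequences = 6, n_repetitions = 5,
                              seed = seed, ...))
}

small_rsvp <- function(seed = 1, ...) {
  simulate_speller(sim_params(layout = "rsvp", n_classes = 6,
                              n_sequences = 6, n_repetitions = 5,
                              seed = seed, ...))
}

# Lateralized simulation with a symmetric common topography, so reversing
# the channel order mirrors the montage exactly.
mirrored_lateralized <- function(seed = 1, amp = 0.8, ...) {
  nch <- 8
  erp <- list(
    list(latency = 0.15, width = 0.05, amplitude = 1.2,
         topography = ccaerp:::topo_gauss(nch, 0.5, 0.2), condition = "both"),
    list(latency = 0.20, width = 0.05, amplitude = amp,
         topography = ccaerp:::topo_lateral(nch), condition = "lateralized"))
  simulate_lateralized(sim_params(layout = "lateralized", n_channels = nch,
                                  n_sequences = 12, n_repetitions = 8,
                                  erp = erp, seed = seed, ...))
}

# Per-sequence ground-truth targets aligned with a prediction data frame.
truth_of <- function(sim, pr) sim$truth$targets[pr$seqID]
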