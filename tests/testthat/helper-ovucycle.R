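## shared fixtures for the test suite

ref_p <- ref_params()
ref_y0 <- ref_init()

## a cheap 4-cycle reference simulation reused across tests
ref_sim_cache <- new.env()
ref_sim <- function() {
  if (is.null(ref_sim_cache$sim))
    ref_sim_cache$sim <- simulate_cycle(ref_p, init = ref_y0, horizon = 112)
  ref_sim_cache$sim
}

## a minimal hand-built trajectory object for metric tests
fake_sim <- function(times, hormones) {
  structure(list(times = times, hormones = hormones,
                 states = NULL, dose = dose_schedule(),
                 params = ref_p, init = ref_y0, t0 = times[1]),
            class = "cycle_sim")
}

## named state vector of given constant value
const_state <- function(value = 0) {
  setNames(rep(value, 13),
           c("RP_LH", "LH", "RP_FSH", "FSH", "RcF", "GrF", "DomF",
             "Sc1", "Sc2", "Lut1", "Lut2", "Lut3", "Lut4"))
}
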