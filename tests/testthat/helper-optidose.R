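# shared test helpers

# simulation/solver controls used by the heavier tests: tolerances looser
# than the package defaults but still far below any asserted tolerance
ctl_fast <- list(rtol = 1e-8, atol = 1e-10, grid_points = 150L, quiet = TRUE)

# default seed for property-style tests over random trajectories
PROPERTY_SEED <- 20241008

# closed-form concentration of the toy one-compartment model after a single
# bolus D at time s (C = D/V e^{-ke (t-s)}), used as an independent oracle
toy_bolus_C <- function(t, D, s = 0, ke = 0.1, V = 1) {
  ifelse(t < s, 0, D / V * exp(-ke * (t - s)))
}

# closed-form concentration during/after a zero-order infusion of amount
# 'amt' over 'dur' starting at 0 into the toy model
toy_infusion_C <- function(t, amt, dur, ke = 0.1, V = 1) {
  R <- amt / dur
  Cend <- R / (ke * V) * (1 - exp(-ke * dur))
  ifelse(t <= dur,
         R / (ke * V) * (1 - exp(-ke * t)),
         Cend * exp(-ke * (t - dur)))
}
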