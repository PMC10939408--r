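# Shared fixtures: a session prescription with generous flow rates (so no
# Kd-vs-flow warning fires in kinetic tests) and a typical patient.

rx <- function(Kd, Td, UF_volume = 0) {
  session_rx(Kd = Kd, Td = Td, UF_volume = UF_volume, Qb = 500, Qd = 500)
}

typical_patient <- function(Kru = 0, G = 6, V = 35000, ...) {
  patient_kinetics(V_total = V, Kru = Kru, G = G, ...)
}

# small factorial grid used by conservation / rebound property tests
small_grid <- function(unit) {
  build_parameter_grid(unit, Kru = c(0, 4), Kd = c(100, 200),
                       G = c(2.78, 9.76), Td = c(120, 200))
}
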