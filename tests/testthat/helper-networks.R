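# Small assembled systems reused across test files.

tiny_system <- function(n_cables = 3, condition = "proximal", g_gj = 1,
                        amplitude = 0, stim_cables = 1,
                        passive = passive_params(), active = ml_params()) {
  topo <- if (condition == "none")
    build_ladder_topology(n_cables, "none", 0)
  else build_ladder_topology(n_cables, condition, g_gj)
  stim <- stimulus_protocol(stim_cables, amplitude)
  assemble_network(topo, passive, active, stim)
}

# all-passive variant: the "active" compartment is given pure leak dynamics
# (no Ca/K conductances), so the whole network is a linear system
all_passive_system <- function(n_cables = 4, condition = "middle", g_gj = 0.5,
                               amplitude = 5, stim_cables = 1:2,
                               passive = passive_params()) {
  act <- ml_params(c_m = passive$c_m, g_ca = 0, g_k = 0,
                   g_l = passive$g_leak, e_l = passive$e_leak)
  tiny_system(n_cables, condition, g_gj, amplitude, stim_cables,
              passive, act)
}

expect_counts <- function(result, count) {
  expect_identical(result$spiking_cable_count, as.integer(count))
}
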