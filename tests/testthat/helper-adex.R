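# shared fixtures for the test suite ---------------------------------------

# slightly relaxed solver for the heavier optimization tests; feature
# values at these tolerances differ from the default solver's by far less
# than any assertion tolerance used below
fast_solver <- function() {
  solver_config(rtol = 1e-6, atol = 1e-8, h_min = 1e-5, max_steps = 3e5)
}

# an in-bounds parameter set that never spikes under any bundled protocol
# (strong leak pins V ~2 mV above E_L = -80, far below V_T = -20)
silent_params <- function() {
  adex_parameters(C_m = 3, g_L = 10, E_L = -80, Delta_T = 1, V_T = -20,
                  V_peak = 0, V_r = -80, a = 0, b = 0, tau_w = 100)
}

# a passive-membrane configuration (a = b = 0, threshold far away) for
# linear-response checks
passive_params <- function(a = 0) {
  adex_parameters(C_m = 3, g_L = 0.5, E_L = -70, Delta_T = 2, V_T = -50,
                  V_peak = 0, V_r = -70, a = a, b = 0, tau_w = 200)
}

# memoised full feature-table reproduction (shared by several acceptance
# blocks; ~2 s to compute)
.adexfit_test_cache <- new.env(parent = emptyenv())
reproduced_table <- function() {
  if (is.null(.adexfit_test_cache$tab)) {
    .adexfit_test_cache$tab <- reproduce_feature_table()
  }
  .adexfit_test_cache$tab
}
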