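# Shared small objects for the test suite. Kept deliberately light so the
# helpers themselves cannot hide long computations.

awake_tc <- function(...) thalamic_cell_params("TC", "awake", ...)
awake_re <- function(...) thalamic_cell_params("RE", "awake", ...)
sleep_tc <- function(...) thalamic_cell_params("TC", "sleep", ...)

# connectivity seen by one TC cell under the default wiring (cortical drive
# K = 0.05 * 8000 excitatory, recurrent RE inhibition K = 0.05 * 500)
tc_input <- function(params = awake_tc()) {
  input_connectivity(params, K_e = 400, K_i = 25)
}
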