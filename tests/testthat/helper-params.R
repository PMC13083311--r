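# Reference parameter set: the population-stage start-distribution means.
ref_params <- function() ssp_parameters(1.8, 0.017, 0.6, 60, 250, 30)

# Tiny fitting control for contract tests where estimate quality is not the
# point; keeps each fit under a second.
tiny_control <- function(n_starts = 2, maxit = 25, ...) {
  fit_control("desk", n_starts = n_starts, n_sim_congruent = 400,
              n_sim_incongruent = 400, maxit = maxit, n_restarts = 0, ...)
}

make_trials <- function(rt, accuracy, congruency = "congruent") {
  tibble::tibble(congruency = congruency, rt = rt, accuracy = accuracy,
                 responded = TRUE)
}
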