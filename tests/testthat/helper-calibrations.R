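# Generator calibrations used across tests.

# Hierarchy treatments behave exactly like the control condition: no true
# hierarchy effect on contributions, hence none on success.
null_calibration <- function() {
  empirical_params(
    contrib_intercept_low = 11, contrib_slope_k_low = 0,
    contrib_slope_t_low = 0,
    contrib_intercept_high = 11, contrib_slope_k_high = 0,
    contrib_slope_t_high = 0
  )
}

# Hierarchy contributions depressed (sum mean 18 vs 22 in control): a clear
# negative effect of hierarchy on success, direction as in the study.
injected_calibration <- function() {
  empirical_params(
    contrib_intercept_low = 8, contrib_slope_k_low = 0,
    contrib_slope_t_low = 0,
    contrib_intercept_high = 10, contrib_slope_k_high = 0,
    contrib_slope_t_high = 0
  )
}

# One full pipeline repetition: generate a three-treatment study with the
# given hierarchy calibration and return the success model's h1 row.
run_success_pipeline <- function(hier_params, rep_seed, n_groups = 6,
                                 n_boot = 100) {
  design <- study_design(
    groups = c(control = n_groups, earned = n_groups, random = n_groups),
    agent_params = list(control = empirical_params(),
                        earned = hier_params, random = hier_params),
    seed = rep_seed
  )
  fit <- fit_success_model(generate_study(design), n_boot = n_boot,
                           seed = rep_seed + 1L)
  fit[fit$term == "h1", ]
}
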