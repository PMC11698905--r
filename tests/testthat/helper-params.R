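# Shared fixtures: the printed parameter sets used across the figures, and
# random feasible parameter generators for property-style tests.

fig1b_params <- function() {
  conjugate_params(s = 0.15, r = 0.3, d = 0.1,
                   gamma = 0.01, alpha1 = 0.9, alpha2 = 0.1)
}

fig2_default_params <- function(gamma = 0.1) {
  conjugate_params(s = 0.08, r = 0.15, d = 0.1,
                   gamma = gamma, alpha1 = 0.6, alpha2 = 0.05)
}

fig3b_params <- function() {
  conjugate_params(s = 0.6, r = 0.8, d = 0.2,
                   gamma = 0.08, alpha1 = 0.5, alpha2 = 0.1)
}

fig4a_params <- function(gamma = 0.02) {
  conjugate_params(s = 0.05, r = 0.15, d = 0.1,
                   gamma = gamma, alpha1 = 0.4, alpha2 = 0.05)
}

fig6a_params <- function() {
  reduced_params(s = 0.05, r = 0.15, d = 0.1,
                 beta1 = 0.0175, beta2 = 0.0025)
}

# random conjugate parameter set, optionally constrained to a feasible
# coexistence point
random_conjugate_params <- function(feasible = TRUE) {
  repeat {
    p <- conjugate_params(s = runif(1, 0.01, 1), r = runif(1, 0.01, 1),
                          d = runif(1, 0.01, 1), gamma = runif(1, 0.001, 0.5),
                          alpha1 = runif(1, 0.01, 1),
                          alpha2 = runif(1, 0.001, 0.5))
    if (!feasible || feasibility_condition(p)) return(p)
  }
}

random_reduced_params <- function(feasible = TRUE) {
  repeat {
    p <- reduced_params(s = runif(1, 0.01, 1), r = runif(1, 0.01, 1),
                        d = runif(1, 0.01, 1), beta1 = runif(1, 0.001, 0.5),
                        beta2 = runif(1, 0.0005, 0.1))
    if (!feasible || feasibility_condition(p)) return(p)
  }
}

random_state <- function(with_C = TRUE) {
  system_state(E = runif(1, 0, 200), T = runif(1, 0, 500),
               C = if (with_C) runif(1, 0, 50) else NULL)
}
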