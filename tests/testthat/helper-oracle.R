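# Independent numeric oracle: integrate the growth/hazard ODE system
#   dP/dt = g P,  dM/dt = k P,  dLambda/dt = M0 + M
# with a tight-tolerance adaptive solver, and random parameter draws for
# property tests.

ode_cumulative_hazard <- function(params, g, t) {
  if (t == 0) return(0)
  rhs <- function(u, y, parms) {
    list(c(g * y[1], params$k * y[1], params$m0 + y[2]))
  }
  out <- deSolve::ode(
    y = c(P = params$p0, M = 0, L = 0),
    times = c(0, t), func = rhs, parms = NULL,
    method = "lsoda", rtol = 1e-10, atol = c(1e-10, 1e-30, 1e-30)
  )
  unname(out[nrow(out), "L"])
}

random_params <- function() {
  tumor_params(
    p0 = 10^runif(1, 5, 10),
    s = 10^runif(1, -11, -6),
    g_mean = runif(1, -0.2, 0.4),
    g_sd = runif(1, 0, 0.05),
    k = 10^runif(1, -14, -9),
    m0 = runif(1, 0, 0.01),
    label = "random"
  )
}

published_sets <- function(precision = "printed") {
  lapply(cancer_labels(), published_parameters, precision = precision)
}
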