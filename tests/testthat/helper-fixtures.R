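# Shared fixtures: the default parameterization and a fast scan wrapper.

default_params <- circuit_parameters()

# A parameterization whose steady state has a closed form: no resource
# competition (weights 0) and no complex formation (k_on = k_off = 0), so
# every species is an isolated linear birth-death process.
linear_params <- update_parameters(default_params,
                                   w_G = 0, w_R = 0, w_I = 0,
                                   k_on = 0, k_off = 0)

# Closed-form fixed point of the uncoupled system at a given dose for the
# open-loop (P_LR pinned at 1) topology with recombinase expressed.
linear_fixed_point <- function(p, dose, P_LR = 1) {
  h <- p$leak + (1 - p$leak) *
    ifelse(dose == 0, 0, 1 / (1 + (p$K_L / dose)^p$n_H))
  cg <- p$copy_gain
  c(G = cg * p$k_G / p$d_G,
    R = cg * p$k_R * h * P_LR / p$d_R,
    X = cg * p$k_X * h * P_LR / p$d_X,
    I = cg * p$k_I / p$d_I,
    C = 0,
    P_LR = P_LR)
}

# Random valid state inside the invariant box.
random_state <- function() {
  system_state(G = runif(1, 0, 100), R = runif(1, 0, 100),
               X = runif(1, 0, 20), I = runif(1, 0, 20),
               C = runif(1, 0, 10), P_LR = runif(1))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(1e-12, abs(y))), tol)
}
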