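test_that("hill activation has the stated limits and monotonicity", {
  p <- default_params
  expect_identical(hill_activation(0, p), 0)
  expect_equal(hill_activation(p$K_L, p), 0.5)
  expect_lt(abs(hill_activation(1e6 * p$K_L, p) - 1), 1e-6)
  expect_error(hill_activation(-1e-3, p), "dose")

  # leak floors the activity and the curve is non-decreasing
  set.seed(11)
  for (i in 1:20) {
    pl <- update_parameters(p, leak = runif(1, 0, 0.5),
                            K_L = 10^runif(1, -4, -2),
                            n_H = runif(1, 1, 4))
    doses <- sort(runif(50, 0, 1e-2))
    a <- hill_activation(doses, pl)
    expect_true(all(a >= pl$leak - 1e-15 & a < 1))
    expect_true(all(diff(a) >= -1e-15))
  }
})

test_that("promoter activities implement feedback and feedforward wiring", {
  p <- update_parameters(default_params, beta_FF = 0.8)
  big <- 1e3 * p$K_L  # hill ~ 1
  s1 <- system_state(P_LR = 1)
  expect_equal(promoter_activities(s1, big, p, "RE_NF_FF")$u_G, 1)
  s0 <- system_state(P_LR = 0)
  a0 <- promoter_activities(s0, big, p, "RE_NF_FF")
  expect_equal(a0$u_G, 1 + 0.8 * hill_activation(big, p))
  # without the feedforward branch the flipped promoter does not reach GFP
  expect_equal(promoter_activities(s0, big, p, "RE_NF")$u_G, 1)
  expect_equal(promoter_activities(s0, big, p, "NO_CONTROLLER")$u_I, 0)
  expect_equal(promoter_activities(s0, big, p, "OPEN_LOOP_MUT")$u_I, 1)
  # u_R = hill * P_LR
  sh <- system_state(P_LR = 0.4)
  expect_equal(promoter_activities(sh, p$K_L, p, "RE_NF")$u_R, 0.5 * 0.4)
})

test_that("resource share is 1/(1 + weighted demand), in (0,1], decreasing", {
  p <- default_params
  expect_equal(resource_share(list(u_G = 1, u_R = 1, u_I = 1),
                              update_parameters(p, w_G = 0, w_R = 0, w_I = 0)),
               1)
  expect_equal(resource_share(list(u_G = 1, u_R = 0, u_I = 0),
                              update_parameters(p, w_G = 1, w_R = 0, w_I = 0)),
               0.5)
  set.seed(12)
  for (i in 1:20) {
    pw <- update_parameters(p, w_G = runif(1, 0, 3), w_R = runif(1, 0, 3),
                            w_I = runif(1, 0, 3))
    acts <- list(u_G = runif(1, 0, 2), u_R = runif(1), u_I = runif(1))
    phi <- resource_share(acts, pw)
    expect_true(phi > 0 && phi <= 1)
    acts2 <- acts; acts2$u_R <- 2 * acts$u_R
    if (pw$w_R * acts$u_R > 0) {
      expect_lt(resource_share(acts2, pw), phi)
    }
  }
})

test_that("RHS matches the stated production/removal/flipping balance", {
  p <- default_params
  # empty cell, no induction: only constitutive GFP (and integrase) made
  d <- ode_rhs(system_state(), 0, p, "OPEN_LOOP_MUT")
  expect_equal(unname(d[c("R", "X", "C", "P_LR")]), rep(0, 4))
  expect_gt(d[["G"]], 0)
  phi0 <- resource_share(list(u_G = 1, u_R = 0, u_I = 1), p)
  expect_equal(d[["G"]], p$copy_gain * p$k_G * phi0)

  # without feedback (V_off = 0) the orientation relaxes toward LR
  p0 <- update_parameters(p, V_off = 0)
  d0 <- ode_rhs(system_state(I = 2, P_LR = 0.5), 1e-3, p0, "RE_NF")
  expect_gt(d0[["P_LR"]], 0)

  expect_error(ode_rhs(structure(c(G = NaN, R = 0, X = 0, I = 0, C = 0,
                                   P_LR = 1), class = "system_state"),
                       0, p, "RE_NF"),
               "non-finite")
})

test_that("closed-form fixed point of the uncoupled system zeroes the RHS", {
  p <- linear_params
  for (dose in c(0, 6.25e-4, 5e-3)) {
    fp <- linear_fixed_point(p, dose)
    d <- ode_rhs(validate_state(fp), dose, p, "OPEN_LOOP_MUT")
    expect_lt(max(abs(d)), 1e-9)
  }
})

test_that("topology reductions hold bit-level on the RHS", {
  p <- default_params
  p_nf <- update_parameters(p, beta_FF = 0)
  p_ol <- update_parameters(p, V_on = 0, V_off = 0)
  p_nc <- update_parameters(p, k_X = 0, k_I = 0, w_I = 0)
  set.seed(13)
  for (i in 1:25) {
    s <- random_state()
    dose <- runif(1, 0, 5e-3)
    expect_identical(ode_rhs(s, dose, p_nf, "RE_NF_FF"),
                     ode_rhs(s, dose, p_nf, "RE_NF"))
    # flip rates zeroed + pinned orientation == open-loop mutant
    r_nf <- ode_rhs(s, dose, p_ol, "RE_NF")
    r_ol <- ode_rhs(s, dose, p_ol, "OPEN_LOOP_MUT")
    expect_identical(r_nf, r_ol)
    expect_identical(r_nf[["P_LR"]], 0)
    expect_identical(ode_rhs(s, dose, p_nc, "OPEN_LOOP_MUT"),
                     ode_rhs(s, dose, p_nc, "NO_CONTROLLER"))
  }
})

test_that("integrator RHS agrees with the reference RHS", {
  set.seed(14)
  for (topo in CIRCUIT_TOPOLOGIES) {
    for (i in 1:10) {
      p <- update_parameters(default_params,
                             V_off = runif(1, 0, 1.5),
                             d_X = 10^runif(1, -1, 1),
                             beta_FF = runif(1, 0, 2))
      s <- random_state()
      dose <- runif(1, 0, 5e-3)
      ref <- ode_rhs(s, dose, p, topo)
      fast <- unlist(.rhs_desolve(0, unname(unclass(s)),
                                  .rhs_parms(p, topo, dose)))
      expect_equal(unname(fast), unname(ref), tolerance = 1e-14)
    }
  }
})

test_that("parameter and state validation enforce the invariants", {
  expect_error(circuit_parameters(d_G = 0), "removal")
  expect_error(circuit_parameters(n_H = 0.5), "n_H")
  expect_error(circuit_parameters(leak = 1), "leak")
  expect_error(circuit_parameters(copy_gain = 0), "copy_gain")
  expect_error(circuit_parameters(k_on = -1), "negative")
  expect_error(update_parameters(default_params, bogus = 1), "unknown")
  expect_error(system_state(G = -1), "concentrations")
  expect_error(system_state(P_LR = 1.5), "P_LR")
  expect_error(circuit_topology("RE_NF_XX"), "topology")
})

test_that("parameters round-trip through YAML and JSON", {
  p <- update_parameters(default_params, V_off = 0.333, K_L = 1.25e-4)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_parameters(p, f)
    q <- read_parameters(f)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
    unlink(f)
  }
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(V_off = 1, nope = 2), f)
  expect_error(read_parameters(f), "nope")
  unlink(f)
})
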