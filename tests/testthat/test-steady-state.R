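test_that("steady state matches the closed-form fixed point when uncoupled", {
  p <- linear_params
  for (dose in c(0, 6.25e-4)) {
    r <- integrate_to_steady_state(p, "OPEN_LOOP_MUT", dose)
    expect_true(r$converged)
    fp <- linear_fixed_point(p, dose)
    keep <- fp > 0
    expect_rel_equal(unclass(r$state)[keep], fp[keep], 1e-6)
    expect_lt(max(abs(unclass(r$state)[!keep])), 1e-8)
  }
})

test_that("the steady state is independent of the initial condition", {
  p <- default_params
  r1 <- integrate_to_steady_state(p, "OPEN_LOOP_MUT", 6.25e-4)
  far <- linear_fixed_point(linear_params, 6.25e-4)
  init2 <- validate_state(c(far[1:5] * 10, P_LR = 1))
  r2 <- integrate_to_steady_state(p, "OPEN_LOOP_MUT", 6.25e-4, init = init2)
  expect_rel_equal(unclass(r1$state)[1:5], unclass(r2$state)[1:5], 1e-6)
})

test_that("no induction means no RFP at steady state", {
  for (topo in CIRCUIT_TOPOLOGIES) {
    r <- integrate_to_steady_state(default_params, topo, 0)
    expect_true(r$converged)
    expect_lt(unclass(r$state)[["R"]], 1e-10)
  }
})

test_that("open-loop dose response shows resource competition", {
  tab <- dose_response_scan(default_params, "OPEN_LOOP_MUT")
  expect_equal(nrow(tab), 6L)
  expect_true(all(diff(tab$G_ss) <= 1e-10))   # GFP falls as RFP is induced
  expect_true(all(diff(tab$R_ss) >= -1e-10))
  expect_true(all(tab$G_ss > 0))
})

test_that("single zero-dose scan degenerates correctly", {
  tab <- dose_response_scan(default_params, "RE_NF", doses = 0)
  expect_equal(nrow(tab), 1L)
  expect_lt(tab$R_ss, 1e-10)
})

test_that("recombinase expression burdens GFP even without induction", {
  g_nc <- dose_response_scan(default_params, "NO_CONTROLLER", doses = 0)$G_ss
  g_ol <- dose_response_scan(default_params, "OPEN_LOOP_MUT", doses = 0)$G_ss
  expect_gt(g_nc, 0)
  expect_gt(g_ol, 0)
  expect_gt(g_nc, g_ol)  # integrase load costs GFP
})

test_that("warm-started and cold-started scans agree", {
  warm <- dose_response_scan(default_params, "RE_NF_FF")
  cold <- dose_response_scan(default_params, "RE_NF_FF", warm_start = FALSE)
  expect_rel_equal(warm$G_ss, cold$G_ss, 1e-6)
  expect_rel_equal(warm$R_ss + 1, cold$R_ss + 1, 1e-6)
  expect_rel_equal(warm$P_LR_ss, cold$P_LR_ss, 1e-6)
})

test_that("steady states are insensitive to tightening integrator tolerances", {
  r1 <- integrate_to_steady_state(default_params, "RE_NF", 2.5e-3,
                                  rtol = 1e-8, atol = 1e-10)
  r2 <- integrate_to_steady_state(default_params, "RE_NF", 2.5e-3,
                                  rtol = 1e-10, atol = 1e-12)
  expect_rel_equal(unclass(r1$state)[1:5], unclass(r2$state)[1:5], 1e-7)
})

test_that("scan input validation", {
  expect_error(dose_response_scan(default_params, "RE_NF", doses = c(1e-3, 1e-4)),
               "increasing")
  expect_error(dose_response_scan(default_params, "RE_NF", doses = -1),
               "non-negative")
  expect_error(parameter_sweep(default_params, "RE_NF", "nope", 1), "unknown")
})

test_that("a single-value sweep reproduces the plain scan", {
  sw <- parameter_sweep(default_params, "RE_NF", "V_off",
                        swept_values = default_params$V_off)
  tab <- dose_response_scan(default_params, "RE_NF")
  expect_equal(unname(sw$G_matrix[1, ]), tab$G_ss, tolerance = 1e-12)
  expect_equal(sw$G_norm_matrix[1, 1], 1)
})

test_that("the zero-feedback sweep row reproduces the open-loop scan", {
  sw <- parameter_sweep(default_params, "RE_NF", "V_off",
                        swept_values = c(0, 0.75))
  ol <- dose_response_scan(default_params, "OPEN_LOOP_MUT")
  expect_rel_equal(sw$G_matrix[1, ], ol$G_ss, 1e-8)
  expect_rel_equal(sw$scans[[1]]$R_ss + 1, ol$R_ss + 1, 1e-8)
})

test_that("trajectories stay in the invariant box from random interior starts", {
  set.seed(15)
  for (i in 1:8) {
    topo <- sample(CIRCUIT_TOPOLOGIES, 1)
    s <- random_state()
    r <- integrate_to_steady_state(default_params, topo, runif(1, 0, 5e-3),
                                   init = s)
    # validate_state() errors if outside the box; also check phi at the end
    st <- validate_state(r$state)
    acts <- promoter_activities(st, 1e-3, default_params, topo)
    phi <- resource_share(acts, default_params)
    expect_true(phi > 0 && phi <= 1)
    expect_true(r$converged)
  }
})
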