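make_nr <- function(r, g) {
  structure(list(r_norm = r, g_norm = g, source = "simulation"),
            class = "normalized_response")
}

test_that("normalization divides by baseline GFP and maximum RFP", {
  tab <- data.frame(dose = c(0, 1e-4, 1e-3), G_ss = c(500, 500, 500),
                    R_ss = c(0, 50, 100))
  nr <- normalize_responses(tab)
  expect_equal(nr$g_norm, rep(1, 3))
  expect_equal(nr$r_norm, c(0, 0.5, 1))

  tab2 <- data.frame(dose = c(0, 1e-3), G_ss = c(200, 100), R_ss = c(0, 80))
  nr2 <- normalize_responses(tab2)
  expect_equal(nr2$g_norm, c(1, 0.5))
  expect_equal(nr2$r_norm, c(0, 1))
})

test_that("normalization sorts by RFP and averages ties", {
  tab <- data.frame(dose = c(0, 1e-4, 2e-4, 1e-3),
                    G_ss = c(100, 80, 60, 50),
                    R_ss = c(0, 50, 50, 100))
  nr <- normalize_responses(tab)
  expect_equal(nr$r_norm, c(0, 0.5, 1))
  expect_equal(nr$g_norm, c(1, 0.7, 0.5))  # tie at r=0.5 averaged
})

test_that("normalization error paths are informative", {
  expect_error(normalize_responses(
    data.frame(dose = c(1e-4, 1e-3), G_ss = c(1, 2), R_ss = c(0, 1))),
    "zero-dose")
  expect_error(normalize_responses(
    data.frame(dose = c(0, 1e-3), G_ss = c(0, 2), R_ss = c(0, 1))),
    "baseline")
  expect_error(normalize_responses(
    data.frame(dose = c(0, 1e-3), G_ss = c(1, 1), R_ss = c(0, 0))),
    "direct")
})

test_that("the monotone cubic fit interpolates and preserves shape", {
  # linear precision
  r <- c(0, 0.2, 0.55, 1)
  nr <- make_nr(r, 1 - 0.3 * r)
  f <- pchip_interpolant(nr)
  xx <- seq(0, 1, length.out = 101)
  expect_lt(max(abs(f(xx) - (1 - 0.3 * xx))), 1e-12)

  # knots exact, monotone decreasing data stays monotone
  g <- c(1, 0.8, 0.35, 0.3)
  nr2 <- make_nr(r, g)
  f2 <- pchip_interpolant(nr2)
  expect_equal(f2(r), g)
  expect_true(all(diff(f2(xx)) <= 1e-12))
  expect_true(all(f2(xx) >= min(g) - 1e-12 & f2(xx) <= max(g) + 1e-12))

  expect_error(pchip_interpolant(make_nr(0.5, 1)), "2 distinct")
})

test_that("the fit is close to an independent PCHIP implementation", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (i in 1:10) {
    r <- sort(c(0, runif(4), 1))
    g <- cumsum(c(1, -runif(5, 0, 0.2)))  # monotone decreasing
    f <- pchip_interpolant(make_nr(r, g))
    xx <- seq(0, 1, length.out = 200)
    # the two slope-limiting rules differ slightly between the knots
    expect_lt(max(abs(f(xx) - pracma::pchip(r, g, xx))), 0.05)
    expect_lt(mean(abs(f(xx) - pracma::pchip(r, g, xx))), 0.02)
  }
})

test_that("Coupling Index definition: flat, shifted and linear responses", {
  flat <- make_nr(c(0, 0.3, 0.7, 1), rep(1, 4))
  res <- compute_ci(flat, method = "pchip_fit", grid_n = 1001L)
  expect_identical(res$ci, 0)
  expect_identical(res$sign, "decoupled")

  shifted <- make_nr(c(0, 0.5, 1), rep(0.8, 3))
  res2 <- compute_ci(shifted, method = "direct")
  expect_equal(res2$ci, -0.2)
  expect_identical(res2$sign, "negative")

  # analytic mean of (1 - 0.5 r) - 1 over [0,1] is -0.25
  lin <- make_nr(c(0, 0.25, 0.6, 1), 1 - 0.5 * c(0, 0.25, 0.6, 1))
  res3 <- compute_ci(lin, method = "pchip_fit", grid_n = 1001L)
  expect_lt(abs(res3$ci - (-0.25)), 1e-3)
})

test_that("CI sign classification respects the decoupled band", {
  nr <- make_nr(c(0, 1), c(1, 1.02))
  expect_identical(compute_ci(nr, method = "direct", tol = 0.02)$sign,
                   "decoupled")
  expect_identical(compute_ci(nr, method = "direct", tol = 0.001)$sign,
                   "positive")
})

test_that("CI is antisymmetric under reflection about the ideal line", {
  set.seed(22)
  for (i in 1:10) {
    r <- sort(c(0, runif(5), 1))
    g <- 1 + cumsum(rnorm(7, 0, 0.1))
    g <- g - g[1] + 1
    a <- compute_ci(make_nr(r, g), grid_n = 501L)$ci
    b <- compute_ci(make_nr(r, 2 - g), grid_n = 501L)$ci
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("CI is invariant to raw fluorescence units", {
  tab <- dose_response_scan(default_params, "RE_NF")
  scaled <- tab
  scaled$G_ss <- tab$G_ss * 731.4
  scaled$R_ss <- tab$R_ss * 0.013
  a <- compute_ci(normalize_responses(tab))$ci
  b <- compute_ci(normalize_responses(scaled))$ci
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("fitted and direct CI agree on dense noiseless curves", {
  for (topo in c("OPEN_LOOP_MUT", "RE_NF_FF")) {
    doses <- uniform_response_doses(default_params, topo, n = 200L)
    tab <- dose_response_scan(default_params, topo, doses)
    nr <- normalize_responses(tab)
    ci_fit <- compute_ci(nr, method = "pchip_fit", grid_n = 2001L)$ci
    ci_dir <- compute_ci(nr, method = "direct")$ci
    expect_lt(abs(ci_fit - ci_dir), 1e-3)
  }
})

test_that("bootstrap CI standard error is finite and leaves the RNG alone", {
  ds <- generate_dataset(default_params, "RE_NF",
                         noise = noise_model(cv_mult = 0.05, seed = 3))
  set.seed(99)
  before <- .Random.seed
  b <- ci_bootstrap(ds, n_boot = 50L, seed = 7)
  expect_identical(.Random.seed, before)
  expect_true(is.finite(b$ci) && is.finite(b$se))
  expect_gt(b$se, 0)
})
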