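test_that("with negligible loss the field equilibrates to the source value", {
  src <- matrix(FALSE, 5, 8); src[3, 4] <- TRUE
  dom <- grid_domain(8, 5, 10, source_mask = src)
  res <- solve_steady_state(dom, sim_config(phi = 2, loss_rate = 1e-12))
  expect_true(res$converged)
  expect_equal(max(abs(res$concentration - 1), na.rm = TRUE), 0,
               tolerance = 1e-6)
})

test_that("1-D strip steady state matches the analytic diffusion-loss profile", {
  phi <- 4.4; lambda <- 4.4e-4              # decay length 100 km
  dx <- 0.1 * sqrt(phi / lambda)            # stated resolution
  nx <- 101
  dom <- strip_domain(nx, dx)
  res <- solve_steady_state(dom, sim_config(phi = phi, loss_rate = lambda))
  x <- (seq_len(nx) - 1) * dx
  idx <- x > 0 & x <= 400                   # clear of the far no-flux wall
  err <- abs(res$concentration[2, idx] - strip_oracle(x[idx], phi, lambda)) /
    strip_oracle(x[idx], phi, lambda)
  expect_lt(max(err), 0.01)
  # refinement shrinks the discretization error
  dom2 <- strip_domain(201, dx / 2)
  res2 <- solve_steady_state(dom2, sim_config(phi = phi, loss_rate = lambda))
  x2 <- (seq_len(201) - 1) * dx / 2
  idx2 <- x2 > 0 & x2 <= 400
  err2 <- abs(res2$concentration[2, idx2] - strip_oracle(x2[idx2], phi, lambda)) /
    strip_oracle(x2[idx2], phi, lambda)
  expect_lt(max(err2), max(err))
})

test_that("explicit stepping and the direct solve agree", {
  dom <- strip_domain(41, 25)
  cfg <- sim_config(phi = 4.4, loss_rate = 4.4e-4, tolerance = 1e-9)
  direct <- solve_steady_state(dom, cfg, method = "direct")
  explicit <- solve_steady_state(dom, cfg, method = "explicit")
  expect_true(explicit$converged)
  expect_gt(explicit$iterations, 0)
  expect_equal(direct$concentration, explicit$concentration, tolerance = 1e-5)
})

test_that("zero diffusivity leaves all non-source land at zero", {
  dom <- generate_amazon_like_grid(nx = 12, ny = 8, dx = 50)
  res <- solve_steady_state(dom, sim_config(phi = 0, loss_rate = 1e-5))
  cells <- dom$land_mask & !dom$source_mask
  expect_true(all(res$concentration[cells] == 0))
  expect_true(all(res$concentration[dom$source_mask] == 1))
})

test_that("steady states obey the maximum principle on varied domains", {
  set.seed(3)
  for (i in 1:5) {
    nx <- sample(8:20, 1); ny <- sample(8:20, 1)
    land <- matrix(runif(nx * ny) > 0.15, ny, nx)
    land[, 1] <- TRUE
    src <- matrix(FALSE, ny, nx); src[, 1] <- TRUE
    dom <- grid_domain(nx, ny, 30, land_mask = land, source_mask = src)
    cfg <- sim_config(phi = runif(1, 0.5, 8), loss_rate = 10^runif(1, -6, -3),
                      source_concentration = 2)
    res <- solve_steady_state(dom, cfg)
    conc <- res$concentration[dom$land_mask]
    expect_true(all(conc >= 0 & conc <= 2))
    expect_true(all(res$concentration[dom$source_mask] == 2))
  }
})

test_that("pure diffusion without sources conserves total mass", {
  dom <- grid_domain(15, 10, 20)            # all land, no sources
  cfg <- sim_config(phi = 3, loss_rate = 1e-9, dt = "auto")
  set.seed(9)
  init <- matrix(runif(150), 10, 15)
  total0 <- sum(init)
  field <- step_diffusion(dom, cfg, field = init, n_steps = 200, loss_rate = 0)
  expect_equal(sum(field) / total0, 1, tolerance = 1e-8)
})

test_that("unstable explicit steps and missing sources are rejected", {
  dom <- strip_domain(21, 10)
  expect_error(solve_steady_state(dom, sim_config(phi = 4.4, loss_rate = 1e-5,
                                                  dt = 100),
                                  method = "explicit"), "stability")
  no_src <- grid_domain(10, 5, 10)
  expect_error(solve_steady_state(no_src, sim_config()), "source")
})

test_that("percent of baseline is monotone in diffusivity and loss", {
  dom <- generate_amazon_like_grid(nx = 30, ny = 20, dx = 100)
  base_cfg <- sim_config(phi = 4.4, loss_rate = 4.4e-6)
  baseline <- solve_steady_state(dom, base_cfg)
  expect_equal(percent_of_baseline(baseline, baseline, dom), 100)
  pct_phi <- vapply(c(0.5, 1.1, 2.2, 4.4), function(p) {
    cfg <- base_cfg; cfg$phi <- p
    percent_of_baseline(solve_steady_state(dom, cfg), baseline, dom)
  }, numeric(1))
  expect_true(all(diff(pct_phi) > 0))
  expect_equal(pct_phi[4], 100)
  pct_lambda <- vapply(c(4.4e-6, 4.4e-5, 4.4e-4), function(l) {
    cfg <- base_cfg; cfg$loss_rate <- l
    percent_of_baseline(solve_steady_state(dom, cfg), baseline, dom)
  }, numeric(1))
  expect_true(all(diff(pct_lambda) < 0))
})

test_that("threshold experiment sweeps from full fertility to none", {
  fauna <- pleistocene_community()
  mdl <- calibrate_model(fauna)
  dom <- generate_amazon_like_grid(nx = 24, ny = 16, dx = 125)
  sweep <- run_threshold_experiment(dom, sim_config(), fauna, mdl,
                                    thresholds = c(Inf, 3000, 500, 80, 3))
  expect_equal(sweep$threshold_kg, c(Inf, 3000, 500, 80, 3))
  expect_equal(sweep$percent_of_baseline[1], 100)
  expect_true(all(diff(sweep$percent_of_baseline) < 0))
  expect_equal(sweep$phi_km2_yr[1], 4.4, tolerance = 1e-12)
  expect_equal(sweep$percent_of_baseline[5], 0, tolerance = 1e-9)
  # single cohort: any threshold below its mass kills all transport
  solo <- herbivore_community(1000, 2)
  mdl2 <- calibrate_model(solo, target_phi = 4.4)
  sw2 <- run_threshold_experiment(dom, sim_config(), solo, mdl2,
                                  thresholds = c(Inf, 500))
  expect_equal(sw2$percent_of_baseline[2], 0, tolerance = 1e-9)
})

test_that("the solver is deterministic", {
  dom <- generate_amazon_like_grid(nx = 20, ny = 12, dx = 100)
  cfg <- sim_config()
  r1 <- solve_steady_state(dom, cfg)
  r2 <- solve_steady_state(dom, cfg)
  expect_identical(r1$concentration, r2$concentration)
})
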