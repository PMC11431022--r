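test_that("gating rules zero all responses for failed separations", {
  cfg <- cpe_sim_config()
  bad <- ovat_center(); bad$X1 <- "Span 85"
  expect_equal(unname(true_response(cfg, bad)[1, ]), c(0, 0, 0))
  low_salt <- ovat_center(); low_salt$X8 <- 10
  expect_equal(unname(true_response(cfg, low_salt)[1, ]), c(0, 0, 0))
  hot_salty <- ovat_center(); hot_salty$X5 <- 75; hot_salty$X8 <- 18
  expect_equal(unname(true_response(cfg, hot_salty)[1, ]), c(0, 0, 0))
  ok <- ovat_center()
  expect_true(all(true_response(cfg, ok)[1, ] > 0))
})

test_that("the default optimum is attainable and matches its stated objectives", {
  cfg <- cpe_sim_config()
  truth <- sim_true_optimum(cfg)
  expect_equal(unname(true_response(cfg, truth$settings)),
               unname(truth$objectives))
  expect_true(all(truth$objectives > 0))
  # shared-shape factors sit at their profile argmax
  expect_identical(truth$settings$X1, "Tween 80")
  expect_identical(truth$settings$X7, "NaCl")
  expect_identical(truth$settings$X11, "Step 1")
  expect_equal(truth$settings$X2, 10)
  expect_equal(truth$settings$X5, 45, tolerance = 0.25)
  expect_equal(truth$settings$X6, 20)
  expect_equal(truth$settings$X8, 16, tolerance = 0.1)
  expect_equal(truth$settings$X9, 2473)
  expect_equal(truth$settings$X10, 10)
  expect_equal(truth$settings$X3, 0.02, tolerance = 0.025)
  # pH trades phenolics against carotenoids; the equal-weight compromise
  # sits at the phenolics-side peak
  expect_equal(truth$settings$X4, 3, tolerance = 0.1)
})

test_that("temperature profile peaks at 45 and declines to 75", {
  cfg <- cpe_sim_config()
  a <- ovat_center(); a$X5 <- 45
  b <- ovat_center(); b$X5 <- 74
  expect_true(all(true_response(cfg, a)[1, ] > true_response(cfg, b)[1, ]))
})

test_that("zero noise makes simulation identical to the truth", {
  cfg <- cpe_sim_config(noise_cv = c(TPC = 0, TC = 0, AA = 0))
  d <- ovat_grid(cfg$space, "X5", ovat_center())
  sim <- simulate_table(cfg, d, replicates = 3, seed = 1)
  expect_equal(unname(as.matrix(sim$responses)),
               unname(true_response(cfg, d$settings)))
})

test_that("simulation is bit-reproducible and gated rows stay exactly zero", {
  cfg <- cpe_sim_config()
  d <- ovat_grid(cfg$space, "X8", ovat_center())  # grid includes gated levels
  s1 <- simulate_table(cfg, d, replicates = 3, seed = 7)
  s2 <- simulate_table(cfg, d, replicates = 3, seed = 7)
  expect_identical(s1$responses, s2$responses)
  gated <- d$settings$X8 < 15
  expect_true(all(as.matrix(s1$responses)[gated, ] == 0))
  s3 <- simulate_table(cfg, d, replicates = 50, seed = 8)
  expect_true(all(as.matrix(s3$responses)[gated, ] == 0))
})

test_that("replicate averaging concentrates on the noiseless value", {
  cfg <- cpe_sim_config()
  d <- cpe_design(cfg$space, ovat_center())
  sim <- simulate_table(cfg, d, replicates = 1000, seed = 9)
  truth <- true_response(cfg, d$settings)
  rel <- abs(as.matrix(sim$responses) / truth - 1)
  expect_true(all(rel < 0.005))  # CV 0.03, n = 1000
})

test_that("a monotone configured profile produces monotone simulated means", {
  cfg <- cpe_sim_config()   # X9 profile is decreasing
  d <- ovat_grid(cfg$space, "X9", ovat_center())
  sim <- simulate_table(cfg, d, replicates = 200, seed = 10)
  expect_true(all(diff(sim$responses$TPC) < 0))
})

test_that("noiseless screening data interpolates to r2 = 1", {
  cfg <- cpe_sim_config(noise_cv = c(TPC = 0, TC = 0, AA = 0))
  pb <- pb_design(cfg$space, table2_pairing())
  sim <- simulate_table(cfg, pb, replicates = 1, seed = 1)
  fit <- cpe_mlp(sim, hidden = 7, seed = 1)
  expect_equal(unname(round(fit$fit$r_squared, 3)), c(1, 1, 1))
})

test_that("config validation rejects inconsistent definitions", {
  expect_error(cpe_sim_config(baseline = c(TPC = -1, TC = 1, AA = 1)),
               "non-negative")
  expect_error(cpe_sim_config(noise_cv = c(TPC = -0.1, TC = 0, AA = 0)),
               "CV")
  eff <- default_sim_effects()
  eff$nope <- eff$X2
  expect_error(cpe_sim_config(effects = eff), "unknown factor")
})

test_that("bind_designs and drop_failed compose designs correctly", {
  cfg <- cpe_sim_config()
  d1 <- ovat_grid(cfg$space, "X8", ovat_center())
  d2 <- ovat_grid(cfg$space, "X2", ovat_center())
  both <- bind_designs(d1, d2)
  expect_identical(nrow(both$settings), nrow(d1$settings) + nrow(d2$settings))
  sim <- simulate_table(cfg, both, replicates = 1, seed = 3)
  kept <- drop_failed(sim)
  expect_identical(nrow(kept$settings),
                   nrow(both$settings) - sum(failed_separation(sim)))
  expect_true(all(rowSums(as.matrix(kept$responses)) > 0))
})
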