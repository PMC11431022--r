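test_that("Yoon RI matches the hand-evaluated two-input example", {
  sp <- toy_space(2L, responses = "TPC")
  m <- make_mlp(sp, W = matrix(c(2, -1), 2, 1), b1 = 0,
                V = matrix(1, 1, 1), b2 = 0)
  s <- yoon_sensitivity(m)
  expect_equal(unname(s$ri[, 1]), c(200 / 3, -100 / 3), tolerance = 1e-9)
})

test_that("RI is invariant to positive rescaling of the output weights", {
  sp <- toy_space(3L, responses = c("TPC", "TC"))
  set.seed(14)
  W <- matrix(rnorm(6), 3); V <- matrix(rnorm(4), 2)
  m1 <- make_mlp(sp, W, rnorm(2), V, rnorm(2))
  m2 <- make_mlp(sp, W, rnorm(2), 3.7 * V, rnorm(2))
  expect_equal(yoon_sensitivity(m1)$ri, yoon_sensitivity(m2)$ri,
               tolerance = 1e-12)
})

test_that("absolute influences sum to 100 per output for fitted models", {
  pb <- cpe_fixture("pb_design_responses")
  for (seed in 1:3) {
    fit <- cpe_mlp(pb, hidden = 5, seed = seed)
    s <- yoon_sensitivity(fit)
    expect_equal(unname(colSums(abs(s$ri))), c(100, 100, 100),
                 tolerance = 1e-9)
  }
  d <- toy_linear_design(n = 30, k = 4, seed = 17)
  for (act in list(c("identity", "identity"), c("tanh", "identity"))) {
    s <- yoon_sensitivity(cpe_mlp(d, hidden = 3, activations = act, seed = 2))
    expect_equal(unname(colSums(abs(s$ri))), c(100, 100, 100),
                 tolerance = 1e-9)
  }
})

test_that("identity-limit RI equals normalized least-squares coefficients", {
  # well-determined continuous-only data: the quadratic loss has a unique
  # minimum equal to the least-squares solution
  d <- toy_linear_design(n = 40, k = 5, noise_sd = 0.05, seed = 9)
  fit <- cpe_mlp(d, hidden = 4, seed = 3, maxit = 5000, reltol = 1e-15)
  B <- ls_oracle_coef(d)                       # k x 3, normalized scale
  ri_oracle <- sweep(B, 2L, colSums(abs(B)), "/") * 100
  s <- yoon_sensitivity(fit)
  expect_equal(unname(s$ri), unname(ri_oracle), tolerance = 1e-6)
  # signs agree with the equivalent affine coefficients
  expect_equal(sign(unname(s$ri)), sign(unname(fit$W %*% fit$V)))
})

test_that("an all-zero output weight column yields NA influence with warning", {
  sp <- toy_space(2L, responses = c("TPC", "TC"))
  m <- make_mlp(sp, W = matrix(c(1, 2), 2, 1), b1 = 0,
                V = matrix(c(1, 0), 1, 2), b2 = c(0, 0))
  expect_warning(s <- yoon_sensitivity(m), "undefined")
  expect_true(all(is.na(s$ri[, "TC"])))
  expect_false(anyNA(s$ri[, "TPC"]))
})

test_that("rank_factors orders by absolute influence with stable ties", {
  sp <- toy_space(3L, responses = "TPC")
  m <- make_mlp(sp, W = matrix(c(0.1, -5, 0.1), 3, 1), b1 = 0,
                V = matrix(1, 1, 1), b2 = 0)
  s <- yoon_sensitivity(m)
  r <- rank_factors(s, "TPC")
  expect_identical(r[1], "F2")
  expect_identical(r[2:3], c("F1", "F3"))  # tie kept in factor order
  expect_error(rank_factors(s, "nope"), "unknown output")
})

test_that("ranking is equivariant under permutation of the input order", {
  set.seed(23)
  sp1 <- toy_space(4L, responses = "TPC")
  W <- matrix(rnorm(8), 4); V <- matrix(rnorm(2), 2)
  m1 <- make_mlp(sp1, W, rnorm(2), V, 0)
  perm <- c(3, 1, 4, 2)
  sp2 <- factor_space(sp1$factors[perm], response_names = "TPC")
  m2 <- make_mlp(sp2, W[perm, ], rnorm(2) * 0 + m1$b1, V, 0)
  expect_identical(rank_factors(yoon_sensitivity(m1), "TPC"),
                   rank_factors(yoon_sensitivity(m2), "TPC"))
})

test_that("a factor with zero true effect ranks last on simulated data", {
  # all factors flat except X5; identity fit on a gate-free simulation
  eff <- default_sim_effects()
  for (nm in names(eff)) if (nm != "X5") eff[[nm]]$mult[] <- 1
  cfg <- cpe_sim_config(effects = eff, gates = list())
  d <- bind_designs(pb_design(cfg$space, table2_pairing()),
                    random_design(cfg$space, 50, seed = 31))
  sim <- simulate_table(cfg, cpe_design(cfg$space, d$settings),
                        replicates = 3, seed = 32)
  fit <- cpe_mlp_search(sim, hidden = 5, restarts = 4, seed = 33)
  s <- yoon_sensitivity(fit)
  for (j in c("TPC", "TC", "AA")) {
    expect_identical(rank_factors(s, j)[1], "X5")
  }
})

test_that("sensitivity report writes as delimited text", {
  pb <- cpe_fixture("pb_design_responses")
  s <- yoon_sensitivity(cpe_mlp(pb, hidden = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sensitivity(s, path)
  back <- read.delim(path)
  expect_identical(back$factor, rownames(s$factor_ri))
})
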