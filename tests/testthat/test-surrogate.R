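test_that("parameter count follows the weights-plus-biases formula", {
  expect_identical(mlp_param_count(14, 7, 3), 129L)
  expect_identical(mlp_param_count(1, 1, 1), 4L)
  expect_identical(mlp_param_count(14, 5, 3), 93L)
})

test_that("forward pass with zero weights predicts the inverse-scaled zero", {
  sp <- toy_space(2L, responses = c("TPC", "TC"))
  ysc <- structure(list(min = c(10, 5), max = c(20, 9)), class = "cpe_scaling")
  m <- make_mlp(sp, W = matrix(0, 2, 3), b1 = rep(0, 3),
                V = matrix(0, 3, 2), b2 = rep(0, 2), y_scaling = ysc)
  p <- predict(m, data.frame(F1 = 0.3, F2 = 0.8))
  expect_equal(unname(p[1, ]), c(10, 5))  # inverse-scaled 0 = column minima
})

test_that("identity activations make the network an affine map V'W'x + const", {
  set.seed(11)
  for (rep in 1:5) {
    k <- sample(2:5, 1); h <- sample(1:4, 1); q <- sample(1:3, 1)
    sp <- toy_space(k, responses = paste0("R", seq_len(q)))
    W <- matrix(rnorm(k * h), k); b1 <- rnorm(h)
    V <- matrix(rnorm(h * q), h); b2 <- rnorm(q)
    m <- make_mlp(sp, W, b1, V, b2)
    X <- matrix(runif(6 * k), 6)
    s <- as.data.frame(X); names(s) <- paste0("F", seq_len(k))
    pred <- predict(m, s)
    oracle <- sweep(X %*% (W %*% V), 2L, as.numeric(b1 %*% V) + b2, "+")
    expect_equal(unname(pred), unname(oracle), tolerance = 1e-12)
  }
})

test_that("identity surrogate interpolates the screening fixture (r2 = 1.000)", {
  pb <- cpe_fixture("pb_design_responses")
  fit <- cpe_mlp(pb, hidden = 7, seed = 1)
  expect_equal(unname(round(fit$fit$r_squared, 3)), c(1, 1, 1))
  # the best identity network cannot beat the least-squares oracle, and a
  # converged fit must reach it
  expect_lt(abs(fit$fit$loss - ls_oracle_loss(pb)), 1e-6)
  # a fitted interpolant reproduces the printed best run
  expect_equal(unname(predict(fit, pb)[4, ]), c(348.56, 16.4, 968.99),
               tolerance = 1e-4)
})

test_that("training is bit-identical under a fixed seed", {
  pb <- cpe_fixture("pb_design_responses")
  f1 <- cpe_mlp(pb, hidden = 5, seed = 99)
  f2 <- cpe_mlp(pb, hidden = 5, seed = 99)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$fit$loss, f2$fit$loss)
})

test_that("noiseless linear data recovers the generating coefficients via W V", {
  set.seed(3)
  k <- 4L; n <- 30L
  sp <- toy_space(k)
  X <- matrix(runif(n * k), n)
  B <- matrix(rnorm(k * 3), k)
  Y <- 10 + X %*% B
  Y <- Y - min(Y) + 1
  s <- as.data.frame(X); names(s) <- paste0("F", seq_len(k))
  d <- cpe_design(sp, s, as.data.frame(`colnames<-`(Y, c("TPC", "TC", "AA"))))
  fit <- cpe_mlp(d, hidden = 3, seed = 2, maxit = 2000, reltol = 1e-15)
  # compare on the product (W, V individually are not identified); transform
  # the normalized-scale product back to raw-coefficient units
  xr <- fit$x_scaling$max - fit$x_scaling$min
  yr <- fit$y_scaling$max - fit$y_scaling$min
  Braw <- diag(1 / xr) %*% (fit$W %*% fit$V) %*% diag(yr)
  expect_equal(unname(Braw), unname(B), tolerance = 1e-4)
})

test_that("predictions are invariant to training row order", {
  pb <- cpe_fixture("pb_design_responses")
  perm <- c(7, 3, 11, 1, 12, 5, 9, 2, 8, 4, 10, 6)
  pbp <- cpe_design(pb$space, pb$settings[perm, ], pb$responses[perm, ])
  f1 <- cpe_mlp(pb, hidden = 7, seed = 5)
  f2 <- cpe_mlp(pbp, hidden = 7, seed = 5)
  expect_equal(predict(f1, pb), predict(f2, pb), tolerance = 1e-6)
})

test_that("r_squared matches a direct textbook recomputation", {
  d <- toy_linear_design(n = 25, k = 3, seed = 8)
  fit <- cpe_mlp(d, hidden = 2, seed = 1)
  P <- predict(fit, d)
  Y <- as.matrix(d$responses)
  oracle <- sapply(seq_len(3), function(j) {
    1 - sum((Y[, j] - P[, j])^2) / sum((Y[, j] - mean(Y[, j]))^2)
  })
  expect_equal(unname(fit$fit$r_squared), oracle, tolerance = 1e-12)

  # degenerate cases: perfect predictor and mean-only predictor
  sp <- d$space
  perfect <- make_mlp(sp, W = diag(3), b1 = rep(0, 3), V = diag(3),
                      b2 = rep(0, 3))
  dd <- cpe_design(sp, data.frame(F1 = c(0, 1), F2 = c(0, 1), F3 = c(0, 1)),
                   data.frame(TPC = c(0, 1), TC = c(0, 1), AA = c(0, 1)))
  expect_equal(unname(r_squared(perfect, dd)), c(1, 1, 1))
  meanonly <- make_mlp(sp, W = matrix(0, 3, 1), b1 = 0,
                       V = matrix(0, 1, 3), b2 = rep(0.5, 3))
  expect_equal(unname(r_squared(meanonly, dd)), c(0, 0, 0))

  # zero-variance response column is reported as NA with a warning
  dz <- cpe_design(sp, dd$settings, data.frame(TPC = c(0, 1), TC = c(1, 1),
                                               AA = c(0, 1)))
  expect_warning(rz <- r_squared(perfect, dz), "zero-variance")
  expect_true(is.na(rz["TC"]))
})

test_that("search with one restart and one size reduces to a single training run", {
  pb <- cpe_fixture("pb_design_responses")
  got <- cpe_mlp_search(pb, hidden = 7, restarts = 1, seed = 4)
  sub <- cpeopt:::derive_seed(4L, 7L * 10000L + 1L * 100L + 1L)
  ref <- cpe_mlp(pb, hidden = 7, seed = sub)
  expect_identical(got$W, ref$W)
  expect_identical(got$fit$loss, ref$fit$loss)
  expect_identical(nrow(got$search_log), 1L)
})

test_that("enlarging the restart budget never lowers the selected mean r2", {
  d <- toy_linear_design(n = 15, k = 3, noise_sd = 0.3, seed = 21)
  r2s <- vapply(1:3, function(nr) {
    m <- cpe_mlp_search(d, hidden = 2, restarts = nr, seed = 6,
                        activations = list(c("tanh", "identity")))
    mean(m$fit$r_squared)
  }, 0)
  expect_true(all(diff(r2s) >= -1e-12))
})

test_that("serialization round-trips predictions bit-exactly", {
  pb <- cpe_fixture("pb_design_responses")
  fit <- cpe_mlp(pb, hidden = 6, seed = 12,
                 activations = c("tanh", "identity"))
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(fit, path)
  back <- read_mlp(path)
  expect_identical(predict(back, pb), predict(fit, pb))
  expect_identical(back$activations, fit$activations)
  expect_identical(back$n_hidden, fit$n_hidden)
})

test_that("training never ends above its starting loss", {
  d <- toy_linear_design(n = 20, k = 3, seed = 5)
  for (act in list(c("identity", "identity"), c("tanh", "identity"),
                   c("logistic", "exponential"),
                   c("exponential", "exponential"))) {
    fit <- cpe_mlp(d, hidden = 2, activations = act, seed = 31)
    # the mean-matched initialization starts at roughly the variance of the
    # normalized responses; a converged fit must not exceed it
    X <- encode_settings(d$space, d$settings)
    Y <- as.matrix(d$responses)
    Ys <- apply_scaling(fit_scaling(Y), Y)
    start_loss <- 0.5 * sum(sweep(Ys, 2L, colMeans(Ys), "-")^2)
    expect_lt(fit$fit$loss, start_loss * 1.05)
  }
})
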