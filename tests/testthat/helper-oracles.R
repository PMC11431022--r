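# Independent oracles and small fixtures used across the suite.

# Minimal achievable summed squared error of the affine family (the
# identity/identity network family) on the normalized scale, via QR least
# squares with intercept -- independent of the package's training path.
ls_oracle_loss <- function(design) {
  X <- encode_settings(design$space, design$settings)
  Y <- as.matrix(design$responses)
  Xs <- apply_scaling(fit_scaling(X), X)
  Ys <- apply_scaling(fit_scaling(Y), Y)
  fit <- stats::lm.fit(cbind(1, Xs), Ys)
  0.5 * sum(as.matrix(fit$residuals)^2)
}

# Normalized least-squares coefficients (no intercept column returned),
# the identity-limit reference for Yoon sensitivity.
ls_oracle_coef <- function(design) {
  X <- encode_settings(design$space, design$settings)
  Y <- as.matrix(design$responses)
  Xs <- apply_scaling(fit_scaling(X), X)
  Ys <- apply_scaling(fit_scaling(Y), Y)
  fit <- stats::lm.fit(cbind(1, Xs), Ys)
  coefs <- as.matrix(fit$coefficients)[-1L, , drop = FALSE]
  coefs
}

# Brute-force maximization dominance: is row i of `points` dominated by any
# other row (componentwise >= with at least one >)? Deliberately written
# differently from pareto_filter().
brute_dominated <- function(points, tol = 0) {
  n <- nrow(points)
  vapply(seq_len(n), function(i) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (all(points[j, ] >= points[i, ] - tol) &&
          any(points[j, ] > points[i, ] + tol)) {
        return(TRUE)
      }
    }
    FALSE
  }, TRUE)
}

# Assemble a cpe_mlp by hand (identity scalings unless given), for oracle
# tests that need exact control over the weights.
make_mlp <- function(space, W, b1, V, b2,
                     activations = c("identity", "identity"),
                     x_scaling = NULL, y_scaling = NULL) {
  p <- input_width(space)
  W <- matrix(W, nrow = p)
  V <- matrix(V, nrow = ncol(W))
  if (is.null(x_scaling)) {
    x_scaling <- structure(list(min = rep(0, p), max = rep(1, p)),
                           class = "cpe_scaling")
  }
  q <- ncol(V)
  if (is.null(y_scaling)) {
    y_scaling <- structure(list(min = rep(0, q), max = rep(1, q)),
                           class = "cpe_scaling")
  }
  dimnames(W) <- list(input_names(space), NULL)
  dimnames(V) <- list(NULL, space$response_names[seq_len(q)])
  structure(
    list(n_in = p, n_hidden = ncol(W), n_out = q,
         activations = activations, W = W, b1 = b1, V = V, b2 = b2,
         x_scaling = x_scaling, y_scaling = y_scaling,
         space = space,
         fit = list(loss = NA_real_, seed = NA_integer_, n_runs = NA_integer_,
                    r_squared = rep(NA_real_, q)),
         call = NULL),
    class = "cpe_mlp"
  )
}

# A small continuous-only space with q responses for oracle tests.
toy_space <- function(k = 3L, responses = c("TPC", "TC", "AA")) {
  factor_space(lapply(seq_len(k), function(i) {
    continuous_factor(paste0("F", i), 0, 1)
  }), response_names = responses)
}

# Random well-determined linear design on toy_space: n runs, k inputs.
toy_linear_design <- function(n = 40L, k = 5L, noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  sp <- toy_space(k)
  X <- matrix(runif(n * k), n)
  B <- matrix(rnorm(k * 3), k)
  Y <- 5 + X %*% B + matrix(rnorm(n * 3, 0, noise_sd), n)
  Y <- Y - min(Y) + 0.5  # responses must be non-negative
  settings <- as.data.frame(X)
  names(settings) <- paste0("F", seq_len(k))
  cpe_design(sp, settings, as.data.frame(`colnames<-`(Y, c("TPC", "TC", "AA"))))
}
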