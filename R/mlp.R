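## Single-hidden-layer perceptron surrogate, trained by BFGS on the
## min-max-normalized scale. Activations mirror the repertoire of the
## software family this models: identity, logistic, tanh, exponential.

## the exponential activation gets a linear tail beyond x = 30: the value
## and derivative stay consistent and finite, so the optimizer can back out
## of saturation instead of hitting an overflow cliff
exp_cap <- 30

act_fun <- function(id) {
  switch(id,
    identity    = function(x) x,
    logistic    = function(x) 1 / (1 + exp(-x)),
    tanh        = tanh,
    exponential = function(x) {
      ifelse(x < exp_cap, exp(pmin(x, exp_cap)),
             exp(exp_cap) * (1 + (x - exp_cap)))
    },
    stop("unknown activation '", id, "'", call. = FALSE)
  )
}

act_grad <- function(id) {
  switch(id,
    identity    = function(x, fx) rep(1, length(x)),
    logistic    = function(x, fx) fx * (1 - fx),
    tanh        = function(x, fx) 1 - fx^2,
    exponential = function(x, fx) ifelse(x < exp_cap, fx, exp(exp_cap)),
    stop("unknown activation '", id, "'", call. = FALSE)
  )
}

# inverse of an activation, used to aim the output biases at the response
# means so that no restart starts in a saturated (zero-gradient) regime
act_inv <- function(id) {
  switch(id,
    identity    = function(y) y,
    logistic    = function(y) stats::qlogis(pmin(pmax(y, 1e-6), 1 - 1e-6)),
    tanh        = function(y) atanh(pmin(pmax(y, -1 + 1e-6), 1 - 1e-6)),
    exponential = function(y) log(pmax(y, 1e-6)),
    stop("unknown activation '", id, "'", call. = FALSE)
  )
}

#' Trainable parameter count of a single-hidden-layer MLP
#'
#' `n_in * n_hidden` input weights, `n_hidden` hidden biases,
#' `n_hidden * n_out` output weights and `n_out` output biases.
#' The screening surrogate topology (14, 7, 3) has 129 parameters.
#'
#' @param n_in,n_hidden,n_out Layer sizes (all >= 1).
#' @return Integer parameter count.
#' @export
#' @examples
#' mlp_param_count(14, 7, 3)  # 129
mlp_param_count <- function(n_in, n_hidden, n_out) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  as.integer(n_in * n_hidden + n_hidden + n_hidden * n_out + n_out)
}

unpack_theta <- function(theta, n_in, n_hidden, n_out) {
  i <- 0L
  W <- matrix(theta[i + seq_len(n_in * n_hidden)], n_in, n_hidden)
  i <- i + n_in * n_hidden
  b1 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  V <- matrix(theta[i + seq_len(n_hidden * n_out)], n_hidden, n_out)
  i <- i + n_hidden * n_out
  b2 <- theta[i + seq_len(n_out)]
  list(W = W, b1 = b1, V = V, b2 = b2)
}

# forward pass on the normalized scale; X is n x n_in
mlp_forward_scaled <- function(X, W, b1, V, b2, act) {
  f1 <- act_fun(act[[1L]]); f2 <- act_fun(act[[2L]])
  Z <- sweep(X %*% W, 2L, b1, "+")
  H <- f1(Z)
  O <- sweep(H %*% V, 2L, b2, "+")
  list(Z = Z, H = H, O = O, P = f2(O))
}

#' Fit the MLP surrogate to a design/response table
#'
#' Trains a single-hidden-layer perceptron mapping the one-hot-encoded,
#' min-max-normalized factor settings to the min-max-normalized responses by
#' minimizing the summed squared error over all outputs with the BFGS
#' quasi-Newton algorithm (analytic gradients), from one random
#' initialization with weights and biases drawn uniformly on (-0.5, 0.5).
#'
#' With identity activations in both layers the network family equals the
#' family of affine maps, so on a full-row-rank table with enough parameters
#' the fit interpolates (training r-squared 1 per output).
#'
#' @param design A `cpe_design` with responses.
#' @param hidden Number of hidden neurons (>= 1).
#' @param activations Length-2 character vector `(hidden, output)`, each one
#'   of `"identity"`, `"logistic"`, `"tanh"`, `"exponential"`.
#' @param seed Integer seed for the weight initialization.
#' @param maxit Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @return An object of class `cpe_mlp` with components `W`, `b1`, `V`, `b2`,
#'   scaling parameters, and `fit` statistics (per-output r-squared, final
#'   loss, convergence code, seed).
#' @seealso [cpe_mlp_search()] for the multi-restart topology search,
#'   [predict.cpe_mlp()], [yoon_sensitivity()], [cpe_optimize()].
#' @export
#' @examples
#' pb <- cpe_fixture("pb_design_responses")
#' fit <- cpe_mlp(pb, hidden = 7, seed = 1)
#' summary(fit)
cpe_mlp <- function(design, hidden = 7L,
                    activations = c("identity", "identity"),
                    seed = 1L, maxit = 500L, reltol = 1e-12) {
  stopifnot(inherits(design, "cpe_design"), hidden >= 1L,
            length(activations) == 2L)
  if (is.null(design$responses)) stop("design has no responses", call. = FALSE)
  for (a in activations) act_fun(a)  # validate ids

  Xraw <- encode_settings(design$space, design$settings)
  Yraw <- as.matrix(design$responses)
  x_scaling <- fit_scaling(Xraw)
  y_scaling <- fit_scaling(Yraw)
  X <- apply_scaling(x_scaling, Xraw)
  Y <- apply_scaling(y_scaling, Yraw)

  n_in <- ncol(X); n_out <- ncol(Y); h <- as.integer(hidden)
  n_par <- mlp_param_count(n_in, h, n_out)
  g1 <- act_grad(activations[[1L]]); g2 <- act_grad(activations[[2L]])

  loss_fn <- function(theta) {
    p <- unpack_theta(theta, n_in, h, n_out)
    fw <- mlp_forward_scaled(X, p$W, p$b1, p$V, p$b2, activations)
    E <- fw$P - Y
    if (any(!is.finite(E))) return(1e12)
    0.5 * sum(E * E)
  }
  grad_fn <- function(theta) {
    p <- unpack_theta(theta, n_in, h, n_out)
    fw <- mlp_forward_scaled(X, p$W, p$b1, p$V, p$b2, activations)
    E <- fw$P - Y
    if (any(!is.finite(E))) return(rep(0, n_par))
    dO <- E * g2(fw$O, fw$P)
    dV <- crossprod(fw$H, dO)
    db2 <- colSums(dO)
    dH <- dO %*% t(p$V)
    dZ <- dH * g1(fw$Z, fw$H)
    dW <- crossprod(X, dZ)
    db1 <- colSums(dZ)
    c(dW, db1, dV, db2)
  }

  run_once <- function(s) {
    set.seed(s)
    # fan-in-scaled uniform initialization keeps pre-activations O(1) (so
    # saturating and exponential hidden units start alive), and the output
    # biases are aimed at the response means so no restart starts in a
    # saturated zero-gradient regime
    theta0 <- stats::runif(n_par, -0.5, 0.5) *
      rep(c(1 / sqrt(n_in), 1, 1 / sqrt(h), 0.2),
          c(n_in * h, h, h * n_out, n_out))
    b2_idx <- n_par - n_out + seq_len(n_out)
    theta0[b2_idx] <- theta0[b2_idx] + act_inv(activations[[2L]])(colMeans(Y))
    stats::optim(theta0, loss_fn, grad_fn, method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol))
  }
  opt <- tryCatch(run_once(as.integer(seed)), error = function(e) e)
  if (inherits(opt, "error")) {
    # one retry with a derived sub-seed before surfacing the failure
    opt <- tryCatch(run_once(derive_seed(as.integer(seed), 999L)),
                    error = function(e) {
                      stop("MLP training failed: ", conditionMessage(e),
                           call. = FALSE)
                    })
  }

  p <- unpack_theta(opt$par, n_in, h, n_out)
  dimnames(p$W) <- list(input_names(design$space), NULL)
  dimnames(p$V) <- list(NULL, design$space$response_names)
  model <- structure(
    list(n_in = n_in, n_hidden = h, n_out = n_out,
         activations = as.character(activations),
         W = p$W, b1 = p$b1, V = p$V, b2 = p$b2,
         x_scaling = x_scaling, y_scaling = y_scaling,
         space = design$space,
         fit = list(loss = opt$value, convergence = opt$convergence,
                    counts = opt$counts, seed = as.integer(seed),
                    n_runs = nrow(X)),
         call = match.call()),
    class = "cpe_mlp"
  )
  model$fit$r_squared <- r_squared(model, design)
  model
}

#' Predict responses from a fitted surrogate
#'
#' Encodes and normalizes the new settings, runs the forward pass
#' `f2(b2 + V' f1(b1 + W' x))` on the normalized scale, and inverse-scales
#' the outputs back to original response units.
#'
#' @param object A `cpe_mlp`.
#' @param newdata A `cpe_design`, or a data frame of factor settings.
#' @param ... Unused.
#' @return Numeric matrix (runs x responses) in original units.
#' @export
predict.cpe_mlp <- function(object, newdata, ...) {
  settings <- if (inherits(newdata, "cpe_design")) newdata$settings else newdata
  Xraw <- encode_settings(object$space, settings)
  if (ncol(Xraw) != object$n_in) stop("input width mismatch", call. = FALSE)
  X <- apply_scaling(object$x_scaling, Xraw)
  fw <- mlp_forward_scaled(X, object$W, object$b1, object$V, object$b2,
                           object$activations)
  out <- invert_scaling(object$y_scaling, fw$P)
  colnames(out) <- object$space$response_names
  out
}

#' Per-output coefficient of determination on a table
#'
#' `r^2 = 1 - SSres/SStot` per response, computed in original units with
#' SStot taken about the evaluation table's own response means. A
#' zero-variance response column has no defined r-squared and is returned as
#' `NA` with a warning.
#'
#' @param model A `cpe_mlp`.
#' @param design A `cpe_design` with responses.
#' @return Named numeric vector, one value per response.
#' @export
r_squared <- function(model, design) {
  stopifnot(inherits(model, "cpe_mlp"), inherits(design, "cpe_design"))
  if (is.null(design$responses)) stop("design has no responses", call. = FALSE)
  Y <- as.matrix(design$responses)
  P <- predict(model, design)
  ss_res <- colSums((Y - P)^2)
  ss_tot <- colSums(sweep(Y, 2L, colMeans(Y), "-")^2)
  out <- ifelse(ss_tot == 0, NA_real_, 1 - ss_res / ss_tot)
  if (anyNA(out)) {
    warning("r-squared undefined for zero-variance response(s): ",
            paste(colnames(Y)[is.na(out)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(out, colnames(Y))
}

#' @export
fitted.cpe_mlp <- function(object, ...) {
  stop("cpe_mlp does not store its training table; call predict() on it",
       call. = FALSE)
}

#' @export
print.cpe_mlp <- function(x, ...) {
  cat(sprintf("MLP %d-%d-%d surrogate (%s hidden / %s output), %d parameters\n",
              x$n_in, x$n_hidden, x$n_out,
              x$activations[1L], x$activations[2L],
              mlp_param_count(x$n_in, x$n_hidden, x$n_out)))
  cat(sprintf("Trained on %d runs, loss %.3e (seed %d)\n",
              x$fit$n_runs, x$fit$loss, x$fit$seed))
  r2 <- x$fit$r_squared
  cat("Training r-squared:",
      paste(sprintf("%s = %.3f", names(r2), r2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cpe_mlp <- function(object, ...) {
  print(object)
  if (object$fit$n_runs < mlp_param_count(object$n_in, object$n_hidden,
                                          object$n_out)) {
    cat("Note: more parameters than training runs; r-squared near 1 reflects\n",
        "interpolation of the training table, not generalization.\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.cpe_mlp <- function(object, ...) {
  list(W = object$W, b1 = object$b1, V = object$V, b2 = object$b2)
}

#' Residuals of the surrogate on a design table
#'
#' @param object A `cpe_mlp`.
#' @param design A `cpe_design` with responses (the model does not store its
#'   training table).
#' @param ... Unused.
#' @return Matrix of observed minus predicted responses, original units.
#' @export
residuals.cpe_mlp <- function(object, design, ...) {
  as.matrix(design$responses) - predict(object, design)
}

#' Observed-versus-predicted plot for a fitted surrogate
#'
#' @param x A `cpe_mlp`.
#' @param design A `cpe_design` with responses.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cpe_mlp <- function(x, design, ...) {
  obs <- as.matrix(design$responses)
  prd <- predict(x, design)
  old <- graphics::par(mfrow = c(1, ncol(obs)))
  on.exit(graphics::par(old))
  for (j in seq_len(ncol(obs))) {
    graphics::plot(obs[, j], prd[, j], xlab = "observed", ylab = "predicted",
                   main = colnames(obs)[j], ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 1009 + 12345) %%
               2147483647)
}

#' Multi-restart topology search for the MLP surrogate
#'
#' Trains `restarts` randomly initialized networks for every combination of
#' hidden-layer size and activation pair, and selects the candidate with the
#' highest mean training r-squared across the responses. Ties are broken by
#' fewer hidden neurons, then lower final loss, then lower restart index.
#' Restart sub-seeds are derived deterministically from `seed` and the
#' candidate's (hidden size, activations, restart) coordinates, so enlarging
#' `restarts` only appends candidates.
#'
#' @param design A `cpe_design` with responses.
#' @param hidden Integer vector of hidden-layer sizes to try (default 5:20).
#' @param restarts Random restarts per configuration.
#' @param activations List of length-2 character vectors (hidden, output
#'   activation) to try; default is the identity/identity reference
#'   configuration only.
#' @param seed Master seed.
#' @param maxit,reltol Passed to [cpe_mlp()].
#' @return The selected `cpe_mlp`, with the full candidate log (a data frame)
#'   attached as `model$search_log`.
#' @export
#' @examples
#' pb <- cpe_fixture("pb_design_responses")
#' best <- cpe_mlp_search(pb, hidden = c(5, 7), restarts = 2, seed = 1)
#' mean(best$fit$r_squared)
cpe_mlp_search <- function(design, hidden = 5:20, restarts = 10L,
                           activations = list(c("identity", "identity")),
                           seed = 1L, maxit = 500L, reltol = 1e-12) {
  stopifnot(restarts >= 1L, length(hidden) >= 1L, length(activations) >= 1L)
  log <- list(); best <- NULL; best_key <- NULL; i <- 0L
  for (ai in seq_along(activations)) {
    act <- activations[[ai]]
    for (h in sort(as.integer(hidden))) {
      for (r in seq_len(restarts)) {
        i <- i + 1L
        sub <- derive_seed(as.integer(seed), h * 10000L + ai * 100L + r)
        m <- tryCatch(
          cpe_mlp(design, hidden = h, activations = act, seed = sub,
                  maxit = maxit, reltol = reltol),
          error = function(e) NULL
        )
        if (is.null(m)) {
          log[[i]] <- data.frame(hidden = h, act_hidden = act[1L],
                                 act_output = act[2L], restart = r, seed = sub,
                                 loss = NA_real_, mean_r2 = NA_real_,
                                 failed = TRUE)
          next
        }
        mr2 <- mean(m$fit$r_squared)
        log[[i]] <- data.frame(hidden = h, act_hidden = act[1L],
                               act_output = act[2L], restart = r, seed = sub,
                               loss = m$fit$loss, mean_r2 = mr2, failed = FALSE)
        key <- c(-mr2, h, m$fit$loss, r)   # lexicographic selection key
        if (is.null(best) ||
            (!is.na(mr2) && lex_less(key, best_key))) {
          best <- m; best_key <- key
          best$fit$restart <- r
        }
      }
    }
  }
  if (is.null(best)) stop("all restarts failed", call. = FALSE)
  best$search_log <- do.call(rbind, log)
  best
}

# strict lexicographic a < b
lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Serialize / deserialize a fitted surrogate as structured text
#'
#' Writes topology, activation identifiers, weight arrays, scaling parameters
#' and fit statistics as JSON with 17 significant digits, which round-trips
#' IEEE doubles exactly: a written-then-read model reproduces predictions
#' bit-for-bit. The factor space is reconstructed from its serialized
#' definition.
#'
#' @param model A `cpe_mlp`.
#' @param path File path.
#' @export
write_mlp <- function(model, path) {
  stopifnot(inherits(model, "cpe_mlp"))
  sp <- model$space
  space_repr <- list(
    factors = lapply(unname(sp$factors), function(f) {
      f["class"] <- NULL
      f[!vapply(f, is.null, TRUE)]
    }),
    response_names = sp$response_names,
    response_units = sp$response_units
  )
  obj <- list(
    topology = c(model$n_in, model$n_hidden, model$n_out),
    activations = model$activations,
    W = model$W, b1 = model$b1, V = model$V, b2 = model$b2,
    x_scaling = list(min = unname(model$x_scaling$min),
                     max = unname(model$x_scaling$max)),
    y_scaling = list(min = unname(model$y_scaling$min),
                     max = unname(model$y_scaling$max)),
    fit = model$fit[c("loss", "seed", "n_runs", "r_squared")],
    space = space_repr
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              matrix = "rowmajor"), path)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  factors <- lapply(seq_len(nrow_or_len(obj$space$factors)), function(i) {
    f <- index_factor(obj$space$factors, i)
    if (f$kind == "continuous") {
      continuous_factor(f$name, f$low, f$high, grid = f$grid,
                        units = f$units %||% "")
    } else {
      categorical_factor(f$name, f$levels, units = f$units %||% "")
    }
  })
  sp <- factor_space(factors, response_names = obj$space$response_names,
                     response_units = obj$space$response_units)
  W <- if (is.matrix(obj$W)) obj$W else
    matrix(obj$W, obj$topology[1L], obj$topology[2L])
  V <- if (is.matrix(obj$V)) obj$V else
    matrix(obj$V, obj$topology[2L], obj$topology[3L])
  dimnames(W) <- list(input_names(sp), NULL)
  dimnames(V) <- list(NULL, sp$response_names)
  fit <- as.list(obj$fit)
  fit$r_squared <- stats::setNames(unlist(fit$r_squared), sp$response_names)
  structure(
    list(n_in = obj$topology[1L], n_hidden = obj$topology[2L],
         n_out = obj$topology[3L], activations = obj$activations,
         W = W, b1 = obj$b1, V = V, b2 = obj$b2,
         x_scaling = structure(list(min = obj$x_scaling$min,
                                    max = obj$x_scaling$max),
                               class = "cpe_scaling"),
         y_scaling = structure(list(min = obj$y_scaling$min,
                                    max = obj$y_scaling$max),
                               class = "cpe_scaling"),
         space = sp,
         fit = fit,
         call = NULL),
    class = "cpe_mlp"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

index_factor <- function(x, i) {
  if (is.data.frame(x)) {
    f <- as.list(x[i, , drop = FALSE])
    f <- lapply(f, function(v) if (is.list(v)) v[[1L]] else v)
    f[!vapply(f, function(v) is.null(v) || all(is.na(v)), TRUE)]
  } else {
    x[[i]]
  }
}
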