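## Mixed-variable NSGA-II-style evolutionary maximization of the surrogate's
## predicted responses over the factor space: tournament selection on
## (nondomination rank, crowding distance), uniform crossover on categorical
## genes, blend crossover + Gaussian mutation (clipped to bounds) on
## continuous genes, elitist environmental selection.

#' Non-dominated subset of objective vectors (maximization)
#'
#' A point dominates another when it is at least as large in every objective
#' and strictly larger in at least one. Returns the maximal (non-dominated)
#' points.
#'
#' @param points Numeric matrix, one row per point, one column per objective.
#' @return Logical vector marking the non-dominated rows.
#' @export
#' @examples
#' pareto_filter(rbind(c(2, 0), c(0, 2), c(1, 1), c(0.5, 0.5)))
pareto_filter <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!n) stop("need at least one point", call. = FALSE)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(points[j, ] >= points[i, ]) && any(points[j, ] > points[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

#' Equal-weights compromise point of a Pareto front
#'
#' Min-max normalizes each objective over the front and returns the index of
#' the member maximizing the weighted sum of normalized objectives. A
#' constant objective contributes 0 for every member. Ties resolve to the
#' first member in front order.
#'
#' @param objectives Numeric matrix of front members' objective values.
#' @param weights Objective weights (default equal); normalized internally.
#' @return Integer index of the compromise member.
#' @export
#' @examples
#' compromise_point(rbind(c(1, 0), c(0, 1), c(0.9, 0.9)))  # 3
compromise_point <- function(objectives, weights = NULL) {
  objectives <- as.matrix(objectives)
  if (!nrow(objectives)) stop("empty front", call. = FALSE)
  m <- ncol(objectives)
  if (is.null(weights)) weights <- rep(1, m)
  weights <- weights / sum(weights)
  lo <- apply(objectives, 2L, min)
  hi <- apply(objectives, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  norm <- sweep(sweep(objectives, 2L, lo, "-"), 2L, rng, "/")
  norm[, hi == lo] <- 0
  which.max(norm %*% weights)
}

# fast-enough nondominated sorting (n <= a few hundred)
nds_rank <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    idx <- which(remaining)
    nd <- pareto_filter(obj[idx, , drop = FALSE])
    rank[idx[nd]] <- r
    remaining[idx[nd]] <- FALSE
  }
  rank
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  if (n <= 2L) return(rep(Inf, n))
  for (j in seq_len(ncol(obj))) {
    o <- order(obj[, j])
    d[o[c(1L, n)]] <- Inf
    rng <- obj[o[n], j] - obj[o[1L], j]
    if (rng == 0) next
    d[o[2:(n - 1L)]] <- d[o[2:(n - 1L)]] +
      (obj[o[3:n], j] - obj[o[1:(n - 2L)], j]) / rng
  }
  d
}

#' Multi-objective optimization of predicted responses
#'
#' Maximizes all responses predicted by a fitted surrogate simultaneously
#' over the factor space with an NSGA-II-style evolutionary algorithm
#' handling mixed categorical/continuous decision variables. Continuous
#' genes evolve by blend (BLX-0.5) crossover and Gaussian mutation (sigma =
#' 5% of range), clipped to the factor bounds; categorical genes by uniform
#' crossover and random level resets. The final population is filtered to
#' its non-dominated set and an equal-weights compromise member is selected
#' (see [compromise_point()]).
#'
#' @param model A `cpe_mlp`.
#' @param space Factor space to search (default: the model's own). Continuous
#'   bounds default to the declared factor ranges; override with `bounds`.
#' @param generations,pop Evolution length and population size.
#' @param seed Integer seed; results are bit-reproducible for a fixed seed.
#' @param weights Compromise weights (default equal).
#' @param p_crossover Per-pair crossover probability.
#' @param mutation_sd Gaussian mutation scale as a fraction of each
#'   continuous factor's range.
#' @param polish Rounds of final local dominance polish: each front member
#'   is perturbed (Gaussian, up to 5% of range, scale varied per round) and
#'   replaced whenever the perturbation dominates it. With three objectives the population is
#'   front-saturated well before the last generation and stragglers that a
#'   dominating neighbour would beat can survive; the polish removes them.
#'   Set 0 to disable.
#' @param bounds Optional named list of length-2 numeric bounds per
#'   continuous factor, overriding the space's ranges.
#' @return An object of class `cpe_pareto`: `front` (settings data frame),
#'   `front_objectives` (predicted responses), `compromise` (row index into
#'   the front), `trace` (per-generation best equal-weight score), `config`.
#' @export
#' @examples
#' pb <- cpe_fixture("pb_design_responses")
#' fit <- cpe_mlp(pb, hidden = 7, seed = 1)
#' opt <- cpe_optimize(fit, generations = 10, pop = 40, seed = 1)
#' opt$front_objectives[opt$compromise, ]
cpe_optimize <- function(model, space = model$space, generations = 36L,
                         pop = 100L, seed = 1L, weights = NULL,
                         p_crossover = 0.9, mutation_sd = 0.05,
                         polish = 25L, bounds = NULL) {
  stopifnot(inherits(model, "cpe_mlp"), inherits(space, "cpe_factor_space"),
            generations >= 1L, pop >= 4L)
  set.seed(as.integer(seed))

  facs <- space$factors
  is_cont <- vapply(facs, function(f) f$kind == "continuous", TRUE)
  cont <- names(facs)[is_cont]
  cat_ <- names(facs)[!is_cont]
  lo <- vapply(cont, function(nm) {
    if (!is.null(bounds[[nm]])) bounds[[nm]][1L] else facs[[nm]]$low
  }, 0)
  hi <- vapply(cont, function(nm) {
    if (!is.null(bounds[[nm]])) bounds[[nm]][2L] else facs[[nm]]$high
  }, 0)
  if (any(hi <= lo)) stop("empty feasible space: invalid bounds", call. = FALSE)
  nlev <- vapply(cat_, function(nm) length(facs[[nm]]$levels), 0L)
  n_genes <- length(cont) + length(cat_)
  p_mut <- 1 / n_genes
  sd_mut <- mutation_sd * (hi - lo)

  decode <- function(Xc, Xk) {
    df <- as.data.frame(Xc)
    names(df) <- cont
    for (i in seq_along(cat_)) {
      df[[cat_[i]]] <- facs[[cat_[i]]]$levels[Xk[, i]]
    }
    df[names(facs)]
  }
  evaluate <- function(Xc, Xk) {
    unname(predict(model, decode(Xc, Xk)))
  }

  # initial population: uniform in the box, uniform over levels
  Xc <- matrix(stats::runif(pop * length(cont)), pop)
  Xc <- sweep(sweep(Xc, 2L, hi - lo, "*"), 2L, lo, "+")
  Xk <- if (length(cat_)) {
    matrix(0L, pop, length(cat_))
  } else {
    matrix(0L, pop, 0L)
  }
  for (i in seq_along(cat_)) Xk[, i] <- sample.int(nlev[i], pop, replace = TRUE)
  obj <- evaluate(Xc, Xk)

  trace <- numeric(generations)
  for (gen in seq_len(generations)) {
    rank <- nds_rank(obj)
    crowd <- numeric(pop)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
    }
    tournament <- function() {
      a <- sample.int(pop, 1L); b <- sample.int(pop, 1L)
      if (rank[a] < rank[b]) a
      else if (rank[b] < rank[a]) b
      else if (crowd[a] >= crowd[b]) a else b
    }
    Cc <- Xc; Ck <- Xk
    for (p in seq_len(floor(pop / 2))) {
      i1 <- tournament(); i2 <- tournament()
      c1c <- Xc[i1, ]; c2c <- Xc[i2, ]
      c1k <- Xk[i1, ]; c2k <- Xk[i2, ]
      if (stats::runif(1) < p_crossover) {
        if (length(cont)) {  # BLX-0.5 blend
          a <- stats::runif(length(cont), -0.5, 1.5)
          t1 <- a * c1c + (1 - a) * c2c
          t2 <- (1 - a) * c1c + a * c2c
          c1c <- t1; c2c <- t2
        }
        if (length(cat_)) {  # uniform
          swap <- stats::runif(length(cat_)) < 0.5
          tmp <- c1k[swap]; c1k[swap] <- c2k[swap]; c2k[swap] <- tmp
        }
      }
      mutate <- function(xc, xk) {
        if (length(cont)) {
          hit <- stats::runif(length(cont)) < p_mut
          xc[hit] <- xc[hit] + stats::rnorm(sum(hit), 0, sd_mut[hit])
        }
        if (length(cat_)) {
          hit <- stats::runif(length(cat_)) < p_mut
          for (i in which(hit)) xk[i] <- sample.int(nlev[i], 1L)
        }
        list(xc = pmin(pmax(xc, lo), hi), xk = xk)
      }
      m1 <- mutate(c1c, c1k); m2 <- mutate(c2c, c2k)
      Cc[2L * p - 1L, ] <- m1$xc; Ck[2L * p - 1L, ] <- m1$xk
      Cc[2L * p, ] <- m2$xc;      Ck[2L * p, ] <- m2$xk
    }
    cobj <- evaluate(Cc, Ck)

    # elitist environmental selection on the combined population
    Ac <- rbind(Xc, Cc); Ak <- rbind(Xk, Ck); aobj <- rbind(obj, cobj)
    arank <- nds_rank(aobj)
    acrowd <- numeric(nrow(aobj))
    for (r in unique(arank)) {
      idx <- which(arank == r)
      acrowd[idx] <- crowding_distance(aobj[idx, , drop = FALSE])
    }
    keep <- order(arank, -acrowd)[seq_len(pop)]
    Xc <- Ac[keep, , drop = FALSE]
    Xk <- Ak[keep, , drop = FALSE]
    obj <- aobj[keep, , drop = FALSE]

    sc <- apply(obj, 2L, function(v) {
      r <- range(v); if (diff(r) == 0) rep(0, length(v)) else (v - r[1L]) / diff(r)
    })
    trace[gen] <- max(rowMeans(sc))
  }

  # local dominance polish: climb each member to the surface where a small
  # perturbation strictly dominates it
  for (p in seq_len(polish)) {
    if (length(cont)) {
      step <- stats::runif(1, 0.1, 1)  # vary the climb scale across rounds
      Pc <- Xc + matrix(stats::rnorm(pop * length(cont)), pop) %*%
        diag(step * sd_mut, length(cont))
      Pc <- pmin(pmax(Pc, matrix(lo, pop, length(cont), byrow = TRUE)),
                 matrix(hi, pop, length(cont), byrow = TRUE))
      pobj <- evaluate(Pc, Xk)
      better <- vapply(seq_len(pop), function(i) {
        all(pobj[i, ] >= obj[i, ]) && any(pobj[i, ] > obj[i, ])
      }, TRUE)
      Xc[better, ] <- Pc[better, , drop = FALSE]
      obj[better, ] <- pobj[better, , drop = FALSE]
    }
  }

  nd <- which(pareto_filter(obj))
  # drop duplicated objective rows (GA populations accumulate copies)
  nd <- nd[!duplicated(round(obj[nd, , drop = FALSE], 10L))]
  front_obj <- obj[nd, , drop = FALSE]
  colnames(front_obj) <- space$response_names
  front <- decode(Xc[nd, , drop = FALSE], Xk[nd, , drop = FALSE])
  comp <- compromise_point(front_obj, weights)
  structure(
    list(front = front, front_objectives = front_obj, compromise = comp,
         trace = trace,
         config = list(generations = generations, pop = pop, seed = seed,
                       p_crossover = p_crossover, mutation_sd = mutation_sd,
                       weights = weights)),
    class = "cpe_pareto"
  )
}

#' @export
print.cpe_pareto <- function(x, ...) {
  cat(sprintf("Pareto front: %d non-dominated points (%d generations, pop %d, seed %s)\n",
              nrow(x$front), x$config$generations, x$config$pop,
              format(x$config$seed)))
  cat("Compromise (equal weights unless configured):\n")
  print(cbind(x$front[x$compromise, , drop = FALSE],
              as.data.frame(x$front_objectives)[x$compromise, , drop = FALSE]))
  invisible(x)
}

#' Pairwise scatter of the Pareto front
#'
#' @param x A `cpe_pareto`.
#' @param ... Passed to [graphics::pairs()].
#' @export
plot.cpe_pareto <- function(x, ...) {
  obj <- x$front_objectives
  if (ncol(obj) == 2L) {
    graphics::plot(obj, ...)
    graphics::points(obj[x$compromise, 1L], obj[x$compromise, 2L],
                     pch = 19, col = 2)
  } else {
    graphics::pairs(obj, ...)
  }
  invisible(x)
}

#' Write a Pareto result as delimited text
#'
#' @param result A `cpe_pareto`.
#' @param path File path.
#' @export
write_pareto <- function(result, path) {
  df <- cbind(result$front, as.data.frame(result$front_objectives))
  df$compromise <- seq_len(nrow(df)) == result$compromise
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
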