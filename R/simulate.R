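## Response-surface simulator: multiplicative graded effects per factor,
## phase-separation gates that zero all responses, and multiplicative
## log-normal replicate noise. The default configuration emulates the
## OVAT-observed effect shapes of the CPE screening study.

#' Build a response-surface simulator configuration
#'
#' The simulated noiseless response is
#' `gate(settings) * baseline_j * prod_i f_ij(x_i)` per response `j`, where
#' `f_ij` is a piecewise-linear multiplier profile (continuous factors) or a
#' per-level multiplier (categorical factors), and `gate` is 0 when any
#' phase-separation rule fires and 1 otherwise. Replicate noise in
#' [simulate_table()] is multiplicative log-normal.
#'
#' The default configuration mirrors the OVAT findings qualitatively:
#' saturating surfactant-concentration effect, solid:liquid ratio peaked at
#' 1:50, pH effect opposite in sign for phenolics versus carotenoids,
#' equilibration temperature peaked at 45 degC, mildly decreasing
#' equilibration time, decreasing centrifugation speed and time, and a lower
#' second-step multiplier for carotenoids. Gates: no phase separation for
#' Span 85 / Ceteareth-12, for CaCl2, below 15% salt, or at >= 75 degC
#' combined with >= 18% salt (which reproduces all-zero rows in
#' Plackett-Burman tables using the printed level pairing). Effect
#' prominences sit well above the default replicate noise so the synthetic
#' optimum is identifiable at the designs' resolution.
#'
#' @param space Factor space the simulator is defined on.
#' @param baseline Named response baseline (response at all-multipliers-1).
#' @param effects Named list (per factor) of effect definitions: continuous
#'   factors take `list(knots = <numeric>, mult = <matrix knots x responses>)`,
#'   categorical factors `list(mult = <matrix levels x responses>)`.
#' @param gates List of gating rules; each is one of
#'   `list(type = "level", factor, levels)`,
#'   `list(type = "below", factor, threshold)`,
#'   `list(type = "and_ge", factors, thresholds)`.
#' @param noise_cv Per-response coefficient of variation of the log-normal
#'   replicate noise.
#' @return An object of class `cpe_sim_config`.
#' @export
#' @examples
#' cfg <- cpe_sim_config()
#' true_response(cfg, ovat_center())
cpe_sim_config <- function(space = cpe_ovat_space(),
                           baseline = c(TPC = 350, TC = 16.5, AA = 980),
                           effects = default_sim_effects(),
                           gates = default_sim_gates(),
                           noise_cv = c(TPC = 0.03, TC = 0.03, AA = 0.03)) {
  stopifnot(inherits(space, "cpe_factor_space"))
  rn <- space$response_names
  baseline <- baseline[rn]
  noise_cv <- noise_cv[rn]
  if (any(!is.finite(baseline)) || any(baseline < 0)) {
    stop("baselines must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(noise_cv)) || any(noise_cv < 0)) {
    stop("noise CVs must be finite and non-negative", call. = FALSE)
  }
  for (nm in names(effects)) {
    f <- space$factors[[nm]]
    if (is.null(f)) stop("effect for unknown factor '", nm, "'", call. = FALSE)
    e <- effects[[nm]]
    if (f$kind == "continuous") {
      stopifnot(length(e$knots) >= 1L, nrow(e$mult) == length(e$knots),
                ncol(e$mult) == length(rn))
    } else {
      stopifnot(nrow(e$mult) == length(f$levels), ncol(e$mult) == length(rn))
    }
  }
  structure(list(space = space, baseline = baseline, effects = effects,
                 gates = gates, noise_cv = noise_cv),
            class = "cpe_sim_config")
}

# multiplier matrix helper: one column per response (TPC, TC, AA)
mm <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("TPC", "TC", "AA")
  m
}

#' @rdname cpe_sim_config
#' @export
default_sim_effects <- function() {
  list(
    X1 = list(mult = mm(c(1, 1, 1),            # Tween 80
                        c(0.65, 0.65, 0.65),   # Triton X-100
                        c(0.5, 0.5, 0.5),      # Ceteareth-12 (gated anyway)
                        c(0.5, 0.5, 0.5))),    # Span 85 (gated anyway)
    X2 = list(knots = c(2, 4, 6, 8, 10),
              mult = mm(c(0.6, 0.6, 0.6), c(0.82, 0.82, 0.82),
                        c(0.88, 0.88, 0.88), c(0.96, 0.96, 0.96),
                        c(1, 1, 1))),
    X3 = list(knots = parse_ratio(c("1:100", "1:70", "1:50", "1:30", "1:10")),
              mult = mm(c(0.61, 0.61, 0.61), c(0.89, 0.89, 0.89),
                        c(1, 1, 1), c(0.67, 0.67, 0.67),
                        c(0.53, 0.53, 0.53))),
    X4 = list(knots = c(1.5, 3, 4.5, 6, 7.5),  # opposite sign for TC
              mult = mm(c(0.82, 0.85, 0.82), c(1, 0.88, 1),
                        c(0.63, 0.95, 0.63), c(0.5, 1, 0.5),
                        c(0.45, 1, 0.45))),
    X5 = list(knots = c(35, 45, 55, 65, 75),
              mult = mm(c(0.82, 0.82, 0.82), c(1, 1, 1),
                        c(0.75, 0.75, 0.75), c(0.6, 0.6, 0.6),
                        c(0.3, 0.3, 0.3))),
    X6 = list(knots = c(20, 60),
              mult = mm(c(1, 1, 1), c(0.72, 0.72, 0.72))),
    X7 = list(mult = mm(c(1, 1, 1),            # NaCl
                        c(0.75, 0.75, 0.75),   # KCl
                        c(0.5, 0.5, 0.5))),    # CaCl2 (gated anyway)
    X8 = list(knots = c(6, 10, 14, 16, 18),
              mult = mm(c(0.5, 0.5, 0.5), c(0.7, 0.7, 0.7),
                        c(0.9, 0.9, 0.9), c(1, 1, 1),
                        c(0.72, 0.72, 0.72))),
    X9 = list(knots = c(2473, 5564, 9892),
              mult = mm(c(1, 1, 1), c(0.92, 0.92, 0.92),
                        c(0.8, 0.8, 0.8))),
    X10 = list(knots = c(10, 15, 20),
               mult = mm(c(1, 1, 1), c(0.7, 0.7, 0.7),
                         c(0.55, 0.55, 0.55))),
    X11 = list(mult = mm(c(1, 1, 1),           # Step 1
                         c(0.75, 0.5, 0.75)))  # Step 2: TC halves
  )
}

#' @rdname cpe_sim_config
#' @export
default_sim_gates <- function() {
  list(
    list(type = "level", factor = "X1", levels = c("Ceteareth-12", "Span 85")),
    list(type = "level", factor = "X7", levels = "CaCl2"),
    list(type = "below", factor = "X8", threshold = 15),
    list(type = "and_ge", factors = c("X5", "X8"), thresholds = c(75, 18))
  )
}

# TRUE where any gate fires (no phase separation)
sim_gated <- function(config, settings) {
  out <- rep(FALSE, nrow(settings))
  for (g in config$gates) {
    fired <- switch(g$type,
      level = as.character(settings[[g$factor]]) %in% g$levels,
      below = as.numeric(settings[[g$factor]]) < g$threshold,
      and_ge = {
        hit <- rep(TRUE, nrow(settings))
        for (i in seq_along(g$factors)) {
          hit <- hit & as.numeric(settings[[g$factors[i]]]) >= g$thresholds[i]
        }
        hit
      },
      stop("unknown gate type '", g$type, "'", call. = FALSE)
    )
    out <- out | fired
  }
  out
}

# per-factor multiplier profile evaluated at x (vectorized over runs)
sim_multiplier <- function(factor_def, effect, x, j) {
  if (factor_def$kind == "continuous") {
    if (length(effect$knots) == 1L) return(rep(effect$mult[1L, j], length(x)))
    stats::approx(effect$knots, effect$mult[, j], xout = as.numeric(x),
                  rule = 2)$y
  } else {
    effect$mult[match(as.character(x), factor_def$levels), j]
  }
}

#' Noiseless simulated responses
#'
#' Evaluates the configuration's ground-truth surface: the per-response
#' baseline times every factor's multiplier, zeroed where a
#' phase-separation gate fires.
#'
#' @param config A `cpe_sim_config`.
#' @param settings Data frame of factor settings (one or more runs).
#' @return Numeric matrix (runs x responses).
#' @export
true_response <- function(config, settings) {
  stopifnot(inherits(config, "cpe_sim_config"))
  settings <- as.data.frame(settings, stringsAsFactors = FALSE)
  rn <- config$space$response_names
  n <- nrow(settings)
  out <- matrix(rep(config$baseline, each = n), n, length(rn),
                dimnames = list(NULL, rn))
  for (nm in names(config$effects)) {
    f <- config$space$factors[[nm]]
    e <- config$effects[[nm]]
    for (j in seq_along(rn)) {
      out[, j] <- out[, j] * sim_multiplier(f, e, settings[[nm]], j)
    }
  }
  out[sim_gated(config, settings), ] <- 0
  out
}

#' Simulate noisy responses onto a design
#'
#' Draws `replicates` multiplicative log-normal noise realizations per run
#' and response (`true * exp(e)`, `e ~ Normal(0, cv)`) and stores their
#' mean. Gated runs remain exactly zero whatever the noise or replicate
#' count. Fully determined by `seed`.
#'
#' @param config A `cpe_sim_config`.
#' @param design A `cpe_design` (its responses, if any, are replaced).
#' @param replicates Number of replicates averaged per run (>= 1; the assays
#'   the simulator emulates were run in triplicate).
#' @param seed Integer seed.
#' @return The design with simulated responses attached.
#' @export
#' @examples
#' cfg <- cpe_sim_config()
#' d <- ovat_grid(cfg$space, "X5", ovat_center())
#' simulate_table(cfg, d, replicates = 3, seed = 1)$responses
simulate_table <- function(config, design, replicates = 3L, seed = 1L) {
  stopifnot(inherits(config, "cpe_sim_config"), inherits(design, "cpe_design"),
            replicates >= 1L)
  tr <- true_response(config, design$settings)
  set.seed(as.integer(seed))
  n <- nrow(tr)
  resp <- tr
  for (j in seq_len(ncol(tr))) {
    cv <- config$noise_cv[j]
    noise <- matrix(stats::rnorm(n * replicates, 0, cv), n)
    resp[, j] <- tr[, j] * rowMeans(exp(noise))
  }
  cpe_design(design$space, design$settings, as.data.frame(resp))
}

#' Concatenate designs over a common factor space
#'
#' @param ... `cpe_design` objects sharing one factor space.
#' @return A single `cpe_design` with the runs stacked in order.
#' @export
bind_designs <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) >= 1L, all(vapply(ds, inherits, TRUE, "cpe_design")))
  settings <- do.call(rbind, lapply(ds, `[[`, "settings"))
  resp <- lapply(ds, `[[`, "responses")
  has <- !vapply(resp, is.null, TRUE)
  responses <- if (all(has)) do.call(rbind, resp) else NULL
  cpe_design(ds[[1L]]$space, settings, responses)
}

#' Drop failed-separation (all-zero) runs from a design
#'
#' @param design A `cpe_design` with responses.
#' @return The design without its all-zero response rows.
#' @export
drop_failed <- function(design) {
  keep <- !failed_separation(design)
  if (!any(keep)) stop("all runs are failed separations", call. = FALSE)
  cpe_design(design$space, design$settings[keep, , drop = FALSE],
             design$responses[keep, , drop = FALSE])
}
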