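## Verification arithmetic (relative errors, table sums, percentage shares)
## and the end-to-end pipeline driver.

# round half away from zero at `digits` decimals (the convention of the
# printed tables; base round() rounds half to even)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Relative error of a model value against an experimental value
#'
#' `(model - experimental) / experimental * 100`, rounded half away from
#' zero to two decimals - the convention under which the verification
#' table's sample-6 total-phenolics pair (139.12 model, 144.23
#' experimental) gives -3.54%.
#'
#' @param model,experimental Numeric vectors (recycled).
#' @return Signed percentage, 2 decimals; `NA` (with a warning) where the
#'   experimental value is 0.
#' @export
#' @examples
#' relative_error(139.12, 144.23)  # -3.54
relative_error <- function(model, experimental) {
  out <- ifelse(experimental == 0, NA_real_,
                round_half_away((model - experimental) / experimental * 100, 2L))
  if (anyNA(out)) {
    warning("relative error undefined where experimental value is 0",
            call. = FALSE)
  }
  out
}

#' Check a printed total against its addends
#'
#' @param values Numeric addends.
#' @param printed_total The total as printed.
#' @param tol Tolerance (default 0.01, the print precision).
#' @return List with `pass` and `delta` (= sum - printed_total).
#' @export
#' @examples
#' sum_check(c(416.72, 136.06), 552.78)
sum_check <- function(values, printed_total, tol = 0.01) {
  delta <- sum(values) - printed_total
  list(pass = abs(delta) <= tol, delta = delta)
}

#' Percentage share of a part in a whole
#'
#' @param part,whole Numerics, `whole > 0`.
#' @param digits Decimals of the (half-away-from-zero) rounding; the printed
#'   shares use whole percent (default 0).
#' @return Rounded percentage.
#' @export
#' @examples
#' share_percent(416.72, 552.78)  # 75
#' share_percent(42.86, 58.87)    # 73
share_percent <- function(part, whole, digits = 0L) {
  if (any(whole <= 0)) stop("whole must be positive", call. = FALSE)
  round_half_away(part / whole * 100, digits)
}

#' Recompute the verification table's relative errors
#'
#' Applies [relative_error()] to every model/experimental pair of the
#' bundled verification fixture (four modified screening runs plus the
#' optimal sample, for each of TP, TC, AA).
#'
#' @return Data frame in long form: sample, quantity, model, experimental,
#'   relative_error (%).
#' @export
#' @examples
#' v <- verification_errors()
#' subset(v, sample == "6" & quantity == "TP")$relative_error  # -3.54
verification_errors <- function() {
  tab <- cpe_fixture("verification")
  qty <- c("TP", "TC", "AA")
  out <- do.call(rbind, lapply(qty, function(q) {
    data.frame(sample = as.character(tab$sample), quantity = q,
               model = tab[[paste0("model_", q)]],
               experimental = tab[[paste0("exp_", q)]],
               stringsAsFactors = FALSE)
  }))
  out$relative_error <- relative_error(out$model, out$experimental)
  rownames(out) <- NULL
  out
}

#' Run the full screening-to-optimization pipeline
#'
#' Orchestrates design -> surrogate fit -> Yoon sensitivity -> multi-objective
#' optimization (-> verification arithmetic when the bundled fixture is the
#' data source) with all randomness derived from one seed. Rerunning with an
#' identical config reproduces every artifact bit-exactly.
#'
#' @param data `"fixture"` to use the bundled 12-run screening table, a
#'   `cpe_design` with responses, or a `cpe_sim_config` (a campaign is then
#'   simulated as in [recovery_experiment()]).
#' @param seed Master seed; stage sub-seeds are derived deterministically.
#' @param hidden,restarts,activations Passed to [cpe_mlp_search()].
#' @param generations,pop Passed to [cpe_optimize()].
#' @param out_dir Optional directory; when given, every artifact is written
#'   there as delimited/structured text together with a plain-text run log.
#' @return List of class `cpe_pipeline`: `design`, `model`, `sensitivity`,
#'   `pareto`, `verification` (fixture source only), `log` (character).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline("fixture", seed = 1, hidden = 7, restarts = 3)
#' mean(res$model$fit$r_squared)
#' }
run_pipeline <- function(data = "fixture", seed = 1L, hidden = 5:10,
                         restarts = 10L,
                         activations = list(c("identity", "identity")),
                         generations = 36L, pop = 100L, out_dir = NULL) {
  seed <- as.integer(seed)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("pipeline start: seed %d, package cpeopt %s", seed,
      as.character(utils::packageVersion("cpeopt")))

  is_fixture <- identical(data, "fixture")
  design <- stage("design", {
    if (is_fixture) {
      cpe_fixture("pb_design_responses")
    } else if (inherits(data, "cpe_design")) {
      if (is.null(data$responses)) stop("design has no responses")
      data
    } else if (inherits(data, "cpe_sim_config")) {
      pb <- pb_design(data$space, pairing = table2_pairing())
      sweeps <- lapply(names(data$space$factors), function(nm) {
        ovat_grid(data$space, nm, ovat_center())
      })
      simulate_table(data, do.call(bind_designs, c(list(pb), sweeps)),
                     seed = derive_seed(seed, 1L))
    } else {
      stop("data must be \"fixture\", a cpe_design, or a cpe_sim_config")
    }
  })
  say("design: %d runs, %d failed separations", nrow(design$settings),
      sum(failed_separation(design)))

  model <- stage("fit", {
    cpe_mlp_search(design, hidden = hidden, restarts = restarts,
                   activations = activations, seed = derive_seed(seed, 2L))
  })
  say("fit: MLP %d-%d-%d (%s/%s), mean training r2 = %.4f",
      model$n_in, model$n_hidden, model$n_out, model$activations[1L],
      model$activations[2L], mean(model$fit$r_squared))

  sens <- stage("sensitivity", yoon_sensitivity(model))
  say("sensitivity: top factors %s",
      paste(vapply(model$space$response_names,
                   function(j) paste0(j, ":", rank_factors(sens, j)[1L]), ""),
            collapse = ", "))

  pareto <- stage("optimize", {
    cpe_optimize(model, generations = generations, pop = pop,
                 seed = derive_seed(seed, 3L))
  })
  say("optimize: %d front points; compromise predicts %s",
      nrow(pareto$front),
      paste(sprintf("%s=%.2f", colnames(pareto$front_objectives),
                    pareto$front_objectives[pareto$compromise, ]),
            collapse = ", "))

  verification <- if (is_fixture) stage("verify", verification_errors()) else NULL
  if (!is.null(verification)) {
    say("verify: max |relative error| = %.2f%%",
        max(abs(verification$relative_error)))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_design(design, file.path(out_dir, "design.tsv"))
    write_mlp(model, file.path(out_dir, "model.json"))
    write_sensitivity(sens, file.path(out_dir, "sensitivity.tsv"))
    write_pareto(pareto, file.path(out_dir, "pareto.tsv"))
    if (!is.null(verification)) {
      utils::write.table(verification, file.path(out_dir, "verification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(log, file.path(out_dir, "run.log"))
    say("artifacts written to %s", out_dir)
  }

  structure(list(design = design, model = model, sensitivity = sens,
                 pareto = pareto, verification = verification, log = log,
                 seed = seed),
            class = "cpe_pipeline")
}

#' @export
print.cpe_pipeline <- function(x, ...) {
  writeLines(x$log)
  invisible(x)
}
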