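#' Yoon connection-weight global sensitivity
#'
#' Computes the signed relative influence (RI) of every encoded input on
#' every output from a single-hidden-layer network's connection weights:
#' \deqn{RI_{ij} = 100 \cdot \frac{\sum_k W_{ik} V_{kj}}
#'                              {\sum_{i'} |\sum_k W_{i'k} V_{kj}|}}
#' Biases are excluded. By construction the absolute influences of each
#' output sum to 100%. Because the surrogate is trained on the normalized
#' scale, influences are comparable across factors with different units.
#'
#' For identity activations \eqn{\sum_k W_{ik} V_{kj}} is exactly the
#' network's equivalent affine coefficient, so signed RI then equals the
#' normalized coefficients of the corresponding linear model.
#'
#' Because a one-hot block's slots sum to 1, adding a constant to every slot
#' of a block is absorbed by the bias: slot products are identified only up
#' to a per-block additive constant, and the constant a gradient-trained net
#' leaves behind is initialization noise. The implementation therefore
#' centers each block's products (the canonical estimable contrast) before
#' normalizing. Factor-level aggregation reports the signed RI for
#' continuous factors and the magnitude of the level contrast (sum of
#' absolute centered slot RIs) for categorical factors, whose centered
#' signed sum is structurally zero.
#'
#' @param model A `cpe_mlp` (one hidden layer).
#' @return An object of class `cpe_sensitivity`: list with `ri` (encoded
#'   input x output, signed percentages, one-hot blocks centered),
#'   `factor_ri` (factor x output aggregation as described above), and
#'   `undefined` (outputs whose connection-weight products all vanish,
#'   reported as `NA`).
#' @export
#' @examples
#' pb <- cpe_fixture("pb_design_responses")
#' sens <- yoon_sensitivity(cpe_mlp(pb, hidden = 7, seed = 1))
#' colSums(abs(sens$ri))  # 100 100 100
yoon_sensitivity <- function(model) {
  stopifnot(inherits(model, "cpe_mlp"))
  P <- model$W %*% model$V                 # n_in x n_out products
  # canonicalize one-hot blocks: a constant added to all slots of a block is
  # absorbed by the bias (slots sum to 1), so slot products are identified
  # only up to a per-block additive constant; centering picks the estimable
  # contrast representative
  row <- 1L
  for (f in model$space$factors) {
    k <- if (f$kind == "continuous") 1L else length(f$levels)
    if (k > 1L) {
      blk <- row:(row + k - 1L)
      P[blk, ] <- sweep(P[blk, , drop = FALSE], 2L,
                        colMeans(P[blk, , drop = FALSE]), "-")
    }
    row <- row + k
  }
  denom <- colSums(abs(P))
  undefined <- denom == 0
  if (any(undefined)) {
    warning("relative influence undefined for output(s): ",
            paste(colnames(P)[undefined], collapse = ", "), call. = FALSE)
  }
  ri <- sweep(P, 2L, ifelse(undefined, NA_real_, denom), "/") * 100
  dimnames(ri) <- list(input_names(model$space), model$space$response_names)

  fnames <- names(model$space$factors)
  agg <- matrix(0, length(fnames), ncol(ri),
                dimnames = list(fnames, colnames(ri)))
  row <- 1L
  for (f in model$space$factors) {
    k <- if (f$kind == "continuous") 1L else length(f$levels)
    blk <- ri[row:(row + k - 1L), , drop = FALSE]
    # continuous: the signed RI itself; categorical: the magnitude of the
    # level contrast (centered slots sum to zero, so their signed sum is
    # structurally 0 and carries no information)
    agg[f$name, ] <- if (k == 1L) blk else colSums(abs(blk))
    row <- row + k
  }
  structure(list(ri = ri, factor_ri = agg, undefined = undefined,
                 topology = c(model$n_in, model$n_hidden, model$n_out)),
            class = "cpe_sensitivity")
}

#' @export
print.cpe_sensitivity <- function(x, digits = 2, ...) {
  cat("Yoon relative influence (%), factor level:\n")
  print(round(x$factor_ri, digits))
  invisible(x)
}

#' Rank factors by absolute relative influence
#'
#' @param report A `cpe_sensitivity`.
#' @param output Response name (or index) to rank for.
#' @return Character vector of factor names, descending by `|factor RI|`,
#'   ties kept in factor order.
#' @export
#' @examples
#' pb <- cpe_fixture("pb_design_responses")
#' sens <- yoon_sensitivity(cpe_mlp(pb, hidden = 7, seed = 1))
#' rank_factors(sens, "TPC")
rank_factors <- function(report, output) {
  stopifnot(inherits(report, "cpe_sensitivity"))
  if (is.character(output) && !output %in% colnames(report$factor_ri)) {
    stop("unknown output '", output, "'", call. = FALSE)
  }
  v <- report$factor_ri[, output]
  names(v)[order(-abs(v), seq_along(v))]
}

#' Bar chart of factor-level relative influence
#'
#' @param x A `cpe_sensitivity`.
#' @param output Response to plot (default: first).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.cpe_sensitivity <- function(x, output = 1L, ...) {
  v <- x$factor_ri[, output]
  graphics::barplot(v, las = 2, ylab = "relative influence (%)",
                    main = colnames(x$factor_ri)[output], ...)
  invisible(x)
}

#' Write a sensitivity report as delimited text
#'
#' @param report A `cpe_sensitivity`.
#' @param path File path.
#' @export
write_sensitivity <- function(report, path) {
  df <- data.frame(factor = rownames(report$factor_ri),
                   report$factor_ri, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
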