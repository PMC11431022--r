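#' Define a continuous process factor
#'
#' A continuous factor has numeric bounds `low < high` and, optionally, an
#' OVAT grid: the ordered set of values at which the factor was (or is to be)
#' varied one-at-a-time while all other factors are held fixed.
#'
#' @param name Factor name, e.g. `"X5"` or `"temperature"`.
#' @param low,high Numeric bounds of the admissible range.
#' @param grid Optional numeric vector of OVAT grid values (must lie within
#'   `[low, high]`).
#' @param units Unit string, e.g. `"degC"`, `"min"`, `"%, w/v"`.
#' @return An object of class `cpe_factor`.
#' @seealso [categorical_factor()], [factor_space()]
#' @export
#' @examples
#' continuous_factor("X5", 35, 75, grid = c(35, 45, 55, 65, 75), units = "degC")
continuous_factor <- function(name, low, high, grid = NULL, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("continuous factor '", name, "': need finite low < high", call. = FALSE)
  }
  if (!is.null(grid)) {
    grid <- as.numeric(grid)
    if (any(!is.finite(grid))) stop("non-finite OVAT grid for '", name, "'", call. = FALSE)
  }
  structure(
    list(name = name, kind = "continuous", low = low, high = high,
         grid = grid, units = units),
    class = "cpe_factor"
  )
}

#' Define a categorical process factor
#'
#' @param name Factor name, e.g. `"X1"` or `"surfactant"`.
#' @param levels Character vector of at least two distinct level labels, in
#'   declared order (the order fixes the one-hot slot layout).
#' @param units Unit string (usually `""` for categorical factors).
#' @return An object of class `cpe_factor`.
#' @seealso [continuous_factor()], [factor_space()]
#' @export
#' @examples
#' categorical_factor("X1", c("Tween 80", "Triton X-100"))
categorical_factor <- function(name, levels, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L || anyDuplicated(levels)) {
    stop("categorical factor '", name, "' needs >= 2 distinct levels", call. = FALSE)
  }
  structure(
    list(name = name, kind = "categorical", levels = levels, units = units),
    class = "cpe_factor"
  )
}

#' Assemble a factor space
#'
#' A factor space is the ordered collection of process factors together with
#' the names (and units) of the responses measured on each run. Its encoded
#' input width is \eqn{\sum_f (1)} for continuous factors plus
#' \eqn{\sum_f n_{levels}(f)} for categorical factors (full one-hot coding).
#'
#' @param ... `cpe_factor` objects (or a single list of them).
#' @param response_names Character vector of response names.
#' @param response_units Character vector of response units, recycled to
#'   `length(response_names)`.
#' @return An object of class `cpe_factor_space`.
#' @export
#' @examples
#' sp <- factor_space(
#'   categorical_factor("surfactant", c("Tween 80", "Triton X-100")),
#'   continuous_factor("pH", 1.5, 7.5)
#' )
#' input_width(sp)
factor_space <- function(..., response_names = c("TPC", "TC", "AA"),
                         response_units = c("mg GAE/100 g dw",
                                            "mg beta-carotene/100 g dw",
                                            "umol TE/100 g dw")) {
  factors <- list(...)
  if (length(factors) == 1L && !inherits(factors[[1L]], "cpe_factor")) {
    factors <- factors[[1L]]
  }
  if (!length(factors) || !all(vapply(factors, inherits, TRUE, "cpe_factor"))) {
    stop("factor_space() takes cpe_factor objects", call. = FALSE)
  }
  nm <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("factor names must be unique", call. = FALSE)
  names(factors) <- nm
  response_names <- as.character(response_names)
  if (!length(response_names)) stop("need at least one response name", call. = FALSE)
  structure(
    list(factors = factors, response_names = response_names,
         response_units = rep_len(as.character(response_units),
                                  length(response_names))),
    class = "cpe_factor_space"
  )
}

#' @export
print.cpe_factor <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("<factor %s: continuous [%g, %g]%s%s>\n", x$name, x$low, x$high,
                if (nzchar(x$units)) paste0(" ", x$units) else "",
                if (!is.null(x$grid)) paste0(", grid {", paste(x$grid, collapse = ", "), "}") else ""))
  } else {
    cat(sprintf("<factor %s: categorical {%s}>\n", x$name,
                paste(x$levels, collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.cpe_factor_space <- function(x, ...) {
  cat(sprintf("Factor space: %d factors (%d categorical, %d continuous), encoded width %d\n",
              length(x$factors),
              sum(vapply(x$factors, function(f) f$kind == "categorical", TRUE)),
              sum(vapply(x$factors, function(f) f$kind == "continuous", TRUE)),
              input_width(x)))
  for (f in x$factors) print(f)
  cat("Responses:", paste(x$response_names, collapse = ", "), "\n")
  invisible(x)
}

#' Encoded input width of a factor space
#'
#' @param space A `cpe_factor_space`.
#' @return Integer: 1 per continuous factor plus one slot per categorical
#'   level. The 8-continuous, 3 two-level-categorical screening space encodes
#'   to width 14, matching an MLP 14-h-3 surrogate.
#' @export
input_width <- function(space) {
  stopifnot(inherits(space, "cpe_factor_space"))
  sum(vapply(space$factors, function(f) {
    if (f$kind == "continuous") 1L else length(f$levels)
  }, 0L))
}

#' Names of the encoded input columns
#'
#' @param space A `cpe_factor_space`.
#' @return Character vector of length `input_width(space)`; categorical slots
#'   are labelled `"factor=level"`.
#' @export
input_names <- function(space) {
  stopifnot(inherits(space, "cpe_factor_space"))
  unlist(lapply(space$factors, function(f) {
    if (f$kind == "continuous") f$name else paste0(f$name, "=", f$levels)
  }), use.names = FALSE)
}

#' One-hot / numeric encoding of factor settings
#'
#' Maps one or more runs' factor settings to the numeric model-input matrix:
#' each continuous factor contributes its raw value (normalization is a
#' separate, later step), each categorical factor contributes a full one-hot
#' block with exactly one 1 in the slot of its level. For the screening space
#' of [cpe_screening_space()] the encoded width is 14.
#'
#' Continuous values outside the declared bounds raise a warning but are
#' encoded as given (optimizers may probe the bounds); unknown categorical
#' levels and missing factors are errors.
#'
#' @param space A `cpe_factor_space`.
#' @param settings A data frame (or coercible list) with one column per factor
#'   and one row per run.
#' @return Numeric matrix, `nrow(settings)` x `input_width(space)`, with
#'   column names from [input_names()].
#' @export
#' @examples
#' sp <- cpe_screening_space()
#' run4 <- data.frame(X1 = "Tween 80", X2 = 2, X3 = 0.01, X4 = 7.5, X5 = 35,
#'                    X6 = 60, X7 = "NaCl", X8 = 18, X9 = 2473, X10 = 10,
#'                    X11 = "Step 1")
#' encode_settings(sp, run4)
encode_settings <- function(space, settings) {
  stopifnot(inherits(space, "cpe_factor_space"))
  settings <- as.data.frame(settings, stringsAsFactors = FALSE)
  missing <- setdiff(names(space$factors), names(settings))
  if (length(missing)) {
    stop("missing factor(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(settings)
  out <- matrix(0, n, input_width(space),
                dimnames = list(NULL, input_names(space)))
  col <- 1L
  for (f in space$factors) {
    v <- settings[[f$name]]
    if (f$kind == "continuous") {
      v <- as.numeric(v)
      if (anyNA(v)) stop("missing value for factor '", f$name, "'", call. = FALSE)
      oob <- v < f$low | v > f$high
      if (any(oob)) {
        warning("factor '", f$name, "': ", sum(oob),
                " value(s) outside [", f$low, ", ", f$high, "]", call. = FALSE)
      }
      out[, col] <- v
      col <- col + 1L
    } else {
      v <- as.character(v)
      idx <- match(v, f$levels)
      if (anyNA(idx)) {
        bad <- unique(v[is.na(idx)])
        stop("factor '", f$name, "': unknown level(s) ",
             paste(sQuote(bad), collapse = ", "), call. = FALSE)
      }
      out[cbind(seq_len(n), col - 1L + idx)] <- 1
      col <- col + length(f$levels)
    }
  }
  out
}

#' Parse a solid:liquid ratio label
#'
#' Converts a label such as `"1:50"` into the solids mass fraction `a/b`
#' (here 0.02), the numeric form on which the ratio enters the model.
#'
#' @param label Character vector of `"a:b"` labels (numeric input is returned
#'   unchanged, so already-converted columns pass through).
#' @return Numeric vector of fractions.
#' @export
#' @examples
#' parse_ratio(c("1:50", "1:100", "1:1"))  # 0.02 0.01 1
parse_ratio <- function(label) {
  if (is.numeric(label)) return(as.numeric(label))
  label <- as.character(label)
  m <- regmatches(label, regexec("^\\s*([0-9.]+)\\s*:\\s*([0-9.]+)\\s*$", label))
  vapply(seq_along(label), function(i) {
    p <- m[[i]]
    if (length(p) != 3L) {
      stop("cannot parse solid:liquid ratio ", sQuote(label[i]), call. = FALSE)
    }
    a <- as.numeric(p[2L]); b <- as.numeric(p[3L])
    if (!is.finite(a) || !is.finite(b) || b <= 0) {
      stop("cannot parse solid:liquid ratio ", sQuote(label[i]), call. = FALSE)
    }
    a / b
  }, 0)
}

#' Fit per-column min-max scaling
#'
#' Records each column's minimum and maximum on a training matrix so that
#' [apply_scaling()] maps the fitted columns into \[0, 1\] and
#' [invert_scaling()] restores original units. A constant column (max = min)
#' scales to the constant 0 and inverts back to its original value.
#'
#' @param x Numeric matrix (runs x columns).
#' @return An object of class `cpe_scaling` with fields `min` and `max`.
#' @export
#' @examples
#' sc <- fit_scaling(cbind(a = c(0, 5, 10)))
#' apply_scaling(sc, cbind(a = c(0, 5, 10)))  # 0 0.5 1
fit_scaling <- function(x) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("cannot fit scaling on an empty table", call. = FALSE)
  structure(
    list(min = apply(x, 2L, min), max = apply(x, 2L, max)),
    class = "cpe_scaling"
  )
}

#' @rdname fit_scaling
#' @param scaling A `cpe_scaling` object.
#' @export
apply_scaling <- function(scaling, x) {
  stopifnot(inherits(scaling, "cpe_scaling"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaling$min)) stop("scaling width mismatch", call. = FALSE)
  rng <- scaling$max - scaling$min
  rng[rng == 0] <- 1  # constant columns map to 0
  sweep(sweep(x, 2L, scaling$min, "-"), 2L, rng, "/")
}

#' @rdname fit_scaling
#' @export
invert_scaling <- function(scaling, x) {
  stopifnot(inherits(scaling, "cpe_scaling"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaling$min)) stop("scaling width mismatch", call. = FALSE)
  rng <- scaling$max - scaling$min
  sweep(sweep(x, 2L, rng, "*"), 2L, scaling$min, "+")
}

#' The 11-factor CPE screening space
#'
#' The two-level factor space of the 12-run Plackett-Burman screening
#' experiment: surfactant type, salt type and number of CPE steps as two-level
#' categorical factors, and eight continuous processing factors at the bounds
#' explored in the screening runs. One-hot encoding of the three two-level
#' categorical factors plus the eight continuous factors gives the 14 model
#' inputs of the MLP 14-h-3 surrogate family.
#'
#' The solid:liquid ratio (X3) enters as the solids mass fraction (1:100 =
#' 0.01, 1:10 = 0.1); use [parse_ratio()] to convert printed labels.
#'
#' @return A `cpe_factor_space` of encoded width 14.
#' @seealso [cpe_ovat_space()] for the wider OVAT space.
#' @export
cpe_screening_space <- function() {
  factor_space(
    categorical_factor("X1", c("Tween 80", "Triton X-100")),
    continuous_factor("X2", 2, 10, grid = c(2, 4, 6, 8, 10), units = "%, w/v"),
    continuous_factor("X3", 0.01, 0.1,
                      grid = parse_ratio(c("1:100", "1:70", "1:50", "1:30", "1:10")),
                      units = "w/v fraction"),
    continuous_factor("X4", 1.5, 7.5, grid = c(1.5, 3, 4.5, 6, 7.5)),
    continuous_factor("X5", 35, 75, grid = c(35, 45, 55, 65, 75), units = "degC"),
    continuous_factor("X6", 20, 60, grid = c(20, 30, 40, 50, 60), units = "min"),
    categorical_factor("X7", c("NaCl", "KCl")),
    continuous_factor("X8", 6, 18, grid = c(6, 10, 14, 16, 18), units = "%, w/v"),
    continuous_factor("X9", 2473, 9892, grid = c(2473, 5564, 9892), units = "g"),
    continuous_factor("X10", 10, 20, grid = c(10, 15, 20), units = "min"),
    categorical_factor("X11", c("Step 1", "Step 2"))
  )
}

#' The full OVAT factor space
#'
#' Like [cpe_screening_space()] but with the complete level sets screened in
#' the one-factor-at-a-time stage: four candidate surfactants (two of which
#' never produce phase separation) and three candidate salts. Used by the
#' response-surface simulator, whose gating rules act on the extra levels.
#'
#' @return A `cpe_factor_space` of encoded width 17.
#' @export
cpe_ovat_space <- function() {
  sp <- cpe_screening_space()
  sp$factors$X1 <- categorical_factor(
    "X1", c("Tween 80", "Triton X-100", "Ceteareth-12", "Span 85"))
  sp$factors$X7 <- categorical_factor("X7", c("NaCl", "KCl", "CaCl2"))
  sp
}
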