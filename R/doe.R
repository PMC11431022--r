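#' Construct a design/response table
#'
#' The central exchange object between all pipeline stages: a factor space,
#' an ordered table of run settings, and (optionally) the measured responses.
#' All-zero response rows are legal and encode phase-separation failures
#' (no surfactant-rich phase formed, nothing recovered).
#'
#' @param space A `cpe_factor_space`.
#' @param settings Data frame of factor settings, one column per factor.
#' @param responses Optional data frame / matrix of responses with one column
#'   per `space$response_names` entry; `NULL` before measurement.
#' @return An object of class `cpe_design`.
#' @export
cpe_design <- function(space, settings, responses = NULL) {
  stopifnot(inherits(space, "cpe_factor_space"))
  settings <- as.data.frame(settings, stringsAsFactors = FALSE)
  if (!nrow(settings)) stop("design has no runs", call. = FALSE)
  # validates levels / bounds as a side effect
  invisible(encode_settings(space, settings))
  settings <- settings[, names(space$factors), drop = FALSE]
  if (!is.null(responses)) {
    responses <- as.data.frame(responses)
    if (nrow(responses) != nrow(settings)) {
      stop("responses and settings disagree on run count", call. = FALSE)
    }
    if (!all(space$response_names %in% names(responses))) {
      stop("responses must have columns ",
           paste(space$response_names, collapse = ", "), call. = FALSE)
    }
    responses <- responses[, space$response_names, drop = FALSE]
    if (any(responses < 0, na.rm = TRUE)) {
      stop("responses must be non-negative", call. = FALSE)
    }
  }
  structure(list(space = space, settings = settings, responses = responses),
            class = "cpe_design")
}

#' @export
print.cpe_design <- function(x, ...) {
  cat(sprintf("CPE design: %d runs x %d factors%s\n", nrow(x$settings),
              length(x$space$factors),
              if (is.null(x$responses)) " (no responses)" else
                sprintf(", responses %s", paste(x$space$response_names, collapse = "/"))))
  print(utils::head(as.data.frame(x), 12L))
  if (nrow(x$settings) > 12L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.cpe_design <- function(x, ...) {
  if (is.null(x$responses)) x$settings else cbind(x$settings, x$responses)
}

#' Runs flagged as failed phase separations
#'
#' @param design A `cpe_design` with responses.
#' @return Logical vector: `TRUE` where every response is exactly zero.
#' @export
failed_separation <- function(design) {
  stopifnot(inherits(design, "cpe_design"), !is.null(design$responses))
  apply(as.matrix(design$responses) == 0, 1L, all)
}

# 12-run Plackett-Burman generator row (k = 11 two-level factors)
pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

#' Generate a 12-run Plackett-Burman screening design
#'
#' Builds the standard cyclic 12-run Plackett-Burman design for exactly 11
#' two-level factors: the generator row is cycled through 11 rows and a final
#' all-minus row is appended. Every factor column carries each of its two
#' levels exactly 6 times and any two distinct columns are orthogonal under
#' +/-1 coding.
#'
#' Level assignment to the +/- codes is configurable through `pairing`; the
#' default maps `-` to the first and `+` to the second element of each
#' factor's pairing. Continuous factors default to (low, high); categorical
#' factors must have exactly two levels (taken in declared order) unless a
#' two-level pairing is supplied.
#'
#' @param space A `cpe_factor_space` with 11 factors.
#' @param pairing Optional named list giving, per factor, the length-2 vector
#'   of settings assigned to (-, +).
#' @return A `cpe_design` with 12 runs and no responses.
#' @export
#' @examples
#' d <- pb_design(cpe_screening_space())
#' nrow(d$settings)  # 12
pb_design <- function(space, pairing = NULL) {
  stopifnot(inherits(space, "cpe_factor_space"))
  k <- length(space$factors)
  if (k != 11L) {
    stop("pb_design supports the 12-run construction for exactly 11 factors ",
         "(got ", k, ")", call. = FALSE)
  }
  code <- rbind(
    t(vapply(0:10, function(s) pb12_generator[(seq_len(11L) - 1L + s) %% 11L + 1L],
             numeric(11L))),
    rep(-1, 11L)
  )
  cols <- lapply(seq_along(space$factors), function(j) {
    f <- space$factors[[j]]
    lv <- if (!is.null(pairing) && !is.null(pairing[[f$name]])) {
      pairing[[f$name]]
    } else if (f$kind == "continuous") {
      c(f$low, f$high)
    } else {
      if (length(f$levels) != 2L) {
        stop("categorical factor '", f$name,
             "' has >2 levels; supply a two-level pairing", call. = FALSE)
      }
      f$levels
    }
    if (length(lv) != 2L) stop("pairing for '", f$name, "' must have 2 values",
                               call. = FALSE)
    if (f$kind == "continuous") {
      as.numeric(lv)[(code[, j] + 3) / 2]  # -1 -> 1, +1 -> 2
    } else {
      as.character(lv)[(code[, j] + 3) / 2]
    }
  })
  names(cols) <- names(space$factors)
  cpe_design(space, as.data.frame(cols, check.names = FALSE))
}

#' Level pairing used by the printed screening runs
#'
#' The (-, +) assignment observed in the bundled Plackett-Burman table:
#' `+` corresponds to Tween 80, 10%, 1:100, pH 7.5, 75 degC, 60 min, NaCl,
#' 18%, 9892 g, 20 min, Step 2. Note that the salt-concentration screening
#' levels (16, 18) sit inside the wider OVAT range.
#'
#' @return Named list suitable for the `pairing` argument of [pb_design()].
#' @export
table2_pairing <- function() {
  list(X1 = c("Triton X-100", "Tween 80"),
       X2 = c(2, 10),
       X3 = c(0.1, 0.01),   # + is 1:100
       X4 = c(1.5, 7.5),
       X5 = c(35, 75),
       X6 = c(20, 60),
       X7 = c("KCl", "NaCl"),
       X8 = c(16, 18),
       X9 = c(2473, 9892),
       X10 = c(10, 20),
       X11 = c("Step 1", "Step 2"))
}

#' One-factor-at-a-time (OVAT) grid design
#'
#' Varies a single factor over its declared OVAT grid (continuous) or level
#' set (categorical) while holding every other factor at the supplied fixed
#' settings.
#'
#' @param space A `cpe_factor_space`.
#' @param vary Name of the factor to vary.
#' @param fixed One-row data frame (or named list) of settings for all
#'   factors; the varied factor's entry is overwritten.
#' @param grid Optional explicit grid overriding the factor's declared one.
#' @return A `cpe_design` with one run per grid value and no responses.
#' @export
#' @examples
#' sp <- cpe_screening_space()
#' ctr <- ovat_center()
#' ovat_grid(sp, "X2", ctr)  # 5 runs at 2, 4, 6, 8, 10 %
ovat_grid <- function(space, vary, fixed, grid = NULL) {
  stopifnot(inherits(space, "cpe_factor_space"))
  f <- space$factors[[vary]]
  if (is.null(f)) stop("unknown factor '", vary, "'", call. = FALSE)
  if (is.null(grid)) {
    grid <- if (f$kind == "continuous") f$grid else f$levels
  }
  if (is.null(grid) || !length(grid)) {
    stop("factor '", vary, "' has no OVAT grid", call. = FALSE)
  }
  fixed <- as.data.frame(as.list(fixed), stringsAsFactors = FALSE,
                         check.names = FALSE)
  settings <- fixed[rep(1L, length(grid)), , drop = FALSE]
  settings[[vary]] <- grid
  rownames(settings) <- NULL
  cpe_design(space, settings)
}

#' Default OVAT center point
#'
#' The fixed context used for one-at-a-time sweeps: each factor at the level
#' the OVAT stage identified as best (Tween 80, 10% surfactant, ratio 1:50,
#' pH 3, 45 degC, 20 min equilibration, NaCl, 16% salt, 2473 g, 10 min
#' centrifugation, one CPE step).
#'
#' @return One-row data frame of settings valid in [cpe_screening_space()]
#'   and [cpe_ovat_space()].
#' @export
ovat_center <- function() {
  data.frame(X1 = "Tween 80", X2 = 10, X3 = 0.02, X4 = 3, X5 = 45, X6 = 20,
             X7 = "NaCl", X8 = 16, X9 = 2473, X10 = 10, X11 = "Step 1",
             stringsAsFactors = FALSE)
}

# md5 checksums of the bundled fixture files
fixture_md5 <- c(
  pb_design_responses = "6675ff0b4912fbb2dec1de14b62b78f0",
  cpe_steps           = "815059b4808aeff01a930fc9387530ed",
  hplc_profile        = "2149f99a04c086d801de4919b9cdb771",
  verification        = "eb46110685e67c634e72c148c82eb9bf"
)

#' Load a bundled fixture table
#'
#' Ships the printed tables of the source screening study as plain-text
#' fixtures: `"pb_design_responses"` (the 12-run Plackett-Burman design with
#' measured TPC/TC/AA, returned as a `cpe_design` in the screening space),
#' `"cpe_steps"` (two-step CPE yields with their sum row), `"hplc_profile"`
#' (HPLC phenol and carotenoid profiles per extraction method), and
#' `"verification"` (model vs experimental values for the verification
#' samples). Files are checksummed on load.
#'
#' @param name Fixture name (see above).
#' @return A `cpe_design` for `"pb_design_responses"`, otherwise a data frame.
#' @export
#' @examples
#' pb <- cpe_fixture("pb_design_responses")
#' max(pb$responses$TPC)  # 348.56
cpe_fixture <- function(name = c("pb_design_responses", "cpe_steps",
                                 "hplc_profile", "verification")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "cpeopt",
                      mustWork = TRUE)
  if (unname(tools::md5sum(path)) != fixture_md5[[name]]) {
    stop("fixture '", name, "' is corrupted (checksum mismatch)", call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (name != "pb_design_responses") return(tab)
  tab$X3 <- parse_ratio(tab$X3)
  cpe_design(cpe_screening_space(),
             settings = tab[paste0("X", 1:11)],
             responses = tab[c("TPC", "TC", "AA")])
}

#' Write / read a design table as delimited text
#'
#' Plain tab-separated serialization of a design's settings and responses.
#' Numeric cells are written with full precision so a write/read round trip
#' reproduces every cell exactly.
#'
#' @param design A `cpe_design`.
#' @param path File path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "cpe_design"))
  df <- as.data.frame(design)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param space Factor space the stored settings belong to.
#' @param has_responses Does the file carry response columns?
#' @export
read_design <- function(path, space, has_responses = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  resp <- if (has_responses) tab[space$response_names] else NULL
  cpe_design(space, tab[names(space$factors)], resp)
}
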