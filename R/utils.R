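# Internal helpers shared across modules.

#' Round to two decimals, halves away from zero
#'
#' Heatmap activities are quantized to two decimals before thresholding, and
#' a value of exactly 0.195 must round up to 0.20 (and hence call as cleaved).
#' Base `round()` rounds half to even, so we use explicit half-up rounding
#' with a small guard against binary representation error.
#'
#' @param x numeric vector.
#' @return `x` rounded to two decimals.
#' @keywords internal
round2 <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

# Deterministic per-cell substream: mixes a global seed with up to three
# indices into a 31-bit state so that subsetting targets/variants/replicates
# never perturbs the draws of other cells. All arithmetic stays below 2^53,
# hence exact in doubles.
cell_seed <- function(seed, i = 0L, j = 0L, k = 0L) {
  m <- 2147483647
  x <- (seed %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + i * 2654435) %% m
  x <- (x * 69621) %% m
  x <- (x + j * 40503) %% m
  x <- (x * 16807) %% m
  x <- (x + k * 9176) %% m
  as.integer(x)
}

# Run `expr` under a temporary RNG state seeded from a cell substream,
# restoring the caller's RNG afterwards.
with_cell_rng <- function(seed, i, j, k, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(cell_seed(seed, i, j, k))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}
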