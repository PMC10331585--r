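#' Raw median absolute deviation
#'
#' Median of absolute deviations from the median, without the 1.4826
#' normal-consistency constant. This is the spread estimate used throughout
#' the screen statistics (Z'-factor denominators and robust z-scores);
#' the constant can be reinstated via `constant`.
#'
#' @param x numeric vector.
#' @param constant multiplier applied to the raw MAD (default 1; use 1.4826
#'   for normal consistency).
#' @param na.rm drop `NA`s before computing.
#' @return a single non-negative number.
#' @export
#' @examples
#' raw_mad(c(0.8, 1.0, 1.2, 1.0))  # 0.1
raw_mad <- function(x, constant = 1, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  constant * median(abs(x - median(x)))
}

#' Derive a reproducible sub-seed for a named generator stage
#'
#' All generators in the package draw from independent RNG streams keyed off
#' `(seed, stage)`, so that e.g. adding drugs to a simulated screen does not
#' perturb the control draws. The stage name is hashed with a small
#' polynomial byte hash and mixed with the master seed; the result is always
#' a valid 32-bit seed.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, length(seed) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  s <- (h + (as.numeric(seed) %% m) * 48271) %% (m - 1)
  as.integer(s + 1)
}

# Evaluate `expr` under the RNG stream (seed, stage), restoring the caller's
# RNG state afterwards. Generators stay pure functions of their seed.
with_stream <- function(seed, stage, expr) {
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
  set.seed(derive_seed(seed, stage))
  expr
}

#' Hit percentage of a screened library
#'
#' The percentage is truncated (not rounded) at `digits` decimals, the
#' conservative convention for reporting screen hit rates: 103 hits out of
#' 1,280 compounds (8.0469%) prints as 8.04%, never 8.05%.
#'
#' @param n_hits number of hit compounds.
#' @param library_size number of compounds screened.
#' @param digits decimals kept in the printed percentage (default 2).
#' @return percentage of the library called as hits.
#' @export
#' @examples
#' hit_percentage(103, 1280)  # 8.04
hit_percentage <- function(n_hits, library_size, digits = 2) {
  stopifnot(library_size > 0, n_hits >= 0, n_hits <= library_size)
  trunc(100 * n_hits / library_size * 10^digits) / 10^digits
}

#' Concentration after diluting a stock into a well
#'
#' Final concentration when `stock_ul` of a `stock_um` solution is brought to
#' `final_ul` total volume, e.g. dosing a compound plate into assay wells.
#'
#' @param stock_um stock concentration (micromolar).
#' @param stock_ul volume of stock dispensed (microliters).
#' @param final_ul final well volume (microliters).
#' @return final concentration in micromolar.
#' @export
#' @examples
#' dilution_um(20, 100, 200)  # 10
dilution_um <- function(stock_um, stock_ul, final_ul) {
  stopifnot(stock_um >= 0, stock_ul >= 0, final_ul > 0, stock_ul <= final_ul)
  stock_um * stock_ul / final_ul
}

# internal: stop() with a consistent prefix naming the pipeline stage
stage_error <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
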