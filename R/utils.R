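#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish schema problems from bad values.
lp_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "lignoprep_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

lp_validation_error <- function(msg) lp_stop(msg, "lignoprep_validation_error")
lp_schema_error     <- function(msg) lp_stop(msg, "lignoprep_schema_error")
lp_lookup_error     <- function(msg) lp_stop(msg, "lignoprep_lookup_error")
lp_io_error         <- function(msg) lp_stop(msg, "lignoprep_io_error")

#' Round half away from zero
#'
#' Printed tables in this field round 0.5 upward (e.g. 42.75 prints as 42.8,
#' 86.75 as 86.8), unlike [round()] which rounds half to even. This helper
#' reproduces the printed convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return `x` rounded to `digits` decimals, ties going away from zero.
#' @examples
#' round_half_away(86.75, 1) # 86.8, where round() gives 86.8 or 86.7
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# scalar numeric check used throughout the validators
check_num <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    lp_validation_error(sprintf("'%s' must be a single non-missing number", name))
  }
  if (x < lower || x > upper) {
    lp_validation_error(sprintf(
      "'%s' = %g is outside the allowed range [%g, %g]", name, x, lower, upper
    ))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a local RNG seed, restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}
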