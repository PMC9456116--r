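#' Physical constants used throughout the package
#'
#' Fixed values: the vacuum permittivity `eps0` (F/m), the molar gas constant
#' `R` (J/(mol K)) and `log10e = log10(exp(1))`. These are not user-settable;
#' every energy conversion in the package goes through this single definition.
#'
#' @return A named list with elements `eps0`, `R` and `log10e`.
#' @export
#' @examples
#' physical_constants()$R
physical_constants <- function() {
  list(
    eps0   = 8.8541878128e-12,
    R      = 8.314,
    log10e = 0.4342944819032518
  )
}

# internal shortcuts
.EPS0 <- 8.8541878128e-12
.RGAS <- 8.314
.LOG10E <- 0.4342944819032518

# validate a scalar numeric argument; `cond` is a quoted predicate description
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g%s.",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}
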