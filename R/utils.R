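#' @useDynLib fruitdrop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm optimize coef pt sd rnorm runif
#' @importFrom utils read.csv write.csv head tail
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x)) stopf("'%s' must be a single finite number", name)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stopf("'%s' = %g outside the admissible range %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  invisible(x)
}
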