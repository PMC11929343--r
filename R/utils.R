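`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mrmediate_config_error", "error", "condition")))
}

stop_parse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mrmediate_parse_error", "error", "condition")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config("'%s' must be a single non-missing number", name)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop_config("'%s' = %g is outside its admissible range", name, x)
  invisible(x)
}

#' @noRd
fmt_num <- function(x) {
  # 15 significant digits preserves doubles through a text round trip
  # well past the 12 digits the report contract requires
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

two_sided_normal_p <- function(z) 2 * stats::pnorm(-abs(z))

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) unname(DNA_COMPLEMENT[a])

is_palindromic <- function(a1, a2) complement_allele(a1) == a2
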