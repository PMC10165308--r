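#' Value with standard uncertainty
#'
#' A `uvalue` couples a numeric value with a standard uncertainty and an
#' optional unit string. It is the currency of the filling-metrology and
#' reporting functions, and renders in the concise parenthesis notation
#' conventional in metrology: `"409(14)"` means a value of 409 with a
#' standard uncertainty of 14 in the last displayed digits.
#'
#' @param value numeric value.
#' @param u standard uncertainty, must be `>= 0`. Default 0 (exact).
#' @param unit unit string, e.g. `"MBq/mL"`. Informational only.
#' @return An object of class `uvalue`.
#' @examples
#' uvalue(2.00, 0.06, "MBq/mL")
#' format_concise(uvalue(409, 14))
#' @export
uvalue <- function(value, u = 0, unit = "") {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0)
    stop("standard uncertainty 'u' must be a single finite number >= 0")
  structure(list(value = value, u = u, unit = unit), class = "uvalue")
}

#' @export
print.uvalue <- function(x, ...) {
  cat(format_concise(x), if (nzchar(x$unit)) x$unit else NULL, "\n")
  invisible(x)
}

#' @export
format.uvalue <- function(x, ...) format_concise(x)

# scale a uvalue by an exact constant
uv_scale <- function(x, k, unit = x$unit) uvalue(k * x$value, abs(k) * x$u, unit)

# combine relative uncertainties in quadrature for a product/quotient result
uv_combine_rel <- function(value, rel_us, unit = "") {
  uvalue(value, abs(value) * sqrt(sum(rel_us^2)), unit)
}

#' Render a value/uncertainty pair in concise parenthesis notation
#'
#' The uncertainty is quoted in units of the last displayed digit of the
#' value, to one significant figure; when the uncertainty leads with 1 and
#' has a nonzero second digit, both digits are kept (so 14 renders
#' `"(14)"`, while 0.01 renders `"(1)"`). Rounding is round-half-even.
#' A zero uncertainty renders the bare value without parentheses.
#'
#' @param x a [uvalue].
#' @return A string such as `"98.25(3)"` or `"409(14)"`.
#' @seealso [parse_concise()] for the inverse.
#' @export
format_concise <- function(x) {
  stopifnot(inherits(x, "uvalue"))
  v <- x$value
  u <- x$u
  if (u == 0) {
    return(format(v, trim = TRUE, scientific = FALSE))
  }
  e1 <- floor(log10(u))
  # one significant figure, except when the uncertainty leads with 1 and a
  # nonzero second digit would be lost (so 14 renders "(14)" but 0.01 "(1)")
  mant2 <- round(u / 10^(e1 - 1))
  ndig <- if (mant2 >= 10 && mant2 <= 19 && mant2 %% 10 != 0) 2L else 1L
  p <- e1 - (ndig - 1L)                       # exponent of the last digit
  repeat {                                    # handle decade overflow (0.99 -> 1)
    u_disp <- round(u / 10^p)
    if (u_disp < 10^ndig) break
    p <- p + 1L
  }
  v_round <- round(v / 10^p) * 10^p
  if (p >= 0) {
    val_str <- format(round(v_round), trim = TRUE, scientific = FALSE)
    u_str <- format(u_disp * 10^p, trim = TRUE, scientific = FALSE)
  } else {
    val_str <- formatC(v_round, format = "f", digits = -p)
    u_str <- format(u_disp, trim = TRUE, scientific = FALSE)
  }
  paste0(val_str, "(", u_str, ")")
}

#' Parse concise parenthesis notation into a value/uncertainty pair
#'
#' @param s a string such as `"0.6(8)"` (or a bare number, parsed with
#'   zero uncertainty).
#' @param unit unit string attached to the result.
#' @return A [uvalue].
#' @examples
#' parse_concise("0.6(8)")   # value 0.6, u 0.8
#' @export
parse_concise <- function(s, unit = "") {
  stopifnot(is.character(s), length(s) == 1L)
  s <- trimws(s)
  m <- regmatches(s, regexec("^([+-]?[0-9]+)(?:\\.([0-9]+))?\\(([0-9]+)\\)$", s))[[1]]
  if (length(m) == 0L) {
    if (grepl("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", s))
      return(uvalue(as.numeric(s), 0, unit))
    stop("malformed concise-notation string: '", s, "'")
  }
  ndec <- nchar(m[3])
  value <- as.numeric(paste0(m[2], if (ndec > 0) paste0(".", m[3])))
  u <- as.numeric(m[4]) * 10^(-ndec)
  uvalue(value, u, unit)
}
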