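#' Radioactive decay factors and corrections
#'
#' `decay_factor()` returns the dimensionless survival factor
#' `2^(-dt/half_life)`. `decay_apply()` moves a measured activity forward in
#' time (later reference, smaller activity); `decay_correct()` moves it
#' backward (earlier reference, larger activity). The two are exact inverses.
#'
#' @param dt elapsed time, in the same unit as `half_life` (hours throughout
#'   this package). May be negative, which swaps the roles of the two
#'   functions.
#' @param half_life radionuclide half-life, `> 0`.
#' @param x activity (or concentration) to rescale.
#' @return `decay_factor()`: a factor in (0, Inf); the others: `x` rescaled.
#' @examples
#' decay_factor(0, 159.46)            # 1
#' decay_apply(100, 159.46, 159.46)   # 50
#' @export
decay_factor <- function(dt, half_life) {
  if (!is.numeric(half_life) || any(half_life <= 0))
    stop("half_life must be positive")
  2^(-dt / half_life)
}

#' @rdname decay_factor
#' @export
decay_apply <- function(x, dt, half_life) x * decay_factor(dt, half_life)

#' @rdname decay_factor
#' @export
decay_correct <- function(x, dt, half_life) x * decay_factor(-dt, half_life)

#' Default Lu-177 half-life in hours
#'
#' Lu-177 physical half-life of 6.6443 days expressed in hours. Shipped as a
#' configurable default; this is external nuclear data, not a quantity this
#' package determines.
#' @return Half-life in hours (159.4632).
#' @export
lu177_half_life_h <- function() 6.6443 * 24
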