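#' Coerce numbers to canonical exact rationals
#'
#' Exact scalars are represented as character strings `"p/q"` (or `"p"` for
#' integers).  Character input may mix integers, `p/q` fractions and decimal
#' literals (`"0.5"` parses exactly to `1/2`, exponents allowed); numeric
#' input is converted through its exact binary value, which is exact for
#' integers and binary fractions such as `0.25` -- a decimal like `0.1` should
#' be given as the string `"1/10"`.
#'
#' @param x numeric or character vector/matrix.
#' @return character vector/matrix of canonical rationals, same shape as `x`.
#' @examples
#' as_rational(c("1/3", "0.5", "-2"))
#' as_rational(0.25)
#' @export
as_rational <- function(x) {
  if (is.character(x)) return(cpp_canon(x))
  if (is.numeric(x)) return(cpp_dbl2q(x))
  stop("cannot coerce an object of class '", class(x)[1L],
       "' to exact rationals")
}

#' Convert exact rationals to doubles
#'
#' Lossy companion of [as_rational()], for plotting and reporting.
#'
#' @param x character vector/matrix of rationals.
#' @return numeric vector/matrix.
#' @export
rational_to_double <- function(x) {
  stopifnot(is.character(x))
  cpp_q2dbl(x)
}

# internal: canonical key of an exact point (used for deduplication)
point_key <- function(p) paste(p, collapse = ",")
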