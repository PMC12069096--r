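#' Box-Cox transformation and its inverse
#'
#' `boxcox()` maps positive amounts to an approximately normal scale,
#' `g(x; lambda) = (x^lambda - 1)/lambda` for `lambda != 0` and `log(x)` at
#' `lambda = 0`. `inv_boxcox()` is the exact functional inverse; it errors
#' outside the support of the inverse (`lambda * y + 1 <= 0` for
#' `lambda > 0`) unless `truncate = TRUE`, in which case inadmissible values
#' are mapped to 0 (the transform's support boundary) and the truncation count
#' is attached as attribute `"n_truncated"`.
#'
#' @param x Positive amounts.
#' @param lambda Box-Cox power parameter.
#' @param y Transformed-scale values.
#' @param truncate Truncate inadmissible inverse values at the support
#'   boundary instead of erroring.
#' @return Transformed (or back-transformed) numeric vector.
#' @examples
#' boxcox(2, 1) # 1
#' inv_boxcox(boxcox(3.7, 0.4), 0.4) # 3.7
#' @export
boxcox <- function(x, lambda) {
  if (any(x <= 0)) stop("boxcox() requires strictly positive x")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' @rdname boxcox
#' @export
inv_boxcox <- function(y, lambda, truncate = FALSE) {
  if (abs(lambda) < 1e-12) return(exp(y))
  z <- lambda * y + 1
  bad <- z <= 0
  if (any(bad)) {
    if (!truncate) {
      stop("inv_boxcox(): value outside the support of the inverse transform; ",
           "callers must truncate explicitly (truncate = TRUE)")
    }
    z[bad] <- 0
  }
  out <- z^(1 / lambda)
  if (truncate) attr(out, "n_truncated") <- sum(bad)
  out
}

# d/dlambda of boxcox(x, lambda), used in the likelihood gradient
boxcox_dlambda <- function(x, lambda) {
  if (abs(lambda) < 1e-12) return(log(x)^2 / 2)
  (lambda * x^lambda * log(x) - (x^lambda - 1)) / lambda^2
}
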