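#' Weighted empirical quantiles
#'
#' The single percentile convention used throughout the package: the weighted
#' empirical quantile with linear interpolation between adjacent order
#' statistics on the (midpoint) cumulative-weight scale. With equal weights on
#' `n` points this reduces to interpolation at plotting positions
#' `(k - 0.5)/n`, so the median of `1:100` is 50.5.
#'
#' @param x Numeric vector of values.
#' @param w Non-negative weights, recycled if length 1. Default: equal weights.
#' @param probs Probabilities in `[0, 1]`.
#' @param na.rm Drop missing values (and their weights) first.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @examples
#' weighted_quantile(1:100, probs = 0.5) # 50.5
#' @export
weighted_quantile <- function(x, w = NULL, probs = 0.5, na.rm = FALSE) {
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) == 1L) w <- rep(w, length(x))
  stopifnot(length(w) == length(x), all(probs >= 0 & probs <= 1))
  if (na.rm) {
    keep <- !is.na(x) & !is.na(w)
    x <- x[keep]; w <- w[keep]
  }
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  if (any(w < 0)) stop("weights must be non-negative")
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  keep <- w > 0
  if (!any(keep)) stop("all weights are zero")
  x <- x[keep]; w <- w[keep]
  if (length(x) == 1L) return(rep(x, length(probs)))
  cw <- cumsum(w)
  # midpoint plotting positions on the cumulative-weight scale
  pk <- (cw - 0.5 * w) / cw[length(cw)]
  stats::approx(pk, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Gauss-Hermite quadrature for standard-normal expectations
#'
#' Nodes and weights such that `E[f(Z)] ~ sum(w * f(z))` for `Z ~ N(0, 1)`.
#' Computed by the Golub-Welsch algorithm (eigendecomposition of the Jacobi
#' matrix of the Hermite recurrence), then rescaled from physicists' to
#' probabilists' form.
#'
#' @param n Number of nodes (>= 1).
#' @return A list with numeric vectors `nodes` and `weights` (weights sum to 1).
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1)
  # Jacobi matrix for physicists' Hermite polynomials
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2 # sum to 1 after normalization (total mass sqrt(pi)/sqrt(pi))
  ord <- order(x)
  list(nodes = sqrt(2) * x[ord], weights = w[ord])
}

#' Derive a named substream seed from a master seed
#'
#' Fans a single integer master seed out to deterministic per-stage seeds so
#' that pipeline stages can be regenerated independently.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name (e.g. `"population"`, `"assays"`).
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # cheap deterministic hash of the stream name, independent of the RNG state
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 2654435761) %% 1000003
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% .Machine$integer.max)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x < 18
  out[small] <- log1p(exp(x[small]))
  big <- x >= 18 & x < 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

# row-wise log-sum-exp of a matrix
row_logsumexp <- function(m) {
  mx <- matrixStats_rowMaxs(m)
  mx + log(rowSums(exp(m - mx)))
}

matrixStats_rowMaxs <- function(m) {
  # base-R row maxima (no matrixStats dependency)
  do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
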