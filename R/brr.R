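#' Sylvester Hadamard matrix
#'
#' Hadamard matrix of order `n` (a power of two), built by the Sylvester
#' doubling construction; used to balance BRR half-sample selections.
#'
#' @param n Order, a power of two.
#' @return An `n x n` matrix of +1/-1 with orthogonal columns.
#' @export
hadamard_matrix <- function(n) {
  if (n < 1 || bitwAnd(n, n - 1L) != 0)
    stop("Sylvester construction requires a power-of-two order")
  H <- matrix(1, 1, 1)
  while (nrow(H) < n) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

#' Build balanced-repeated-replication weights with Fay's method
#'
#' Each pseudo-stratum has exactly two half-sample units. In replicate `r`,
#' the unit selected by a Hadamard-type balanced design has its weights
#' multiplied by `2 - F` and the complement by `F` (Fay's factor, default
#' 0.3); every replicate is then rescaled so its weight total matches the
#' full-sample total. With `F = 1` every replicate reproduces the base
#' weights.
#'
#' @param persons Person tibble with columns weight, pseudo_stratum,
#'   half_sample.
#' @param n_replicates Number of replicates (default 32); must be a power of
#'   two at least the number of strata.
#' @param fay Fay factor `F` in `[0, 1]`.
#' @return Numeric matrix, persons x replicates, of replicate weights.
#' @export
build_replicate_weights <- function(persons, n_replicates = 32, fay = 0.3) {
  stopifnot(fay >= 0, fay <= 1)
  units <- dplyr::distinct(persons, .data$pseudo_stratum, .data$half_sample)
  per_stratum <- table(units$pseudo_stratum)
  if (any(per_stratum != 2))
    stop("every pseudo-stratum must have exactly two half-sample units")
  strata <- sort(unique(persons$pseudo_stratum))
  if (n_replicates < length(strata))
    stop("need at least as many replicates as pseudo-strata")
  H <- hadamard_matrix(n_replicates)
  w <- persons$weight
  h_idx <- match(persons$pseudo_stratum, strata)
  first_half <- persons$half_sample == min(persons$half_sample)
  out <- matrix(0, nrow(persons), n_replicates)
  total <- sum(w)
  for (r in seq_len(n_replicates)) {
    sel <- H[r, h_idx] == 1
    fac <- ifelse(sel == first_half, 2 - fay, fay)
    wr <- w * fac
    out[, r] <- wr * total / sum(wr)
  }
  dimnames(out) <- list(persons$person_id,
                        paste0("rep", seq_len(n_replicates)))
  out
}

#' Fay-adjusted BRR variance, confidence interval and test
#'
#' Evaluates a point estimator under the full-sample weights and under each
#' replicate weight set; the variance is
#' `sum((theta_r - theta_hat)^2) / (R * (1 - F)^2)`. For positive
#' estimators (ratios), the 95% CI and two-sided p-value are computed on the
#' log scale with the delta-method standard error and a normal reference.
#' Replicates on which the estimator fails are dropped and counted; more
#' than 25% failures aborts.
#'
#' @param estimator Function of a weight vector returning a scalar.
#' @param replicate_weights Matrix from [build_replicate_weights()].
#' @param base_weights Full-sample weights.
#' @param fay Fay factor used to build the replicates.
#' @param null_value Null hypothesis value for the two-sided test
#'   (default 1, i.e. no ratio difference).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: estimate, variance, se, conf_low, conf_high, p_value,
#'   n_replicates_used, n_failed.
#' @export
brr_ci <- function(estimator, replicate_weights, base_weights, fay = 0.3,
                   null_value = 1, conf_level = 0.95) {
  theta <- estimator(base_weights)
  reps <- apply(replicate_weights, 2, function(wr) {
    tryCatch(estimator(wr), error = function(e) NA_real_)
  })
  failed <- sum(is.na(reps))
  if (failed > 0.25 * length(reps)) {
    stop("BRR aborted: ", failed, " of ", length(reps),
         " replicates failed (more than 25%)")
  }
  if (failed > 0) {
    message(failed, " BRR replicate(s) failed and were dropped; ",
            length(reps) - failed, " used")
  }
  reps <- reps[!is.na(reps)]
  R <- length(reps)
  variance <- sum((reps - theta)^2) / (R * (1 - fay)^2)
  se <- sqrt(variance)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (theta > 0 && se > 0) {
    se_log <- se / theta # delta method on the log scale
    lo <- exp(log(theta) - z * se_log)
    hi <- exp(log(theta) + z * se_log)
    p <- 2 * stats::pnorm(-abs(log(theta) - log(null_value)) / se_log)
  } else if (se == 0) {
    lo <- hi <- theta
    p <- if (isTRUE(all.equal(theta, null_value))) 1 else 0
  } else {
    lo <- theta - z * se; hi <- theta + z * se
    p <- 2 * stats::pnorm(-abs(theta - null_value) / se)
  }
  tibble::tibble(estimate = theta, variance = variance, se = se,
                 conf_low = lo, conf_high = hi, p_value = p,
                 n_replicates_used = R, n_failed = failed)
}
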