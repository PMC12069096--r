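#' Build the fixed-effects design matrix for the two-part model
#'
#' Three layouts are supported (the intercept is carried separately by the
#' model parameters and is not a column):
#'
#' * `"children"` (ages 1-19): gender indicator, continuous age, a linear
#'   age spline with a knot at 11, age x gender and spline x gender
#'   cross-products, an end-of-week indicator (Friday/Saturday/Sunday), and a
#'   second-recall indicator.
#' * `"adults"` (ages 20+): as above with spline knots at 29, 39, 49, 59, 69.
#' * `"basic"`: gender, centred age in decades `(age - 40)/10`, end-of-week
#'   and second-recall indicators; a parsimonious cohort-agnostic layout used
#'   as generative truth by the synthetic-data module.
#'
#' @param data Tibble with columns `gender` ("female"/"male"), `age`,
#'   `end_of_week` (logical or 0/1) and `sequence` (1 = first in-person
#'   recall, 2 = second phone recall).
#' @param design One of `"children"`, `"adults"`, `"basic"`.
#' @param extra Optional character vector of extra covariate columns in
#'   `data` (factors/characters are dummy-expanded) appended to the design.
#' @return Numeric matrix, one row per row of `data`.
#' @export
build_design_matrix <- function(data, design = c("children", "adults", "basic"),
                                extra = NULL) {
  design <- match.arg(design)
  male <- as.numeric(data$gender == "male")
  age <- data$age
  eow <- as.numeric(data$end_of_week)
  seq2 <- as.numeric(data$sequence == 2)
  if (design == "children" && (any(age < 1) || any(age > 19)))
    stop("children design requires ages 1-19")
  if (design == "adults" && any(age < 20))
    stop("adults design requires ages 20+")
  X <- switch(design,
    basic = cbind(male = male, age10 = (age - 40) / 10,
                  end_of_week = eow, seq2 = seq2),
    children = {
      sp <- pmax(age - 11, 0)
      cbind(male = male, age = age, age_sp11 = sp,
            male_age = male * age, male_sp11 = male * sp,
            end_of_week = eow, seq2 = seq2)
    },
    adults = {
      knots <- c(29, 39, 49, 59, 69)
      sp <- matrix(vapply(knots, function(k) pmax(age - k, 0),
                          numeric(length(age))),
                   nrow = length(age))
      colnames(sp) <- paste0("age_sp", knots)
      msp <- male * sp
      colnames(msp) <- paste0("male_sp", knots)
      cbind(male = male, age = age, sp, male_age = male * age, msp,
            end_of_week = eow, seq2 = seq2)
    })
  if (!is.null(extra)) {
    stopifnot(all(extra %in% names(data)))
    mm <- stats::model.matrix(~., data = as.data.frame(data[extra]))
    X <- cbind(X, mm[, -1, drop = FALSE])
  }
  X
}

# negative log-likelihood + analytic gradient of the correlated two-part
# model, marginalised over (u1, u2) by Gauss-Hermite product quadrature.
# Returns closures sharing one cache so optim's fn/gr pairs cost one pass.
make_two_part_objective <- function(id, A, X1, X2, R, w_person, n_quad,
                                    lambda_fixed, lambda_range) {
  n <- length(w_person)
  N <- length(id)
  pos <- which(A == 1)
  idpos <- id[pos]
  X2pos <- X2[pos, , drop = FALSE]
  logR <- log(R)
  sum_logR <- as.vector(rowsum_vec(logR, idpos, n))
  S0 <- as.vector(rowsum_vec(rep(1, length(pos)), idpos, n))
  gq <- gauss_hermite(n_quad)
  K <- n_quad
  KK <- K * K
  z1big <- rep(gq$nodes, each = K)
  z2big <- rep(gq$nodes, times = K)
  logwbig <- log(rep(gq$weights, each = K) * rep(gq$weights, times = K))
  ind_block <- outer(rep(seq_len(K), each = K), seq_len(K), "==") * 1
  free_lambda <- is.null(lambda_fixed)
  p_beta <- ncol(X1)
  npar <- 2 * p_beta + 4 + as.integer(free_lambda)

  unpack <- function(theta) {
    b1 <- theta[seq_len(p_beta)]
    b2 <- theta[p_beta + seq_len(p_beta)]
    k <- 2 * p_beta
    su1 <- exp(theta[k + 1]); su2 <- exp(theta[k + 2])
    rho <- tanh(theta[k + 3]); sig <- exp(theta[k + 4])
    lam <- if (free_lambda) {
      lambda_range[1] +
        diff(lambda_range) * stats::plogis(theta[k + 5])
    } else lambda_fixed
    list(b1 = b1, b2 = b2, su1 = su1, su2 = su2, rho = rho, sig = sig,
         lam = lam)
  }

  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL

  compute <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return()
    p <- unpack(theta)
    E1 <- drop(X1 %*% p$b1)
    y <- boxcox(R, p$lam)
    r <- y - drop(X2pos %*% p$b2)
    S1 <- as.vector(rowsum_vec(r, idpos, n))
    S2 <- as.vector(rowsum_vec(r^2, idpos, n))
    sig2 <- p$sig^2
    base <- (p$lam - 1) * sum_logR - 0.5 * S0 * log(2 * pi * sig2) -
      S2 / (2 * sig2)

    # probability part: depends on the u1 node only
    Prows <- matrix(0, N, K)
    M1 <- matrix(0, n, K)
    D1 <- matrix(0, n, K)
    for (k in seq_len(K)) {
      eta <- E1 + p$su1 * gq$nodes[k]
      pk <- stats::plogis(eta)
      Prows[, k] <- pk
      M1[, k] <- rowsum_vec(A * eta - log1pexp(eta), id, n)
      D1[, k] <- rowsum_vec(A - pk, id, n)
    }

    cc <- sqrt(1 - p$rho^2)
    U2 <- p$su2 * (p$rho * z1big + cc * z2big)
    L2 <- outer(S1, U2) / sig2 - outer(S0, U2^2) / (2 * sig2) + base
    Amat <- L2 + M1[, rep(seq_len(K), each = K), drop = FALSE]
    Amat <- sweep(Amat, 2, logwbig, "+")
    li <- row_logsumexp(Amat)
    P <- exp(Amat - li)

    cache$theta <- theta
    cache$p <- p
    cache$li <- li
    cache$P <- P
    cache$Prows <- Prows
    cache$D1 <- D1
    cache$S1 <- S1
    cache$S2 <- S2
    cache$r <- r
    cache$U2 <- U2
    cache$cc <- cc
    invisible()
  }

  fn <- function(theta) {
    compute(theta)
    -sum(w_person * cache$li)
  }

  gr <- function(theta) {
    compute(theta)
    p <- cache$p
    sig2 <- p$sig^2
    P <- cache$P
    U2 <- cache$U2
    Mom <- P %*% cbind(U2, U2^2, z1big, z2big, U2 * z1big, U2 * z2big)
    mu2 <- Mom[, 1]; mu2q <- Mom[, 2]; mz1 <- Mom[, 3]; mz2 <- Mom[, 4]
    mu2z1 <- Mom[, 5]; mu2z2 <- Mom[, 6]
    P1 <- P %*% ind_block

    pbar <- rowSums(P1[id, , drop = FALSE] * cache$Prows)
    g_b1 <- drop(crossprod(X1, w_person[id] * (A - pbar)))

    rbar <- cache$r - mu2[idpos]
    g_b2 <- drop(crossprod(X2pos, w_person[idpos] * rbar)) / sig2

    D1z <- sweep(cache$D1, 2, gq$nodes, "*")
    g_su1 <- sum(w_person * rowSums(P1 * D1z))

    S0i <- S0; S1i <- cache$S1
    g_su2 <- sum(w_person * (S1i * mu2 - S0i * mu2q)) / (p$su2 * sig2)

    rr <- p$rho / cache$cc
    g_rho <- p$su2 / sig2 * sum(w_person *
      (S1i * (mz1 - rr * mz2) - S0i * (mu2z1 - rr * mu2z2)))

    g_sig <- sum(w_person *
      (-S0i / p$sig +
         (cache$S2 - 2 * S1i * mu2 + S0i * mu2q) / p$sig^3))

    grad <- numeric(npar)
    grad[seq_len(p_beta)] <- g_b1
    grad[p_beta + seq_len(p_beta)] <- g_b2
    k <- 2 * p_beta
    grad[k + 1] <- g_su1 * p$su1          # d su1 / d log su1
    grad[k + 2] <- g_su2 * p$su2
    grad[k + 3] <- g_rho * (1 - p$rho^2)  # d tanh
    grad[k + 4] <- g_sig * p$sig
    if (free_lambda) {
      dy <- boxcox_dlambda(R, p$lam)
      g_lam <- sum(w_person[idpos] * (-rbar * dy / sig2 + logR))
      frac <- (p$lam - lambda_range[1]) / diff(lambda_range)
      grad[k + 5] <- g_lam * diff(lambda_range) * frac * (1 - frac)
    }
    -grad
  }

  list(fn = fn, gr = gr, unpack = unpack, npar = npar, p_beta = p_beta,
       free_lambda = free_lambda)
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Fit the survey-weighted correlated two-part usual-intake model
#'
#' Maximises the survey-weighted marginal log-likelihood of the two-part
#' model: a logistic mixed model for the probability of consumption on a
#' recall day and a linear mixed model for the Box-Cox transformed positive
#' amount, with correlated person-level random intercepts `(u1, u2)`
#' integrated out by Gauss-Hermite product quadrature. The Box-Cox parameter
#' is estimated jointly with all other parameters (the likelihood includes
#' the transformation Jacobian), bounded to `lambda_range`. Survey weights
#' are normalised to mean 1 within the fit.
#'
#' @param data Person-day tibble with columns `person_id`, `gender`, `age`,
#'   `end_of_week`, `sequence`, a survey-weight column and an amount column
#'   (zero on non-consumption days).
#' @param design Design layout passed to [build_design_matrix()]; identical
#'   covariates are used in both model parts.
#' @param amount_col,weight_col Names of the amount and survey-weight
#'   columns.
#' @param extra Extra covariate columns (see [build_design_matrix()]).
#' @param n_quad Gauss-Hermite nodes per random-effect dimension
#'   (default 15, i.e. a 225-node product grid).
#' @param lambda Fix the Box-Cox parameter at this value instead of
#'   estimating it.
#' @param lambda_range Box of the Box-Cox parameter when estimated.
#' @param n_starts Number of optimizer starts (first start is
#'   GLM/LM-derived; further starts are jittered).
#' @param se Compute standard errors from the numerically differentiated
#'   analytic gradient (observed information).
#' @param min_eaters Warn when fewer persons consumed on two or more days
#'   (model-stability recommendation: 50).
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return An object of class `hgp_two_part_fit`: estimated
#'   [two_part_params()], standard errors, vcov, log-likelihood and
#'   convergence diagnostics. Supports [tidy()][generics::tidy],
#'   [glance()][generics::glance] and `print()`.
#' @export
fit_two_part <- function(data, design = c("children", "adults", "basic"),
                         amount_col = "intake", weight_col = "weight",
                         extra = NULL, n_quad = 15, lambda = NULL,
                         lambda_range = c(0.01, 1), n_starts = 1,
                         se = TRUE, min_eaters = 50, control = list()) {
  design <- match.arg(design)
  amt <- data[[amount_col]]
  stopifnot(!is.null(amt), all(amt >= 0), !anyNA(amt))
  pid <- factor(data$person_id)
  id <- as.integer(pid)
  n <- nlevels(pid)
  A <- as.numeric(amt > 0)
  if (all(A == 1)) stop("degenerate fit: every person-day has consumption")
  if (all(A == 0)) stop("degenerate fit: no person-day has consumption")
  n_eaters <- sum(tapply(A, id, sum) >= 2)
  if (n_eaters < min_eaters) {
    warning("only ", n_eaters, " persons consumed on both days; at least ",
            min_eaters, " recommended for stable estimates")
  }
  w_raw <- tapply(data[[weight_col]], id, function(x) x[1])
  w_person <- as.vector(w_raw / mean(w_raw))

  X <- build_design_matrix(data, design, extra = extra)
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  X1 <- cbind(`(Intercept)` = 1, X)
  R <- amt[A == 1]

  obj <- make_two_part_objective(id, A, X1, X1, R, w_person, n_quad,
                                 lambda, lambda_range)
  start <- two_part_start(id, A, X1, R, w_person, lambda, lambda_range,
                          obj$free_lambda)
  ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)

  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    th0 <- if (s == 1) start else jitter_start(start, s)
    opt <- stats::optim(th0, obj$fn, obj$gr, method = "BFGS", control = ctrl)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  gnorm <- max(abs(obj$gr(best$par)))
  if (gnorm > 1e-3 * n) { # restart from the optimum if not yet stationary
    opt <- stats::optim(best$par, obj$fn, obj$gr, method = "BFGS",
                        control = ctrl)
    if (opt$value <= best$value) best <- opt
    gnorm <- max(abs(obj$gr(best$par)))
  }
  converged <- best$convergence == 0 && is.finite(gnorm)

  est <- obj$unpack(best$par)
  p_beta <- obj$p_beta
  nm_x <- colnames(X1)[-1]
  params <- two_part_params(
    beta1_0 = est$b1[1], beta_x1 = stats::setNames(est$b1[-1], nm_x),
    sigma2_u1 = est$su1^2,
    beta2_0 = est$b2[1], beta_x2 = stats::setNames(est$b2[-1], nm_x),
    sigma2_u2 = est$su2^2, rho = est$rho, sigma2 = est$sig^2,
    lambda = est$lam, design = design)

  se_theta <- vcov_nat <- NULL
  if (se) {
    H <- numeric_jacobian(obj$gr, best$par)
    H <- (H + t(H)) / 2
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(vc))) {
      J <- transform_jacobian(best$par, p_beta, obj$free_lambda,
                              lambda_range)
      vcov_nat <- J %*% vc %*% t(J)
      dimnames(vcov_nat) <- list(natural_names(nm_x, obj$free_lambda),
                                 natural_names(nm_x, obj$free_lambda))
      se_theta <- sqrt(pmax(diag(vcov_nat), 0))
    }
  }

  structure(list(
    params = params, se = se_theta, vcov = vcov_nat,
    logLik = -best$value, convergence = converged,
    grad_norm = gnorm, optim = best[c("convergence", "counts")],
    n_persons = n, n_days = length(id), n_eaters_both_days = n_eaters,
    n_quad = n_quad, design = design, dropped_columns = dropped,
    lambda_fixed = !obj$free_lambda, lambda_range = lambda_range,
    extra = extra), class = "hgp_two_part_fit")
}

natural_names <- function(nm_x, free_lambda) {
  c(paste0("prob_", c("(Intercept)", nm_x)),
    paste0("amount_", c("(Intercept)", nm_x)),
    "sigma_u1", "sigma_u2", "rho", "sigma",
    if (free_lambda) "lambda")
}

# jacobian of (b1, b2, su1, su2, rho, sig, lam) wrt the unconstrained
# parameterisation, for delta-method standard errors on the natural scale
transform_jacobian <- function(theta, p_beta, free_lambda, lambda_range) {
  k <- 2 * p_beta
  d <- rep(1, length(theta))
  d[k + 1] <- exp(theta[k + 1])
  d[k + 2] <- exp(theta[k + 2])
  d[k + 3] <- 1 - tanh(theta[k + 3])^2
  d[k + 4] <- exp(theta[k + 4])
  if (free_lambda) {
    fr <- stats::plogis(theta[k + 5])
    d[k + 5] <- diff(lambda_range) * fr * (1 - fr)
  }
  diag(d)
}

numeric_jacobian <- function(g, theta, eps = 1e-5) {
  p <- length(theta)
  J <- matrix(0, p, p)
  for (i in seq_len(p)) {
    h <- eps * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    J[, i] <- (g(tp) - g(tm)) / (2 * h)
  }
  J
}

two_part_start <- function(id, A, X1, R, w_person, lambda_fixed,
                           lambda_range, free_lambda) {
  w_row <- w_person[id]
  g1 <- suppressWarnings(
    stats::glm.fit(X1, A, weights = w_row, family = stats::binomial()))
  b1 <- g1$coefficients
  b1[!is.finite(b1)] <- 0

  pos <- A == 1
  Xp <- X1[pos, , drop = FALSE]
  wp <- w_row[pos]
  logR <- log(R)
  prof <- function(lam) {
    y <- boxcox(R, lam)
    f <- stats::lm.wfit(Xp, y, wp)
    rss <- sum(wp * f$residuals^2)
    -0.5 * sum(wp) * log(rss / sum(wp)) + (lam - 1) * sum(wp * logR)
  }
  lam0 <- if (!free_lambda) lambda_fixed else {
    grid <- seq(max(0.05, lambda_range[1]), lambda_range[2], by = 0.05)
    grid[which.max(vapply(grid, prof, 0))]
  }
  f2 <- stats::lm.wfit(Xp, boxcox(R, lam0), wp)
  b2 <- f2$coefficients
  b2[!is.finite(b2)] <- 0
  v <- sum(wp * f2$residuals^2) / sum(wp)
  th <- c(b1, b2, log(1), log(sqrt(0.4 * v)), atanh(0.3),
          log(sqrt(max(0.6 * v, 1e-4))))
  if (free_lambda) {
    fr <- (lam0 - lambda_range[1]) / diff(lambda_range)
    th <- c(th, stats::qlogis(min(max(fr, 0.02), 0.98)))
  }
  unname(th)
}

jitter_start <- function(start, s) {
  set.seed(1000 + s)
  start + stats::rnorm(length(start), 0, 0.3)
}

#' @export
print.hgp_two_part_fit <- function(x, ...) {
  p <- x$params
  cat("Correlated two-part usual-intake model (", x$design,
      " design)\n", sep = "")
  cat(sprintf("  persons: %d  person-days: %d  two-day consumers: %d\n",
              x$n_persons, x$n_days, x$n_eaters_both_days))
  cat(sprintf("  logLik: %.3f  converged: %s  |grad|: %.2e\n",
              x$logLik, x$convergence, x$grad_norm))
  cat(sprintf("  sigma_u1: %.3f  sigma_u2: %.3f  rho: %.3f  sigma: %.3f  lambda: %.3f%s\n",
              sqrt(p$sigma2_u1), sqrt(p$sigma2_u2), p$rho, sqrt(p$sigma2),
              p$lambda, if (x$lambda_fixed) " (fixed)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-part model fit
#'
#' @param x An `hgp_two_part_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `part`
#'   (probability/amount/variance), `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.hgp_two_part_fit <- function(x, ...) {
  p <- x$params
  nm_x <- names(p$beta_x1)
  est <- c(p$beta1_0, p$beta_x1, p$beta2_0, p$beta_x2,
           sqrt(p$sigma2_u1), sqrt(p$sigma2_u2), p$rho, sqrt(p$sigma2),
           if (!x$lambda_fixed) p$lambda)
  terms <- c("(Intercept)", nm_x, "(Intercept)", nm_x,
             "sigma_u1", "sigma_u2", "rho", "sigma",
             if (!x$lambda_fixed) "lambda")
  part <- c(rep("probability", 1 + length(nm_x)),
            rep("amount", 1 + length(nm_x)),
            rep("variance", 4 + as.integer(!x$lambda_fixed)))
  se <- x$se %||% rep(NA_real_, length(est))
  stat <- est / se
  tibble::tibble(part = part, term = terms, estimate = unname(est),
                 std.error = unname(se), statistic = unname(stat),
                 p.value = 2 * stats::pnorm(-abs(unname(stat))))
}

#' Glance at a two-part model fit
#'
#' @param x An `hgp_two_part_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit-level summaries.
#' @export
glance.hgp_two_part_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    logLik = x$logLik, converged = x$convergence, grad_norm = x$grad_norm,
    n_persons = x$n_persons, n_eaters_both_days = x$n_eaters_both_days,
    sigma2_u1 = p$sigma2_u1, sigma2_u2 = p$sigma2_u2, rho = p$rho,
    sigma2 = p$sigma2, lambda = p$lambda, n_quad = x$n_quad)
}
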