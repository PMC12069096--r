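test_that("design matrices encode splines, weekends and recall sequence", {
  d <- tibble::tibble(gender = c("female", "male", "male"),
                      age = c(11, 5, 19),
                      end_of_week = c(FALSE, TRUE, FALSE),
                      sequence = c(1, 1, 2))
  X <- build_design_matrix(d, "children")
  expect_equal(unname(X[1, "age_sp11"]), 0) # knot boundary
  expect_equal(unname(X[2, "end_of_week"]), 1) # Saturday counts as end of week
  expect_equal(unname(X[3, "seq2"]), 1) # second (phone) recall
  expect_equal(unname(X[2, "male_age"]), 5)
  expect_true(all(X[, "age_sp11"] >= 0))
  expect_error(build_design_matrix(dplyr::mutate(d, age = 25), "children"),
               "ages 1-19")
  expect_error(build_design_matrix(d, "adults"), "ages 20")
  Xa <- build_design_matrix(tibble::tibble(gender = "female", age = 45,
                                           end_of_week = FALSE, sequence = 1),
                            "adults")
  expect_equal(unname(Xa[1, c("age_sp29", "age_sp39", "age_sp49")]),
               c(16, 6, 0))
})

test_that("the analytic gradient matches finite differences", {
  td <- truth_scale_data(small_config(n = 700, seed = 201, n_strata = 8))
  dat <- td$data
  pid <- factor(dat$person_id)
  id <- as.integer(pid)
  A <- as.numeric(dat$intake > 0)
  X1 <- cbind(1, build_design_matrix(dat, "basic"))
  R <- dat$intake[A == 1]
  w <- tapply(dat$weight, id, `[`, 1)
  w <- as.vector(w / mean(w))
  obj <- hgpintake:::make_two_part_objective(id, A, X1, X1, R, w, 7, NULL,
                                             c(0.01, 1))
  set.seed(202)
  th <- rnorm(obj$npar, 0, 0.2)
  th[obj$p_beta + 1] <- 7 # amount intercept near the data scale
  g <- obj$gr(th)
  gn <- vapply(seq_along(th), function(i) {
    h <- 1e-6 * max(1, abs(th[i]))
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    (obj$fn(tp) - obj$fn(tm)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g - gn) / (abs(gn) + 1)), 1e-5)
})

test_that("degenerate outcome patterns are refused", {
  td <- truth_scale_data(small_config(n = 700, seed = 203, n_strata = 8))
  dat <- td$data
  dat$intake <- abs(dat$intake) + 1
  expect_error(fit_two_part(dat, "basic"), "every person-day")
  dat$intake <- 0
  expect_error(fit_two_part(dat, "basic"), "no person-day")
})

test_that("the marginal likelihood peaks at the truth on large data", {
  cfg <- small_config(n = 2500, seed = 205)
  td <- truth_scale_data(cfg)
  dat <- td$data
  tp <- cfg$two_part
  pid <- factor(dat$person_id)
  id <- as.integer(pid)
  A <- as.numeric(dat$intake > 0)
  X1 <- cbind(1, build_design_matrix(dat, "basic"))
  R <- dat$intake[A == 1]
  w <- rep(1, nlevels(pid))
  obj <- hgpintake:::make_two_part_objective(id, A, X1, X1, R, w, 15, NULL,
                                             c(0.01, 1))
  th_true <- c(tp$beta1_0, tp$beta_x1, tp$beta2_0, tp$beta_x2,
               log(sqrt(tp$sigma2_u1)), log(sqrt(tp$sigma2_u2)),
               atanh(tp$rho), log(sqrt(tp$sigma2)),
               qlogis((tp$lambda - 0.01) / 0.99))
  nll_true <- obj$fn(th_true)
  set.seed(206)
  for (k in 1:5) {
    perturbed <- th_true + rnorm(length(th_true), 0, 0.25)
    expect_gt(obj$fn(perturbed), nll_true)
  }
})

test_that("parameters are recovered in a single moderate-size fit", {
  cfg <- small_config(n = 800, seed = 207)
  td <- truth_scale_data(cfg)
  fit <- suppressWarnings(fit_two_part(td$data, "basic", n_quad = 15))
  expect_true(fit$convergence)
  tp <- cfg$two_part
  truth_fx <- c(tp$beta1_0, tp$beta_x1, tp$beta2_0, tp$beta_x2)
  td_tab <- tidy(fit)
  fx <- td_tab[td_tab$part %in% c("probability", "amount"), ]
  expect_true(all(abs(fx$estimate - truth_fx) / fx$std.error < 4))
  expect_lt(abs(fit$params$lambda - tp$lambda), 0.15)
  expect_equal(nrow(td_tab), 15)
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$n_persons, 800)
})

test_that("quadrature is converged at the default node count", {
  td <- truth_scale_data(small_config(n = 700, seed = 209, n_strata = 8))
  f1 <- suppressWarnings(fit_two_part(td$data, "basic", n_quad = 15,
                                      se = FALSE))
  f2 <- suppressWarnings(fit_two_part(td$data, "basic", n_quad = 30,
                                      se = FALSE))
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-8)
  expect_lt(rel(f1$params$beta1_0, f2$params$beta1_0), 1e-3)
  expect_lt(rel(f1$params$beta2_0, f2$params$beta2_0), 1e-3)
  expect_lt(rel(f1$params$sigma2_u1, f2$params$sigma2_u1), 1e-3)
  expect_lt(rel(f1$params$sigma2_u2, f2$params$sigma2_u2), 1e-3)
  expect_lt(rel(f1$params$rho, f2$params$rho), 1e-3)
  expect_lt(rel(f1$params$lambda, f2$params$lambda), 1e-3)
})

test_that("with rare zeros and lambda = 1 the amount part matches a
           weighted linear mixed model reference", {
  skip_if_not_installed("lme4")
  tp <- two_part_params(
    beta1_0 = 4, # consumption probability ~ 0.98
    beta_x1 = c(male = 0, age10 = 0, end_of_week = 0, seq2 = 0),
    sigma2_u1 = 1e-4,
    beta2_0 = 50,
    beta_x2 = c(male = 5, age10 = 1, end_of_week = 2, seq2 = -1),
    sigma2_u2 = 9, rho = 0, sigma2 = 16, lambda = 1)
  cfg <- small_config(n = 1200, seed = 211, two_part = tp,
                      weight_dispersion = 1e-6)
  td <- truth_scale_data(cfg)
  fit <- suppressWarnings(
    fit_two_part(td$data, "basic", lambda = 1, se = FALSE))
  pos <- td$data[td$data$intake > 0, ]
  pos$y <- pos$intake - 1 # Box-Cox with lambda = 1
  ref <- lme4::lmer(
    y ~ I(gender == "male") + I((age - 40) / 10) + end_of_week +
      I(sequence == 2) + (1 | person_id),
    data = pos, REML = FALSE)
  fe <- lme4::fixef(ref)
  expect_equal(fit$params$beta2_0, unname(fe[1]), tolerance = 0.02)
  expect_equal(unname(fit$params$beta_x2["male"]), unname(fe[2]),
               tolerance = 0.05)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$params$sigma2_u2, vc$vcov[1], tolerance = 0.05)
  expect_equal(fit$params$sigma2, vc$vcov[2], tolerance = 0.05)
})

test_that("usual-intake simulation is monotone in the consumption intercept", {
  cfg <- small_config(n = 700, seed = 213, n_strata = 8)
  persons <- generate_population(cfg)
  tp <- cfg$two_part
  d1 <- simulate_usual_intake(tp, persons, n_sim = 20, seed = 5)
  tp2 <- tp
  tp2$beta1_0 <- tp$beta1_0 + 1
  d2 <- simulate_usual_intake(tp2, persons, n_sim = 20, seed = 5)
  expect_true(all(d2$usual >= d1$usual))
})
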