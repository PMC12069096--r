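# shared fixtures, all generated in code

small_config <- function(n = 600, seed = 101, ...) {
  truth_config(n_persons = n, seed = seed, ...)
}

# person-day model frame on the generative (raw beef grams) scale, the
# parameter-recovery workhorse
truth_scale_data <- function(cfg, recall_seed = cfg$seed + 1) {
  persons <- generate_population(cfg)
  recipes <- generate_recipes(cfg)
  rec <- generate_recalls(persons, recipes, cfg$two_part, seed = recall_seed)
  dat <- attr(rec, "true_raw_beef")
  dat <- dplyr::inner_join(
    dat,
    dplyr::select(persons, person_id, gender, age, weight),
    by = "person_id")
  dat$intake <- dat$raw_beef_g
  list(data = dat, persons = persons, recipes = recipes, recalls = rec)
}

# a small assay table with known composition
toy_assays <- function(n_detected, detected_values, n_censored, lod = 0.1,
                       analyte = "X", tissue = "non-fat") {
  tibble::tibble(
    sample_id = sprintf("T%04d", seq_len(n_detected + n_censored)),
    analyte = analyte,
    tissue_class = tissue,
    detected = rep(c(TRUE, FALSE), c(n_detected, n_censored)),
    concentration = c(detected_values, rep(NA_real_, n_censored)),
    lod = lod,
    paired_parent_id = NA_character_)
}

# brute-force weighted quantile: explicit CDF inversion with interpolation
# at midpoint plotting positions (independent of weighted_quantile()'s
# approx-based implementation)
bf_weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  W <- sum(w)
  pk <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) {
    pk[i] <- (acc + 0.5 * w[i]) / W
    acc <- acc + w[i]
  }
  out <- numeric(length(p))
  for (j in seq_along(p)) {
    if (p[j] <= pk[1]) { out[j] <- x[1]; next }
    if (p[j] >= pk[length(pk)]) { out[j] <- x[length(x)]; next }
    i <- max(which(pk <= p[j]))
    # step past ties in pk (distinct x at identical plotting position)
    i2 <- i + 1
    out[j] <- x[i] + (x[i2] - x[i]) * (p[j] - pk[i]) / (pk[i2] - pk[i])
  }
  out
}

# enumeration oracle for the signed-rank null (independent of the package's
# expand.grid-based enumeration: recursive sign flipping)
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vs <- 0
  for (s in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(s))[1:m]
    vs <- c(vs, sum(r[bits == 1]))
  }
  vs <- vs[-1]
  min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
}
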