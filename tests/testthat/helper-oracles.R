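# Literal loop-and-accumulate oracles, kept deliberately independent of
# the package's vectorised implementations.

oracle_rms_relative_error <- function(predicted, observed) {
  acc <- 0
  for (i in seq_along(predicted)) {
    acc <- acc + ((predicted[i] - observed[i]) / observed[i])^2
  }
  sqrt(acc / length(predicted))
}

oracle_moments <- function(x) {
  m <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / m
  ss <- 0
  for (v in x) ss <- ss + (v - mu)^2
  sd_unc <- sqrt(ss / m)
  sd_cor <- sqrt(ss / (m - 1))
  s3 <- 0
  s4 <- 0
  for (v in x) {
    s3 <- s3 + ((v - mu) / sd_unc)^3
    s4 <- s4 + ((v - mu) / sd_unc)^4
  }
  skew <- sqrt(m * (m - 1)) / (m - 2) * s3 / m
  kurt <- (m - 1) / ((m - 2) * (m - 3)) * ((m + 1) * s4 / m - 3 * (m - 1)) + 3
  list(mean = mu, sd_corrected = sd_cor, sd_uncorrected = sd_unc,
       skewness = skew, kurtosis = kurt)
}

# closed-form simple-regression normal equations
oracle_ols <- function(x, y) {
  m <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (m * sxy - sx * sy) / (m * sxx - sx^2)
  intercept <- (sy - slope * sx) / m
  c(slope = slope, intercept = intercept)
}

# colony table consistent with the default noise-free biometric laws
make_colonies <- function(n_max, n_other = n_max, fresh = NULL, dry = NA_real_) {
  rachis <- 2.6 * n_max - 1.1
  peduncle <- 3.2 * n_max + 9.2
  n_wt <- (n_max + n_other) / 2
  if (is.null(fresh)) {
    fresh <- pmax(0.01, -0.0013 * n_wt^3 + 0.076 * n_wt^2 - 1.17 * n_wt + 5.342)
  }
  validate_colony_table(data.frame(
    colony_id = sprintf("C%03d", seq_along(n_max)),
    leaves_left = n_max,
    leaves_right = n_other,
    total_length_mm = rachis + peduncle,
    peduncle_length_mm = peduncle,
    fresh_weight_g = fresh,
    dry_weight_g = dry,
    stringsAsFactors = FALSE
  ))
}

default_cubic <- function() {
  cubic_weight_model(-0.0013, 0.076, -1.170, 5.342)
}

quiet_pipeline <- function(...) {
  suppressWarnings(run_pipeline(default_run_config(...)))
}
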