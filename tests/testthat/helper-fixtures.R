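# shared fixtures: default generating parameters and a tiny observation table
fix_pk <- function() mouse_pk_params()
fix_pd <- function() mouse_pd_params()

# minimal well-formed observation data.frame
tiny_obs <- function(values = c(500, 300, 50),
                     times = c(1, 7, 24)) {
  data.frame(subject = paste0("m", seq_along(times)),
             time_h = times, value = values,
             dose_mg_kg = 25, interval_h = 24, n_doses = 1, route = "oral",
             stringsAsFactors = FALSE)
}

human_ss_metrics_for_test <- function(dose_mg, cfg, interval = 24) {
  metapkpd:::human_ss_metrics(dose_mg, cfg, interval)
}

# brute-force least squares on the log-log scale via the normal equations,
# independent of lm(): used as the regression oracle
brute_force_loglog <- function(bw, y) {
  x <- log10(bw); z <- log10(y)
  n <- length(x)
  sx <- sum(x); sz <- sum(z)
  sxx <- sum(x^2); sxz <- sum(x * z)
  slope <- (n * sxz - sx * sz) / (n * sxx - sx^2)
  intercept <- (sz - slope * sx) / n
  zhat <- intercept + slope * x
  r2 <- 1 - sum((z - zhat)^2) / sum((z - mean(z))^2)
  list(coefficient = 10^intercept, exponent = slope, r_squared = r2)
}
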