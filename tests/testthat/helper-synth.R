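# Shared fixtures: all built in code at test time.

# Outcome table with constant parameters across the 11 outcomes.
flat_outcomes <- function(act_change = 0, bt_minus_act = 0, change_sd = 0,
                          rho_left = 0, rho_right = 0) {
  oc <- nirscog:::default_outcome_table()
  oc$act_change <- act_change
  oc$bt_minus_act <- bt_minus_act
  oc$change_sd <- change_sd
  oc$rho_left <- rho_left
  oc$rho_right <- rho_right
  oc
}

# A config with every stochastic component silenced; deterministic outputs.
zero_noise_config <- function(outcomes = flat_outcomes(), amp = 1) {
  effect_config(
    outcomes = outcomes,
    amp_mean = c(BT = amp, ACT = amp), amp_sdlog = 0,
    mayer_amp = 0, cardiac_amp = 0, ar_sd = 0,
    coupling_sd = 0, drift_sd = 0, noise_sd = 0,
    age_sd = 0
  )
}

# Long-format activity table taken directly from a cohort's latent
# amplitudes (ground truth, bypassing the recording stage).
amplitude_activity <- function(cohort) {
  a <- cohort$amplitudes
  rbind(
    data.frame(id = a$id, side = "left", activity = a$left,
               stringsAsFactors = FALSE),
    data.frame(id = a$id, side = "right", activity = a$right,
               stringsAsFactors = FALSE)
  )
}

# Sine-wave amplitude measured away from filter edge transients.
interior_amplitude <- function(x, fs, trim_s = 20) {
  i <- seq(round(trim_s * fs), length(x) - round(trim_s * fs))
  (max(x[i]) - min(x[i])) / 2
}

# Independent classical partial-F oracle: two explicit lm() fits and a
# direct sum-of-squares comparison (never touches the package's QR path).
classical_partial_F <- function(y, group, covariates = NULL) {
  g <- factor(group)
  if (is.null(covariates)) {
    full <- stats::lm(y ~ g)
    red <- stats::lm(y ~ 1)
  } else {
    Z <- as.data.frame(covariates)
    full <- stats::lm(y ~ ., data = cbind(Z, g = g))
    red <- stats::lm(y ~ ., data = Z)
  }
  sse_f <- sum(stats::residuals(full)^2)
  sse_r <- sum(stats::residuals(red)^2)
  df_resid <- stats::df.residual(full)
  ((sse_r - sse_f) / 1) / (sse_f / df_resid)
}
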