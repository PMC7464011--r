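#' Names of the eleven cognitive outcomes
#'
#' Digit symbol coding (Cd) and symbol search (SS) for processing speed;
#' reverse Stroop (rST) and Stroop (ST) for inhibition; digit span forward
#' (DSF) and backward (DSB) for short-term memory; letter-number sequencing
#' (LNS) and working-memory updating (WMU) for working memory; digit
#' cancellation (DCAT) for attention; logical memory immediate (LMi) and
#' delayed (LMd) recall for episodic memory.
#'
#' @return character vector of length 11.
#' @export
outcome_names <- function() {
  c("Cd", "SS", "rST", "ST", "DSF", "DSB", "LNS", "WMU", "DCAT", "LMi", "LMd")
}

# Default per-outcome generative parameters. Baseline means/SDs and the
# arm-specific mean changes are calibrated loosely to values typical of
# healthy young adults on these instruments; `bt_minus_act` is the mean
# change-score advantage of the training arm over the active control.
default_outcome_table <- function() {
  data.frame(
    outcome      = outcome_names(),
    pre_mean     = c(59.8, 30.0, 37.5, 25.7, 5.24, 3.97, 6.29, 7.27, 3.97, 8.91, 8.40),
    pre_sd       = c(10.5,  4.0,  5.6,  7.8, 1.08, 0.98, 1.31, 1.22, 0.98, 3.83, 3.81),
    act_change   = c(0.68, 0.79, 0.89, 0.29, 0.29, 0.21, 0.78, 0.66, 11.14, -0.18, -0.32),
    bt_minus_act = c(3.80, 2.36, 3.11, 2.41, -0.29, 0.12, 2.43, 1.51, 1.23, 3.39, 4.63),
    change_sd    = c(5.10, 3.42, 4.95, 3.86, 1.20, 0.98, 1.87, 0.91, 21.46, 3.08, 3.19),
    rho_left     = c(0.40, 0.40, 0, 0, 0, 0, 0.40, 0.40, 0, 0, 0),
    rho_right    = c(0.40, 0.40, 0, 0, 0, 0, 0.40, 0.40, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Generative configuration for the synthetic trial
#'
#' Bundles every tunable of the synthetic-data generator: per-outcome mean
#' changes and noise, the brain-change correlations `rho_left`/`rho_right`
#' linking latent neural amplitude to change scores, the group-specific
#' latent-amplitude distribution, and the recording noise model (shared
#' systemic physiology, drift, measurement noise).
#'
#' @param outcomes data.frame with columns `outcome`, `pre_mean`, `pre_sd`,
#'   `act_change`, `bt_minus_act`, `change_sd`, `rho_left`, `rho_right`.
#' @param amp_mean named numeric: mean latent neural amplitude (a.u.) per arm.
#' @param amp_sdlog log-scale SD of the log-normal amplitude distribution.
#' @param mayer_amp,mayer_freq amplitude (a.u.) and frequency (Hz) of the
#'   slow vasomotor (Mayer-wave) systemic oscillation.
#' @param cardiac_amp,cardiac_freq amplitude and frequency of the cardiac
#'   pulsation component.
#' @param ar_phi,ar_sd AR(1) coefficient and innovation SD of the slow
#'   systemic wander shared by shallow and deep channels.
#' @param coupling_mean,coupling_sd mean and SD of the per-recording
#'   deep-channel systemic coupling coefficient.
#' @param drift_sd SD of the random linear drift slope (a.u. per second),
#'   drawn independently for shallow and deep.
#' @param noise_sd SD of white measurement noise on each channel.
#' @param age_mean,age_sd,age_range age distribution (years), truncated.
#' @param male_fraction fraction of male participants in the cohort.
#' @return An `effect_config` object (a validated list).
#' @export
effect_config <- function(outcomes = default_outcome_table(),
                          amp_mean = c(BT = 1.0, ACT = 0.65),
                          amp_sdlog = 0.4,
                          mayer_amp = 0.3, mayer_freq = 0.08,
                          cardiac_amp = 0.3, cardiac_freq = 1.1,
                          ar_phi = 0.995, ar_sd = 0.02,
                          coupling_mean = 1.0, coupling_sd = 0.1,
                          drift_sd = 0.01,
                          noise_sd = 0.05,
                          age_mean = 21.63, age_sd = 1.26,
                          age_range = c(18, 30),
                          male_fraction = 2 / 3) {
  cfg <- list(
    outcomes = outcomes, amp_mean = amp_mean, amp_sdlog = amp_sdlog,
    mayer_amp = mayer_amp, mayer_freq = mayer_freq,
    cardiac_amp = cardiac_amp, cardiac_freq = cardiac_freq,
    ar_phi = ar_phi, ar_sd = ar_sd,
    coupling_mean = coupling_mean, coupling_sd = coupling_sd,
    drift_sd = drift_sd, noise_sd = noise_sd,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    male_fraction = male_fraction
  )
  validate_effect_config(cfg)
  class(cfg) <- "effect_config"
  cfg
}

validate_effect_config <- function(cfg) {
  oc <- cfg$outcomes
  need <- c("outcome", "pre_mean", "pre_sd", "act_change", "bt_minus_act",
            "change_sd", "rho_left", "rho_right")
  if (!is.data.frame(oc) || !all(need %in% names(oc))) {
    stop("`outcomes` must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  }
  sds <- c(oc$pre_sd, oc$change_sd, cfg$amp_sdlog, cfg$ar_sd, cfg$drift_sd,
           cfg$noise_sd, cfg$age_sd, cfg$coupling_sd,
           cfg$mayer_amp, cfg$cardiac_amp)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all SDs and noise amplitudes must be finite and >= 0")
  }
  if (any(abs(oc$rho_left) > 1) || any(abs(oc$rho_right) > 1)) {
    stop("|rho| must be <= 1")
  }
  if (any(oc$rho_left^2 + oc$rho_right^2 > 1 + 1e-12)) {
    stop("rho_left^2 + rho_right^2 must be <= 1 for each outcome")
  }
  if (!all(c("BT", "ACT") %in% names(cfg$amp_mean)) || any(cfg$amp_mean <= 0)) {
    stop("`amp_mean` must supply positive values for BT and ACT")
  }
  if (abs(cfg$ar_phi) >= 1) stop("`ar_phi` must lie in (-1, 1)")
  invisible(cfg)
}

#' Null generative configuration
#'
#' An [effect_config()] with every between-arm mean difference and every
#' brain-change correlation set to zero, and identical amplitude
#' distributions in both arms: the generating model satisfies the null
#' hypothesis of every downstream test.
#'
#' @param ... overrides passed on to [effect_config()].
#' @return An `effect_config`.
#' @export
null_effect_config <- function(...) {
  oc <- default_outcome_table()
  oc$bt_minus_act <- 0
  oc$rho_left <- 0
  oc$rho_right <- 0
  effect_config(outcomes = oc, amp_mean = c(BT = 1.0, ACT = 1.0), ...)
}

#' @export
print.effect_config <- function(x, ...) {
  cat("effect_config:", nrow(x$outcomes), "outcomes\n")
  cat(sprintf("  amplitude mean BT %.2f / ACT %.2f (sdlog %.2f)\n",
              x$amp_mean[["BT"]], x$amp_mean[["ACT"]], x$amp_sdlog))
  cat(sprintf("  systemic: %.2f a.u. @ %.2f Hz + %.2f a.u. @ %.2f Hz + AR(1) phi=%.3f\n",
              x$mayer_amp, x$mayer_freq, x$cardiac_amp, x$cardiac_freq, x$ar_phi))
  invisible(x)
}

#' Read or write an effect configuration as YAML
#'
#' @param path file path.
#' @return `read_effect_config` returns an `effect_config`;
#'   `write_effect_config` returns `path` invisibly.
#' @export
read_effect_config <- function(path) {
  raw <- yaml::read_yaml(path)
  oc <- as.data.frame(raw$outcomes, stringsAsFactors = FALSE)
  raw$outcomes <- NULL
  raw$amp_mean <- unlist(raw$amp_mean)
  raw$age_range <- as.numeric(raw$age_range)
  do.call(effect_config, c(list(outcomes = oc), raw))
}

#' @rdname read_effect_config
#' @param cfg an `effect_config`.
#' @export
write_effect_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "effect_config"))
  out <- unclass(cfg)
  out$outcomes <- as.list(cfg$outcomes)
  out$amp_mean <- as.list(cfg$amp_mean)
  yaml::write_yaml(out, path)
  invisible(path)
}
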