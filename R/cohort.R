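# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never clobber user RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Stratified blocked randomization
#'
#' Assigns participants to the BT (brain training) or ACT (active control)
#' arm with a 1:1 allocation ratio using permuted blocks within each sex
#' stratum. Every complete block of `block_size` participants contains
#' exactly `block_size / 2` of each arm, so arm totals within a stratum can
#' differ by at most `block_size / 2` (and only via an incomplete final
#' block, within which counts differ by at most 1).
#'
#' @param participants data.frame with columns `id` and `sex`
#'   (`"M"`/`"F"`).
#' @param block_size even block size (default 4).
#' @param seed integer seed; the assignment is a deterministic function of it.
#' @return Named character vector mapping `id` to `"BT"` or `"ACT"`.
#' @export
stratified_block_randomize <- function(participants, block_size = 4, seed) {
  stopifnot(is.data.frame(participants),
            all(c("id", "sex") %in% names(participants)))
  if (missing(seed)) stop("`seed` is required for a reproducible allocation")
  if (block_size %% 2 != 0 || block_size < 2) {
    stop("`block_size` must be even to satisfy the 1:1 allocation ratio")
  }
  if (anyDuplicated(participants$id)) stop("participant ids must be unique")
  with_seed(seed, {
    out <- character(0)
    for (s in unique(participants$sex)) {
      ids <- participants$id[participants$sex == s]
      n <- length(ids)
      n_blocks <- ceiling(n / block_size)
      arms <- character(0)
      for (b in seq_len(n_blocks)) {
        arms <- c(arms, sample(rep(c("BT", "ACT"), block_size / 2)))
      }
      assign_s <- arms[seq_len(n)]
      names(assign_s) <- ids
      out <- c(out, assign_s)
    }
    out[participants$id]
  })
}

# Truncated-normal draw by rejection; the truncation range is wide relative
# to the SD so rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Standardize a log-normal amplitude by its theoretical (per-arm) moments so
# the configured rho is the exact within-arm correlation scale.
standardize_amplitude <- function(a, mean, sdlog) {
  s <- mean * sqrt(exp(sdlog^2) - 1)
  if (s == 0) return(rep(0, length(a)))
  (a - mean) / s
}

#' Generate a synthetic two-arm trial cohort
#'
#' Draws demographics, randomizes arms by stratified permuted blocks, draws
#' latent left/right neural amplitudes (log-normal, arm-specific mean), and
#' builds pre/post scores for the eleven cognitive outcomes. The change
#' score for outcome j is
#' \deqn{\Delta_j = \mu_{ACT,j} + \delta_j 1[BT] + \sigma_j (\rho_L z_L +
#'   \rho_R z_R + \sqrt{1 - \rho_L^2 - \rho_R^2}\,\epsilon)}
#' where \eqn{z_L, z_R} are the latent amplitudes standardized by their
#' within-arm moments, so \eqn{\rho} is the exact generative brain-change
#' correlation and all latent quantities are stored for ground-truth tests.
#'
#' Each participant consumes an independent seed substream derived from
#' `seed`, so generated values do not depend on generation order.
#'
#' @param n_per_group participants per arm (>= 2).
#' @param config an [effect_config()].
#' @param seed master integer seed.
#' @return A `nirs_cohort`: list with `participants` (data.frame `id`,
#'   `group`, `sex`, `age`, `<outcome>_pre`, `<outcome>_post`), `amplitudes`
#'   (data.frame `id`, `left`, `right`), `rec_seeds`, `config`, `seed`.
#' @export
make_cohort <- function(n_per_group, config = effect_config(), seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(inherits(config, "effect_config"))
  if (n_per_group < 2) stop("`n_per_group` must be >= 2")
  validate_effect_config(config)

  n_total <- 2L * n_per_group
  n_male <- round(n_total * config$male_fraction)
  ids <- sprintf("P%03d", seq_len(n_total))
  sex <- c(rep("M", n_male), rep("F", n_total - n_male))

  streams <- with_seed(seed, {
    list(
      rand_seed = sample.int(.Machine$integer.max, 1L),
      p_seeds = sample.int(.Machine$integer.max, n_total),
      rec_seeds = matrix(sample.int(.Machine$integer.max, 2L * n_total),
                         ncol = 2L, dimnames = list(NULL, c("left", "right")))
    )
  })
  group <- stratified_block_randomize(
    data.frame(id = ids, sex = sex, stringsAsFactors = FALSE),
    block_size = 4, seed = streams$rand_seed
  )

  oc <- config$outcomes
  k <- nrow(oc)
  pre <- post <- matrix(NA_real_, n_total, k, dimnames = list(NULL, oc$outcome))
  age <- amp_l <- amp_r <- numeric(n_total)
  resid_scale <- sqrt(pmax(0, 1 - oc$rho_left^2 - oc$rho_right^2))

  for (i in seq_len(n_total)) {
    g <- group[[i]]
    mu_a <- config$amp_mean[[g]]
    draws <- with_seed(streams$p_seeds[i], {
      list(
        age = rtruncnorm(1, config$age_mean, config$age_sd,
                         config$age_range[1], config$age_range[2]),
        amp = stats::rlnorm(2, meanlog = log(mu_a) - config$amp_sdlog^2 / 2,
                            sdlog = config$amp_sdlog),
        pre = stats::rnorm(k, oc$pre_mean, oc$pre_sd),
        eps = stats::rnorm(k)
      )
    })
    age[i] <- draws$age
    amp_l[i] <- draws$amp[1]
    amp_r[i] <- draws$amp[2]
    z_l <- standardize_amplitude(amp_l[i], mu_a, config$amp_sdlog)
    z_r <- standardize_amplitude(amp_r[i], mu_a, config$amp_sdlog)
    change <- oc$act_change + oc$bt_minus_act * (g == "BT") +
      oc$change_sd * (oc$rho_left * z_l + oc$rho_right * z_r +
                        resid_scale * draws$eps)
    pre[i, ] <- draws$pre
    post[i, ] <- draws$pre + change
  }

  participants <- data.frame(
    id = ids, group = unname(group), sex = sex, age = age,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(k)) {
    participants[[paste0(oc$outcome[j], "_pre")]] <- pre[, j]
    participants[[paste0(oc$outcome[j], "_post")]] <- post[, j]
  }
  cohort <- list(
    participants = participants,
    amplitudes = data.frame(id = ids, left = amp_l, right = amp_r,
                            stringsAsFactors = FALSE),
    rec_seeds = streams$rec_seeds,
    config = config,
    seed = seed
  )
  class(cohort) <- "nirs_cohort"
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  p <- cohort$participants
  oc <- cohort$config$outcomes$outcome
  cols <- c(paste0(oc, "_pre"), paste0(oc, "_post"))
  if (!all(cols %in% names(p))) stop("missing outcome columns in cohort")
  if (!all(is.finite(as.matrix(p[cols])))) stop("non-finite outcome scores")
  rng <- cohort$config$age_range
  if (any(p$age < rng[1] | p$age > rng[2])) stop("age outside configured range")
  if (!all(p$group %in% c("BT", "ACT"))) stop("invalid group labels")
  invisible(cohort)
}

#' @export
print.nirs_cohort <- function(x, ...) {
  tab <- table(x$participants$group, x$participants$sex)
  cat(sprintf("nirs_cohort: %d participants (BT %d / ACT %d), seed %d\n",
              nrow(x$participants), sum(x$participants$group == "BT"),
              sum(x$participants$group == "ACT"), x$seed))
  print(tab)
  invisible(x)
}

#' Compute change scores (post minus pre)
#'
#' @param pre,post numeric vectors of equal length with finite values.
#' @return numeric vector of per-participant change scores.
#' @export
change_scores <- function(pre, post) {
  if (length(pre) != length(post)) stop("`pre` and `post` lengths differ")
  if (!all(is.finite(pre)) || !all(is.finite(post))) {
    stop("`pre` and `post` must be finite")
  }
  post - pre
}

#' Write / read the participant table as CSV
#'
#' One row per participant, columns `id,group,sex,age,<outcome>_pre,
#' <outcome>_post`.
#'
#' @param cohort a `nirs_cohort` or a bare participant data.frame.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the participant data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "nirs_cohort")) cohort$participants else cohort
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
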