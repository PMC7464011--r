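# Shared plumbing for the three analysis families: build the per-analysis
# data frame from the participant table and the long activity table.

sex_indicator <- function(sex) as.numeric(sex == "M")

activity_wide <- function(activity) {
  need <- c("id", "side", "activity")
  if (!all(need %in% names(activity))) {
    stop("activity table must have columns id, side, activity")
  }
  left <- activity[activity$side == "left", c("id", "activity")]
  right <- activity[activity$side == "right", c("id", "activity")]
  names(left)[2] <- "activity_left"
  names(right)[2] <- "activity_right"
  merge(left, right, by = "id")
}

check_complete <- function(df, what) {
  if (anyNA(df)) stop("missing values in ", what,
                      "; supply complete data or impute upstream")
  invisible(df)
}

derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

#' Baseline brain-activity group comparison
#'
#' Permutation ANCOVA of baseline DLPFC activity on group, separately per
#' hemisphere, adjusting for age and sex. The two p-values form one FDR
#' family.
#'
#' @param participants participant data.frame (`id`, `group`, `sex`, `age`,
#'   score columns).
#' @param activity long activity table (`id`, `side`, `activity`).
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return data.frame: one row per side with group means, `F`, dfs, `eta2`,
#'   `p_perm`, `p_adjusted`.
#' @export
baseline_activity_ancova <- function(participants, activity, n_perm = 10000,
                                     seed) {
  if (missing(seed)) stop("`seed` is required")
  wide <- merge(participants[, c("id", "group", "sex", "age")],
                activity_wide(activity), by = "id")
  check_complete(wide, "baseline activity analysis")
  seeds <- derive_seeds(seed, 2L)
  rows <- lapply(seq_along(c("left", "right")), function(i) {
    s <- c("left", "right")[i]
    y <- wide[[paste0("activity_", s)]]
    res <- ancova_permutation(
      y, wide$group,
      covariates = cbind(age = wide$age, sexM = sex_indicator(wide$sex)),
      n_perm = n_perm, seed = seeds[i], outcome = s
    )
    data.frame(
      side = s, n = res$n,
      mean_BT = mean(y[wide$group == "BT"]),
      mean_ACT = mean(y[wide$group == "ACT"]),
      F = res$F, df_effect = res$df_effect, df_resid = res$df_resid,
      eta2 = res$eta2, p_perm = res$p_perm, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- fdr_adjust(out$p_perm)
  out
}

#' Change-score group comparisons across all outcomes
#'
#' For each cognitive outcome, the change score (post minus pre) is compared
#' between arms by permutation ANCOVA with the pre-score, age and sex as
#' covariates. The resulting p-values form one FDR family. The table layout
#' mirrors a standard trial report: per-arm mean/SD of change, effect size,
#' adjusted and non-adjusted p.
#'
#' @inheritParams baseline_activity_ancova
#' @param outcomes character vector of outcome names (default all 11).
#' @return data.frame with one row per outcome.
#' @export
change_score_ancova <- function(participants, outcomes = outcome_names(),
                                n_perm = 10000, seed) {
  if (missing(seed)) stop("`seed` is required")
  seeds <- derive_seeds(seed, length(outcomes))
  rows <- lapply(seq_along(outcomes), function(j) {
    oc <- outcomes[j]
    pre <- participants[[paste0(oc, "_pre")]]
    post <- participants[[paste0(oc, "_post")]]
    if (is.null(pre) || is.null(post)) stop("missing columns for outcome ", oc)
    delta <- change_scores(pre, post)
    df <- data.frame(delta = delta, pre = pre, age = participants$age,
                     sexM = sex_indicator(participants$sex),
                     group = participants$group)
    check_complete(df, paste("change-score analysis of", oc))
    res <- ancova_permutation(
      df$delta, df$group,
      covariates = df[, c("pre", "age", "sexM")],
      n_perm = n_perm, seed = seeds[j], outcome = oc
    )
    bt <- delta[df$group == "BT"]
    act <- delta[df$group == "ACT"]
    data.frame(
      outcome = oc, n = res$n,
      mean_BT = mean(bt), sd_BT = stats::sd(bt),
      mean_ACT = mean(act), sd_ACT = stats::sd(act),
      F = res$F, df_effect = res$df_effect, df_resid = res$df_resid,
      eta2 = res$eta2, p_perm = res$p_perm, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- fdr_adjust(out$p_perm)
  out
}

#' Permutation regressions linking baseline activity to cognitive change
#'
#' For each hemisphere and outcome, a permutation multiple regression with
#' the pre-score, age and sex as covariates, restricted to one arm (the
#' training arm by default). `direction = "change_on_brain"` regresses the
#' change score on activity; `"brain_on_change"` fits the transposed model
#' (activity as response). All p-values across sides and outcomes form one
#' FDR family.
#'
#' @inheritParams baseline_activity_ancova
#' @param outcomes character vector of outcome names.
#' @param group arm to analyse (`"BT"`, `"ACT"` or `"all"`).
#' @param direction see [perm_regression()].
#' @return data.frame with one row per side x outcome.
#' @export
activity_change_regression <- function(participants, activity,
                                       outcomes = outcome_names(),
                                       group = "BT",
                                       direction = c("change_on_brain",
                                                     "brain_on_change"),
                                       n_perm = 10000, seed) {
  if (missing(seed)) stop("`seed` is required")
  direction <- match.arg(direction)
  wide <- merge(participants, activity_wide(activity), by = "id")
  if (group != "all") wide <- wide[wide$group == group, ]
  sides <- c("left", "right")
  seeds <- derive_seeds(seed, length(outcomes) * length(sides))
  i <- 0L
  rows <- list()
  for (oc in outcomes) {
    pre <- wide[[paste0(oc, "_pre")]]
    delta <- change_scores(pre, wide[[paste0(oc, "_post")]])
    for (s in sides) {
      i <- i + 1L
      act <- wide[[paste0("activity_", s)]]
      covs <- cbind(pre = pre, age = wide$age,
                    sexM = sex_indicator(wide$sex))
      check_complete(data.frame(delta, act, covs),
                     paste("regression of", oc, s))
      res <- if (direction == "change_on_brain") {
        perm_regression(delta, act, covariates = covs, n_perm = n_perm,
                        seed = seeds[i], direction = direction,
                        outcome = oc, side = s)
      } else {
        perm_regression(act, delta, covariates = covs, n_perm = n_perm,
                        seed = seeds[i], direction = direction,
                        outcome = oc, side = s)
      }
      rows[[i]] <- data.frame(
        outcome = oc, side = s, direction = direction, n = res$n,
        beta_std = res$beta_std, t = res$t, p_perm = res$p_perm,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- fdr_adjust(out$p_perm)
  out
}
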