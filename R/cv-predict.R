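#' Balanced k-fold split
#'
#' Shuffles the ids (deterministically in `seed`) and assigns them to `k`
#' folds whose sizes differ by at most one, so each held-out fold is
#' `1/k` of the data up to one participant.
#'
#' @param ids character/integer vector of unique ids.
#' @param k number of folds, `2 <= k <= length(ids)`.
#' @param seed integer seed.
#' @return named integer vector mapping id to fold index `1..k`.
#' @export
kfold_split <- function(ids, k = 5, seed) {
  if (missing(seed)) stop("`seed` is required")
  n <- length(ids)
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (k < 2 || k > n) stop("`k` must satisfy 2 <= k <= length(ids)")
  with_seed(seed, {
    shuffled <- sample(ids)
    sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
    fold <- rep(seq_len(k), times = sizes)
    names(fold) <- shuffled
    fold[as.character(ids)]
  })
}

#' Cross-validated RMSE for one hemisphere/outcome prediction model
#'
#' k-fold cross-validation of the linear model
#' `change ~ activity + pre + age + sex` within one arm. In each fold the
#' model is fitted by least squares on the training 80% with every
#' continuous variable z-scored using training-fold statistics; the held-out
#' 20% is transformed with the same statistics and the RMSE of the
#' predictions is computed on the standardized outcome scale (so 1.0 is the
#' error of an uninformative model and values are comparable across
#' outcomes and sides). A fold whose training outcome has zero variance is
#' excluded from the mean with a warning.
#'
#' @param participants participant data.frame.
#' @param activity long activity table (`id`, `side`, `activity`).
#' @param side `"left"` or `"right"`.
#' @param outcome one outcome name.
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold split (ignored when `folds` given).
#' @param folds optional precomputed [kfold_split()] assignment, used to
#'   share folds between the left and right models.
#' @param group arm to analyse (default `"BT"`).
#' @param covariates character subset of `c("pre", "age", "sex")` to adjust
#'   for (default all three).
#' @return A `cv_result`: `side`, `outcome`, `fold_rmse`, `mean_rmse`,
#'   `folds`, `n`, `excluded`.
#' @export
cv_rmse <- function(participants, activity, side, outcome, k = 5, seed = NULL,
                    folds = NULL, group = "BT",
                    covariates = c("pre", "age", "sex")) {
  side <- match.arg(side, c("left", "right"))
  wide <- merge(participants, activity_wide(activity), by = "id")
  if (group != "all") wide <- wide[wide$group == group, ]
  pre <- wide[[paste0(outcome, "_pre")]]
  df <- data.frame(
    id = wide$id,
    change = change_scores(pre, wide[[paste0(outcome, "_post")]]),
    activity = wide[[paste0("activity_", side)]],
    pre = pre, age = wide$age, sex = sex_indicator(wide$sex),
    stringsAsFactors = FALSE
  )
  check_complete(df, paste("cross-validation of", outcome, side))
  if (is.null(folds)) {
    if (is.null(seed)) stop("supply `seed` or a precomputed `folds`")
    folds <- kfold_split(df$id, k, seed)
  }
  if (!setequal(names(folds), df$id)) {
    stop("fold assignment does not cover exactly the analysed participants")
  }
  k <- max(folds)
  cont_preds <- intersect(covariates, c("pre", "age"))
  use_sex <- "sex" %in% covariates

  fold_rmse <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test_ids <- names(folds)[folds == f]
    is_test <- df$id %in% test_ids
    tr <- df[!is_test, ]
    te <- df[is_test, ]
    mu_y <- mean(tr$change); sd_y <- stats::sd(tr$change)
    if (!is.finite(sd_y) || sd_y == 0) {
      warning(sprintf("fold %d: zero outcome variance in training set; excluded", f))
      next
    }
    zcols <- c("activity", cont_preds)
    stats_mu <- vapply(zcols, function(v) mean(tr[[v]]), numeric(1))
    stats_sd <- vapply(zcols, function(v) {
      s <- stats::sd(tr[[v]]); if (is.finite(s) && s > 0) s else 1
    }, numeric(1))
    ztr <- tr; zte <- te
    for (v in zcols) {
      ztr[[v]] <- (tr[[v]] - stats_mu[[v]]) / stats_sd[[v]]
      zte[[v]] <- (te[[v]] - stats_mu[[v]]) / stats_sd[[v]]
    }
    ztr$change <- (tr$change - mu_y) / sd_y
    zte$change <- (te$change - mu_y) / sd_y
    pred_cols <- c("activity", cont_preds, if (use_sex) "sex")
    X_tr <- cbind(1, as.matrix(ztr[, pred_cols, drop = FALSE]))
    X_te <- cbind(1, as.matrix(zte[, pred_cols, drop = FALSE]))
    beta <- stats::lm.fit(X_tr, ztr$change)$coefficients
    beta[is.na(beta)] <- 0
    pred <- as.numeric(X_te %*% beta)
    fold_rmse[f] <- sqrt(mean((pred - zte$change)^2))
  }
  ok <- !is.na(fold_rmse)
  if (!any(ok)) stop("all folds excluded; cannot compute a mean RMSE")
  structure(
    list(side = side, outcome = outcome, fold_rmse = fold_rmse,
         mean_rmse = mean(fold_rmse[ok]), folds = folds, n = nrow(df),
         excluded = which(!ok)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s/%s]: mean RMSE %.3f over %d folds (n = %d)\n",
              x$outcome, x$side, x$mean_rmse, length(x$fold_rmse), x$n))
  invisible(x)
}

#' Compare left- and right-hemisphere prediction models
#'
#' Requires the two results to share the outcome and the fold assignment
#' (a paired comparison). The difference is `second - first` mean RMSE, so
#' exchanging the arguments flips its sign but not the winner.
#'
#' @param cv_a,cv_b two `cv_result` objects for the same outcome and folds.
#' @return data.frame with both RMSEs, their difference and the winning side.
#' @export
compare_sides <- function(cv_a, cv_b) {
  stopifnot(inherits(cv_a, "cv_result"), inherits(cv_b, "cv_result"))
  if (!identical(cv_a$outcome, cv_b$outcome)) {
    stop("results are for different outcomes")
  }
  if (!identical(cv_a$folds[order(names(cv_a$folds))],
                 cv_b$folds[order(names(cv_b$folds))])) {
    stop("fold assignments differ; refit with shared folds")
  }
  diff <- cv_b$mean_rmse - cv_a$mean_rmse
  data.frame(
    outcome = cv_a$outcome,
    side_a = cv_a$side, rmse_a = cv_a$mean_rmse,
    side_b = cv_b$side, rmse_b = cv_b$mean_rmse,
    difference = diff,
    winner = if (diff > 0) cv_a$side else if (diff < 0) cv_b$side else "tie",
    stringsAsFactors = FALSE
  )
}

#' Cross-validate every outcome for both hemispheres
#'
#' Runs [cv_rmse()] for the left and right models of each outcome with a
#' shared fold assignment per outcome, and appends pooled (across-outcome
#' mean) rows per side.
#'
#' @inheritParams cv_rmse
#' @param outcomes character vector of outcome names.
#' @return data.frame with columns `outcome`, `side`, `mean_rmse`, and the
#'   per-fold RMSEs; pooled rows have outcome `"(pooled)"`.
#' @export
cross_validate_all <- function(participants, activity,
                               outcomes = outcome_names(), k = 5, seed,
                               group = "BT") {
  if (missing(seed)) stop("`seed` is required")
  seeds <- derive_seeds(seed, length(outcomes))
  rows <- list()
  for (j in seq_along(outcomes)) {
    oc <- outcomes[j]
    ids <- participants$id[participants$group == group | group == "all"]
    folds <- kfold_split(ids, k, seeds[j])
    for (s in c("left", "right")) {
      res <- cv_rmse(participants, activity, s, oc, k = k, folds = folds,
                     group = group)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, side = s, mean_rmse = res$mean_rmse,
        t(stats::setNames(res$fold_rmse,
                          paste0("fold", seq_along(res$fold_rmse)))),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(c("left", "right"), function(s) {
    sub <- out[out$side == s, ]
    data.frame(outcome = "(pooled)", side = s,
               mean_rmse = mean(sub$mean_rmse),
               t(stats::setNames(rep(NA_real_, k), paste0("fold", seq_len(k)))),
               stringsAsFactors = FALSE)
  }))
  rbind(out, pooled)
}
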