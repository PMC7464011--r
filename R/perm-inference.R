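# Orthonormal basis of the column space of X; used to evaluate residual sums
# of squares for many permuted responses at once:
#   SSE(X, y) = ||y||^2 - ||Q' y||^2.
ortho_basis <- function(X) {
  qr.Q(qr(X))
}

sse_many <- function(Q, Y) {
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

# Rank check with informative error: names the columns that are linearly
# dependent on the preceding ones.
check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is singular; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(qrX)
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  Z <- as.matrix(as.data.frame(covariates))
  if (nrow(Z) != n) stop("covariates must have one row per observation")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("cov", seq_len(ncol(Z)))
  storage.mode(Z) <- "double"
  Z
}

#' Eta-squared effect size
#'
#' The ratio of the effect sum of squares to the total sum of squares.
#'
#' @param ss_effect effect sum of squares, `0 <= ss_effect <= ss_total`.
#' @param ss_total total sum of squares, > 0.
#' @return numeric in \[0, 1\].
#' @export
eta_squared <- function(ss_effect, ss_total) {
  if (!is.finite(ss_total) || ss_total <= 0) stop("`ss_total` must be > 0")
  if (!is.finite(ss_effect) || ss_effect < 0 || ss_effect > ss_total + 1e-12) {
    stop("`ss_effect` must lie in [0, ss_total]")
  }
  min(1, ss_effect / ss_total)
}

#' Covariate-adjusted permutation ANCOVA (Freedman-Lane)
#'
#' Tests a two-level group effect on `y` adjusting for covariates. The
#' observed statistic is the classical partial F comparing the full model
#' (intercept + covariates + group) against the reduced model (intercept +
#' covariates). The permutation null follows the Freedman-Lane scheme:
#' residuals of the reduced model are permuted, added back to the reduced
#' fit, and the partial F recomputed, so the nuisance (covariate) structure
#' is preserved under permutation. With no covariates the permutation
#' distribution collapses onto the `choose(n, n1)` distinct group
#' relabellings; when that count is at most `n_perm` it is enumerated
#' exhaustively and the p-value is exact.
#'
#' @param y numeric response.
#' @param group two-level factor/character vector.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param n_perm number of Monte-Carlo permutations (default 10000).
#' @param seed integer seed (required for the Monte-Carlo path).
#' @param outcome optional label stored on the result.
#' @return A `perm_test`: `F`, `df_effect`, `df_resid`, `eta2`, `p_perm`,
#'   `exact`, `n_perm`, `outcome`.
#' @export
ancova_permutation <- function(y, group, covariates = NULL, n_perm = 10000,
                               seed = NULL, outcome = NA_character_) {
  n <- length(y)
  if (!all(is.finite(y))) stop("`y` must be finite")
  g <- factor(group)
  if (nlevels(g) != 2) stop("`group` must have exactly 2 levels")
  Z <- as_covariate_matrix(covariates, n)
  gx <- as.numeric(g == levels(g)[2])
  Xr <- cbind("(Intercept)" = rep(1, n), Z)
  Xf <- cbind(Xr, group = gx)
  if (n < ncol(Xf) + 2) stop("too few observations for the design")
  check_full_rank(Xf)

  Qf <- ortho_basis(Xf)
  Qr <- ortho_basis(Xr)
  sse_f <- sum(y^2) - sum(crossprod(Qf, y)^2)
  sse_r <- sum(y^2) - sum(crossprod(Qr, y)^2)
  df_resid <- n - ncol(Xf)
  ss_group <- max(0, sse_r - sse_f)
  F_obs <- (ss_group / 1) / (sse_f / df_resid)
  ss_total <- sum((y - mean(y))^2)
  eta2 <- if (ss_total > 0) eta_squared(min(ss_group, ss_total), ss_total) else 0
  tol <- 1e-8 * max(1, abs(F_obs))

  n1 <- sum(g == levels(g)[1])
  n_distinct <- suppressWarnings(choose(n, n1))
  if (is.null(Z) && is.finite(n_distinct) && n_distinct <= n_perm) {
    # Exhaustive: every distinct assignment of n1 labels to n positions.
    idx <- utils::combn(n, n1)
    ybar <- mean(y)
    n0 <- n - n1
    F_all <- apply(idx, 2, function(s) {
      m1 <- mean(y[s]); m0 <- mean(y[-s])
      ssb <- n1 * (m1 - ybar)^2 + n0 * (m0 - ybar)^2
      (ssb / 1) / ((ss_total - ssb) / (n - 2))
    })
    p_perm <- mean(F_all >= F_obs - tol)
    exact <- TRUE
    n_used <- ncol(idx)
  } else {
    if (is.null(seed)) stop("`seed` is required for Monte-Carlo permutation")
    fitted_r <- as.numeric(Qr %*% crossprod(Qr, y)) # reduced-model fit
    e_r <- y - fitted_r
    Ystar <- with_seed(seed, {
      E <- vapply(seq_len(n_perm), function(b) e_r[sample.int(n)], numeric(n))
      fitted_r + E
    })
    sse_f_star <- sse_many(Qf, Ystar)
    sse_r_star <- sse_many(Qr, Ystar)
    F_star <- pmax(0, sse_r_star - sse_f_star) / (sse_f_star / df_resid)
    p_perm <- (sum(F_star >= F_obs - tol) + 1) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }

  structure(
    list(outcome = outcome, F = F_obs, df_effect = 1L, df_resid = df_resid,
         eta2 = eta2, p_perm = p_perm, exact = exact, n_perm = n_used,
         n = n),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "permutation ANCOVA%s: F(%d, %d) = %.3f, eta2 = %.3f, p_perm = %.4g%s\n",
    if (is.na(x$outcome)) "" else paste0(" [", x$outcome, "]"),
    x$df_effect, x$df_resid, x$F, x$eta2, x$p_perm,
    if (x$exact) " (exact)" else sprintf(" (%d permutations)", x$n_perm)
  ))
  invisible(x)
}

# z-score columns that are genuinely continuous; binary indicator columns
# (two distinct values) are left on their original coding.
standardize_columns <- function(M) {
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (length(unique(v)) > 2) {
      s <- stats::sd(v)
      M[, j] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
  }
  M
}

#' Permutation multiple regression with a standardized focal coefficient
#'
#' Fits `response ~ predictor + covariates` by least squares after z-scoring
#' all continuous variables (binary covariates such as a sex indicator keep
#' their coding), and tests the focal predictor with a two-sided
#' Freedman-Lane permutation test: residuals of the covariates-only model
#' are permuted and the focal partial F (= t^2) recomputed.
#'
#' @param response numeric response vector.
#' @param predictor numeric focal predictor; must have positive variance.
#' @param covariates optional matrix/data.frame of covariates.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param direction label recording which analysis direction the call
#'   represents (`"change_on_brain"`: cognitive change regressed on brain
#'   activity; `"brain_on_change"`: the transposed model). The caller passes
#'   the variables accordingly; the label is stored on the result.
#' @param outcome,side optional labels stored on the result.
#' @return A `perm_regression`: `beta_std`, `t`, `p_perm`, `n`, `direction`.
#' @export
perm_regression <- function(response, predictor, covariates = NULL,
                            n_perm = 10000, seed = NULL,
                            direction = c("change_on_brain", "brain_on_change"),
                            outcome = NA_character_, side = NA_character_) {
  direction <- match.arg(direction)
  n <- length(response)
  if (length(predictor) != n) stop("`response` and `predictor` lengths differ")
  if (!all(is.finite(response)) || !all(is.finite(predictor))) {
    stop("inputs must be finite")
  }
  if (stats::var(predictor) == 0) stop("`predictor` has zero variance")
  Z <- as_covariate_matrix(covariates, n)

  M <- cbind(.y = response, .x = predictor, Z)
  M <- standardize_columns(M)
  yz <- M[, 1]
  xz <- M[, 2]
  Zz <- if (is.null(Z)) NULL else M[, -(1:2), drop = FALSE]

  Xr <- cbind("(Intercept)" = rep(1, n), Zz)
  Xf <- cbind(Xr, predictor = xz)
  if (n < ncol(Xf) + 2) stop("too few observations for the design")
  check_full_rank(Xf)

  fit <- stats::lm.fit(Xf, yz)
  p_full <- ncol(Xf)
  df_resid <- n - p_full
  beta <- unname(fit$coefficients["predictor"])
  sse_f <- sum(fit$residuals^2)
  sigma2 <- sse_f / df_resid
  XtXinv <- chol2inv(chol(crossprod(Xf)))
  se <- sqrt(sigma2 * XtXinv[p_full, p_full])
  t_obs <- if (se > 0) beta / se else sign(beta) * Inf
  F_obs <- t_obs^2

  Qf <- ortho_basis(Xf)
  Qr <- ortho_basis(Xr)
  sse_r <- sum(yz^2) - sum(crossprod(Qr, yz)^2)
  if (is.null(seed)) stop("`seed` is required")
  fitted_r <- as.numeric(Qr %*% crossprod(Qr, yz))
  e_r <- yz - fitted_r
  Ystar <- with_seed(seed, {
    E <- vapply(seq_len(n_perm), function(b) e_r[sample.int(n)], numeric(n))
    fitted_r + E
  })
  sse_f_star <- sse_many(Qf, Ystar)
  sse_r_star <- sse_many(Qr, Ystar)
  F_star <- pmax(0, sse_r_star - sse_f_star) / (sse_f_star / df_resid)
  tol <- if (is.finite(F_obs)) 1e-8 * max(1, F_obs) else 0
  p_perm <- (sum(F_star >= F_obs - tol) + 1) / (n_perm + 1)

  structure(
    list(outcome = outcome, side = side, beta_std = beta, t = t_obs,
         p_perm = p_perm, n = n, direction = direction, n_perm = n_perm),
    class = "perm_regression"
  )
}

#' @export
print.perm_regression <- function(x, ...) {
  cat(sprintf(
    "permutation regression%s%s (%s): standardized beta = %.3f, t = %.3f, p_perm = %.4g\n",
    if (is.na(x$outcome)) "" else paste0(" [", x$outcome, "]"),
    if (is.na(x$side)) "" else paste0(" ", x$side),
    x$direction, x$beta_std, x$t, x$p_perm
  ))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `p_adj_(i) = min_{j >= i} min(1, m * p_(j) / j)`. Adjusted values are
#' monotone in the input order and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!all(is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}
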