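test_that("change scores are post minus pre with validation", {
  expect_equal(change_scores(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(change_scores(10, 14), 4)
  co <- make_cohort(10, effect_config(), seed = 2)$participants
  bt <- co[co$group == "BT", ]
  d <- change_scores(bt$Cd_pre, bt$Cd_post)
  expect_equal(mean(d), mean(bt$Cd_post) - mean(bt$Cd_pre), tolerance = 1e-12)
  expect_error(change_scores(1:3, 1:2), "differ")
  expect_error(change_scores(c(1, NA), c(1, 2)), "finite")
})

test_that("group-invariant response gives F = 0 and p = 1", {
  y <- rep(c(5, 6, 7), 4) # identical pattern in both groups
  g <- rep(c("BT", "ACT"), each = 6)
  res <- ancova_permutation(y, g, n_perm = 200, seed = 1)
  expect_equal(res$F, 0, tolerance = 1e-10)
  expect_equal(res$p_perm, 1)
})

test_that("trial-sized ANCOVA with pre, age, sex has 1 and 67 df", {
  set.seed(31)
  y <- rnorm(72)
  g <- rep(c("BT", "ACT"), 36)
  covs <- cbind(pre = rnorm(72), age = rnorm(72, 21), sexM = rbinom(72, 1, 0.5))
  res <- ancova_permutation(y, g, covs, n_perm = 99, seed = 5)
  expect_equal(res$df_effect, 1L)
  expect_equal(res$df_resid, 67L)
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  for (s in 1:5) {
    set.seed(s)
    n1 <- sample(2:4, 1)
    n2 <- sample(2:4, 1)
    y <- rnorm(n1 + n2)
    g <- rep(c("A", "B"), c(n1, n2))
    res <- ancova_permutation(y, g, n_perm = 1000)
    expect_true(res$exact)
    # independent oracle: every assignment of n1 'A' labels, F via lm/anova
    n <- n1 + n2
    idx <- combn(n, n1)
    F_all <- apply(idx, 2, function(ss) {
      gg <- rep("B", n)
      gg[ss] <- "A"
      stats::anova(stats::lm(y ~ factor(gg)))$`F value`[1]
    })
    F_obs <- stats::anova(stats::lm(y ~ factor(g)))$`F value`[1]
    expect_equal(res$p_perm, mean(F_all >= F_obs - 1e-8), tolerance = 1e-12)
    expect_equal(res$n_perm, ncol(idx))
  }
})

test_that("observed F matches the independent two-model SS oracle", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(20:60, 1)
    y <- rnorm(n)
    g <- sample(rep(c("A", "B"), length.out = n))
    covs <- cbind(c1 = rnorm(n), c2 = rnorm(n))
    res <- ancova_permutation(y, g, covs, n_perm = 50, seed = s)
    expect_equal(res$F, classical_partial_F(y, g, covs), tolerance = 1e-10)
  }
})

test_that("singular designs fail naming the collinear columns", {
  y <- rnorm(20)
  g <- rep(c("A", "B"), 10)
  covs <- cbind(a = 1:20, b = 2 * (1:20))
  expect_error(ancova_permutation(y, g, covs, n_perm = 10, seed = 1),
               "collinear.*b")
})

test_that("eta squared follows the SS decomposition", {
  expect_equal(eta_squared(0, 10), 0)
  expect_equal(eta_squared(10, 10), 1)
  # toy one-way layout {1,2,3} vs {4,5,6}: SSB 13.5, SST 17.5
  y <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  a <- stats::anova(stats::lm(y ~ g))
  expect_equal(eta_squared(a$`Sum Sq`[1], sum(a$`Sum Sq`)), 13.5 / 17.5)
  res <- ancova_permutation(y, g, n_perm = 30)
  expect_equal(res$eta2, 13.5 / 17.5, tolerance = 1e-10)
  expect_error(eta_squared(1, 0), "ss_total")
  expect_error(eta_squared(-1, 5), "ss_effect")
})

test_that("a perfect predictor yields beta_std 1 at the minimal p", {
  set.seed(9)
  x <- rnorm(30)
  res <- perm_regression(x, x, n_perm = 500, seed = 2)
  expect_equal(res$beta_std, 1, tolerance = 1e-10)
  expect_equal(res$p_perm, 1 / 501)
  expect_equal(sign(res$beta_std), sign(res$t))
})

test_that("beta_std equals the correlation when there are no covariates", {
  set.seed(77)
  x <- rnorm(10)
  y <- 0.5 * x + rnorm(10)
  res <- perm_regression(y, x, n_perm = 100, seed = 3)
  expect_equal(res$beta_std, unname(cor(x, y)), tolerance = 1e-10)
  expect_error(perm_regression(y, rep(1, 10), n_perm = 10, seed = 1),
               "variance")
})

test_that("null permutation regression rejects at close to nominal level", {
  rej <- vapply(1:1000, function(i) {
    set.seed(2000 + i)
    y <- rnorm(40)
    x <- rnorm(40)
    perm_regression(y, x, n_perm = 500, seed = i)$p_perm <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.036)
  expect_lte(mean(rej), 0.064)
})

test_that("permutation p-values are seed-reproducible and seed-stable", {
  set.seed(55)
  y <- rnorm(40)
  g <- rep(c("A", "B"), 20)
  covs <- cbind(age = rnorm(40))
  a <- ancova_permutation(y, g, covs, n_perm = 1000, seed = 42)
  b <- ancova_permutation(y, g, covs, n_perm = 1000, seed = 42)
  expect_identical(a, b)
  # changing only the seed moves p by no more than Monte-Carlo error
  c2 <- ancova_permutation(y, g, covs, n_perm = 1000, seed = 43)
  se <- sqrt(a$p_perm * (1 - a$p_perm) / 1000)
  expect_lt(abs(a$p_perm - c2$p_perm), 6 * se + 2 / 1001)
})

test_that("BH adjustment matches hand computation and stays in range", {
  expect_equal(fdr_adjust(0.3), 0.3)
  # hand step-up: m * p_(i) / i = .04 .04 .04 .04, cummin from top = .04
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  # order preservation: adjusted values never cross the input ranking
  p <- c(0.2, 0.01, 0.9, 0.04)
  adj <- fdr_adjust(p)
  expect_equal(order(adj), order(p))
  expect_true(all(adj >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches the reference step-up on 1000 random vectors", {
  set.seed(123)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- runif(m)
    expect_equal(fdr_adjust(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("analysis tables carry FDR-adjusted p-values per family", {
  co <- make_cohort(12, effect_config(), seed = 6)
  act <- amplitude_activity(co)
  base <- baseline_activity_ancova(co$participants, act, n_perm = 199,
                                   seed = 8)
  expect_equal(nrow(base), 2)
  expect_true(all(base$p_adjusted >= base$p_perm))
  expect_equal(base$p_adjusted, fdr_adjust(base$p_perm))

  ch <- change_score_ancova(co$participants, n_perm = 199, seed = 9)
  expect_equal(nrow(ch), 11)
  expect_equal(ch$outcome, outcome_names())
  expect_true(all(c("mean_BT", "sd_BT", "mean_ACT", "sd_ACT", "eta2",
                    "p_perm", "p_adjusted") %in% names(ch)))

  reg <- activity_change_regression(co$participants, act, n_perm = 199,
                                    seed = 10)
  expect_equal(nrow(reg), 22)
  expect_equal(reg$p_adjusted, fdr_adjust(reg$p_perm))
  expect_true(all(sign(reg$beta_std) == sign(reg$t)))
})

test_that("both regression directions are available and transpose the model", {
  co <- make_cohort(15, effect_config(), seed = 16)
  act <- amplitude_activity(co)
  fwd <- activity_change_regression(co$participants, act, outcomes = "Cd",
                                    direction = "change_on_brain",
                                    n_perm = 199, seed = 3)
  rev <- activity_change_regression(co$participants, act, outcomes = "Cd",
                                    direction = "brain_on_change",
                                    n_perm = 199, seed = 3)
  expect_equal(unique(fwd$direction), "change_on_brain")
  expect_equal(unique(rev$direction), "brain_on_change")
  # with covariates the two standardized slopes differ in general
  expect_false(isTRUE(all.equal(fwd$beta_std, rev$beta_std)))
})
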