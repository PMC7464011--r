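test_that("blocked randomization forces 1:1 within complete blocks", {
  p4 <- data.frame(id = letters[1:4], sex = rep("M", 4))
  for (s in 1:25) {
    g <- stratified_block_randomize(p4, block_size = 4, seed = s)
    expect_equal(sum(g == "BT"), 2)
    expect_equal(sum(g == "ACT"), 2)
  }
  expect_error(stratified_block_randomize(p4, block_size = 3, seed = 1),
               "even")
  expect_error(stratified_block_randomize(p4[, "id", drop = FALSE], seed = 1))
})

test_that("a 48M + 24F cohort with block size 4 splits 36/36 for every seed", {
  p <- data.frame(id = sprintf("x%02d", 1:72),
                  sex = rep(c("M", "F"), c(48, 24)))
  for (s in 1:60) {
    g <- stratified_block_randomize(p, block_size = 4, seed = s)
    expect_equal(unname(table(g)["BT"]), 36)
    expect_equal(unname(table(g)["ACT"]), 36)
  }
})

test_that("an incomplete final block leaves arm counts within 1", {
  p5 <- data.frame(id = letters[1:5], sex = rep("F", 5))
  for (s in 1:200) {
    g <- stratified_block_randomize(p5, block_size = 4, seed = s)
    # first complete block is exactly 2:2
    expect_equal(sum(g[1:4] == "BT"), 2)
    expect_lte(abs(sum(g == "BT") - sum(g == "ACT")), 1)
  }
  # deterministic in the seed
  expect_identical(stratified_block_randomize(p5, seed = 7),
                   stratified_block_randomize(p5, seed = 7))
})

test_that("randomization balance bound holds across strata", {
  for (s in 1:40) {
    set.seed(s)
    n_m <- sample(3:30, 1)
    n_f <- sample(3:30, 1)
    p <- data.frame(id = sprintf("i%02d", seq_len(n_m + n_f)),
                    sex = rep(c("M", "F"), c(n_m, n_f)))
    g <- stratified_block_randomize(p, block_size = 4, seed = s + 1000)
    expect_lte(abs(sum(g == "BT") - sum(g == "ACT")), 2 * 4 / 2)
  }
})

test_that("cohort with all effects and noise silenced has post == pre", {
  co <- make_cohort(5, zero_noise_config(), seed = 3)
  for (oc in outcome_names()) {
    expect_equal(co$participants[[paste0(oc, "_post")]],
                 co$participants[[paste0(oc, "_pre")]])
  }
})

test_that("rho = 1 with no residual noise gives perfect brain-change correlation", {
  oc <- flat_outcomes(change_sd = 2)
  oc$rho_left[oc$outcome == "Cd"] <- 1
  cfg <- effect_config(outcomes = oc, amp_mean = c(BT = 1, ACT = 1),
                       amp_sdlog = 0.4,
                       mayer_amp = 0, cardiac_amp = 0, ar_sd = 0,
                       coupling_sd = 0, drift_sd = 0, noise_sd = 0)
  co <- make_cohort(12, cfg, seed = 5)
  ch <- change_scores(co$participants$Cd_pre, co$participants$Cd_post)
  expect_equal(cor(co$amplitudes$left, ch), 1, tolerance = 1e-12)
})

test_that("configured BT-ACT change difference is recovered across seeds", {
  # Monte-Carlo oracle: mean arm contrast over 200 seeded cohorts at the
  # default Cd difference of 3.8 score units.
  d <- vapply(1:200, function(s) {
    p <- make_cohort(36, effect_config(), seed = s)$participants
    ch <- p$Cd_post - p$Cd_pre
    mean(ch[p$group == "BT"]) - mean(ch[p$group == "ACT"])
  }, numeric(1))
  expect_lt(abs(mean(d) - 3.8), 0.2)
})

test_that("cohort generation is byte-identical for identical seeds", {
  a <- make_cohort(8, effect_config(), seed = 11)
  b <- make_cohort(8, effect_config(), seed = 11)
  c2 <- make_cohort(8, effect_config(), seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$participants, c2$participants))
})

test_that("invalid effect configurations are rejected", {
  oc <- flat_outcomes()
  oc$change_sd <- -1
  expect_error(effect_config(outcomes = oc), "SD")
  oc <- flat_outcomes(rho_left = 0.9, rho_right = 0.9)
  expect_error(effect_config(outcomes = oc), "rho")
  expect_error(make_cohort(1, effect_config(), seed = 1), ">= 2")
})

test_that("hrf starts at zero, peaks near 5 s and integrates positively", {
  expect_equal(hrf(0), 0)
  tt <- seq(0, 30, by = 0.01)
  h <- hrf(tt)
  peak_t <- tt[which.max(h)] # grid-search oracle
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 7)
  # trapezoid quadrature oracle
  integral <- sum((h[-1] + h[-length(h)]) / 2) * 0.01
  expect_gt(integral, 0)
  expect_error(hrf(-1), "non-negative")
})

test_that("silent recording is identically zero; zero-noise recording is the
           convolved boxcar", {
  sch <- default_schedule()
  cfg <- zero_noise_config()
  r0 <- simulate_recording(0, 10, sch, cfg, seed = 1)
  expect_true(all(r0$deep == 0))
  expect_true(all(r0$shallow == 0))

  r1 <- simulate_recording(1, 5, sch, cfg, seed = 1)
  # direct O(n^2) convolution-sum oracle, unit-peak normalized
  fs <- 5
  n <- length(r1$deep)
  t <- (seq_len(n) - 1) / fs
  box <- as.numeric((t >= 30 & t < 60) | (t >= 90 & t < 120))
  conv <- vapply(seq_len(n), function(k) {
    j <- seq_len(k)
    sum(box[j] * hrf((k - j) / fs)) / fs
  }, numeric(1))
  conv <- conv / max(abs(conv))
  expect_equal(r1$deep, conv, tolerance = 1e-8)
  game_max <- max(r1$deep[t >= 30 & t < 60])
  rest1_max <- max(r1$deep[t < 30])
  expect_gt(game_max, rest1_max)
})

test_that("shared systemic physiology couples shallow and deep channels", {
  cfg <- effect_config()
  sch <- default_schedule()
  cors <- vapply(1:100, function(s) {
    r <- simulate_recording(1, 10, sch, cfg, seed = s)
    cor(r$shallow, r$deep)
  }, numeric(1))
  expect_gt(mean(cors), 0.3)
})

test_that("recording constructor and simulator validate their inputs", {
  sch <- default_schedule()
  expect_error(simulate_recording(1, -1, sch, effect_config(), seed = 1),
               "positive")
  expect_error(simulate_recording(1, 10, "nope", effect_config(), seed = 1))
  expect_error(nirs_recording("a", "left", 10, 1:5, 1:4, sch), "equal length")
  expect_error(block_schedule(c("game", "rest"), c(30, 30)), "begin and end")
  expect_error(block_schedule(c("rest", "rest"), c(30, 30)), "alternate")
})

test_that("latent parameters are exactly recoverable when noise vanishes", {
  oc <- flat_outcomes(act_change = 1, bt_minus_act = 2)
  cfg <- zero_noise_config(outcomes = oc)
  co <- make_cohort(6, cfg, seed = 9)
  ch <- change_scores(co$participants$SS_pre, co$participants$SS_post)
  expect_equal(ch, ifelse(co$participants$group == "BT", 3, 1))
  # recording peak recovers the amplitude exactly (unit-peak regressor)
  r <- simulate_recording(0.73, 10, default_schedule(), cfg, seed = 2)
  expect_equal(max(r$deep), 0.73, tolerance = 1e-12)
})

test_that("cohort and recording round-trip through CSV/JSON on disk", {
  co <- make_cohort(4, effect_config(), seed = 21)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "participants.csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(back$id, co$participants$id)
  expect_equal(back$Cd_pre, co$participants$Cd_pre, tolerance = 1e-10)

  recs <- simulate_cohort_recordings(co, fs = 5,
                                     schedule = default_schedule())[1:4]
  write_recordings(recs, tmp)
  back_recs <- read_recordings(tmp)
  expect_equal(length(back_recs), 4)
  orig <- recs[[1]]
  match_rec <- Filter(function(r) r$id == orig$id && r$side == orig$side,
                      back_recs)[[1]]
  expect_equal(match_rec$deep, orig$deep, tolerance = 1e-10)
  expect_equal(match_rec$true_amplitude, orig$true_amplitude,
               tolerance = 1e-10)
})
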