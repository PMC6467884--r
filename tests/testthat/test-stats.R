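test_that("accuracy is cleared over included trials, honouring the mask", {
  log <- fake_log(c(rep("cleared", 13), rep("failed", 3)))
  expect_identical(accuracy(log), 0.8125)
  expect_identical(accuracy(fake_log(rep("cleared", 16))), 1)
  # excluding 5 trials, all 11 remaining cleared
  log2 <- fake_log(c(rep("cleared", 11), rep("failed", 5)), excluded = 12:16)
  expect_identical(accuracy(log2), 1)
  expect_error(accuracy(fake_log("cleared", excluded = 1L)), "no included")
})

test_that("the one-sided binomial tail matches exact summation", {
  expect_equal(binomial_test(16, 16), 1 / 65536)
  oracle <- sum(choose(16, 8:16)) / 2^16
  expect_equal(binomial_test(8, 16), oracle)
  expect_equal(binomial_test(0, 16), 1)
})

test_that("the epoch-power comparison is signed and antisymmetric", {
  x <- c(5, 6, 7, 8); y <- c(1, 2, 1.5, 2.5)
  res <- power_comparison(x, y)
  expect_gt(res$t, 0)
  expect_equal(power_comparison(y, x)$t, -res$t)
  same <- power_comparison(c(1, 1), c(1, 1))
  expect_equal(same$t, 0)
})

test_that("high-SNR task epochs beat idle epochs on 17 Hz power", {
  cfg <- decoder_config()
  p17 <- function(rec) vapply(epochs(bandlimit(rec, cfg), cfg), function(e)
    bbisim:::psd_at(welch_power(e, cfg), 17), numeric(1))
  task <- unlist(lapply(1:4, function(s)
    p17(generate_ssvep(ssvep_spec(17, snr = 4, seed = s), 10, 250))))
  idle <- unlist(lapply(1:4, function(s)
    p17(generate_idle(10, 250, seed = 100 + s))))
  res <- power_comparison(task, idle)
  expect_gt(res$t, 0)
  expect_lt(res$p, 0.01)
})

test_that("single-point AUC spans the ideal, chance and complement cases", {
  truth <- rep(c(0L, 1L), 8)
  expect_equal(roc_single_point(truth, truth)$auc, 1)
  expect_equal(roc_single_point(1L - truth, truth)$auc, 0)
  # tpr 0.9, fpr 0.4 -> trapezoid through (0,0), (0.4, 0.9), (1,1)
  truth2 <- c(rep(1L, 10), rep(0L, 10))
  dec2 <- c(rep(1L, 9), 0L, rep(1L, 4), rep(0L, 6))
  r <- roc_single_point(dec2, truth2)
  expect_equal(c(r$tpr, r$fpr), c(0.9, 0.4))
  trap <- 0.4 * 0.9 / 2 + (1 - 0.4) * (0.9 + 1) / 2
  expect_equal(r$auc, trap)
  expect_error(roc_single_point(truth, rep(1L, 16)), "single class")
})

test_that("AUC is antisymmetric under complementing the decisions", {
  set.seed(4)
  for (i in 1:20) {
    truth <- rbinom(30, 1, 0.5)
    if (length(unique(truth)) < 2) next
    dec <- rbinom(30, 1, 0.5)
    expect_equal(roc_single_point(1L - dec, truth)$auc,
                 1 - roc_single_point(dec, truth)$auc)
  }
})

test_that("the angular transform hits its closed-form anchors and is increasing", {
  expect_equal(angular_transform(0), 0)
  expect_equal(angular_transform(1), pi / 2)
  expect_equal(angular_transform(0.5), pi / 4)
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(angular_transform(x)) > 0))
  expect_error(angular_transform(1.1), "0, 1")
})

test_that("transformed tests reproduce the V = 15 signed-rank anchor", {
  aucs <- c(0.81, 0.94, 0.72, 0.88, 0.79)   # five values all above chance
  res <- transformed_tests(aucs, reference = 0.5)
  expect_equal(res$wilcoxon$statistic, 15)
  expect_lt(res$t_test$p, 0.05)
  same <- transformed_tests(c(0.5, 0.5, 0.5), reference = 0.5)
  expect_true(same$degenerate)
  expect_equal(same$t_test$statistic, 0)
})

test_that("design-level AUCs are detected above chance in most simulated groups", {
  hits <- vapply(1:20, function(rep) {
    logs <- lapply(1:5, function(i)
      run_session(make_session_plan(rep * 31 + i), seed = rep * 97 + i,
                  simulate_eeg = FALSE))
    aucs <- vapply(evaluate(logs)$roc$triad, `[[`, numeric(1), "auc")
    transformed_tests(aucs, reference = 0.5)$t_test$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("MI hits its limits and matches brute force on a skew joint", {
  r <- rep(c(0L, 1L), 16)
  expect_identical(mutual_information(r, r)$mi, 1)
  ind <- counts_to_vectors(matrix(c(8, 8, 8, 8), 2))
  expect_identical(mutual_information(ind$r, ind$s)$mi, 0)
  skew <- matrix(c(12, 4, 4, 12), 2)
  v <- counts_to_vectors(skew)
  expect_equal(mutual_information(v$r, v$s)$mi, mi_oracle(skew))
  expect_error(mutual_information(c(0L, 1L), c(1L)), "length")
})

test_that("MI is symmetric and bounded on random binary pairs", {
  set.seed(11)
  for (i in 1:50) {
    r <- rbinom(32, 1, runif(1, 0.2, 0.8))
    s <- rbinom(32, 1, runif(1, 0.2, 0.8))
    a <- mutual_information(r, s)$mi
    expect_equal(a, mutual_information(s, r)$mi)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("the MI bias approximation evaluates the printed formula", {
  expect_equal(round(mi_bias(2, 32), 3), -0.045)
  expect_equal(mi_bias(2, 32), -2 / (2 * 32 * log(2)))
  expect_equal(mi_bias(2, 16), -2 / (32 * log(2)))
  expect_lt(abs(mi_bias(2, 1e9)), 1e-8)
})

test_that("the pseudoinverse beta matches hand least squares and a generic solver", {
  expect_equal(block_beta(c(1, 1, 0, 1), c(1, 0, 0, 1)), 1)
  r <- c(1, 0, 1, 0); s <- c(0, 1, 0, 1)
  expect_equal(block_beta(r, s), 0)
  expect_equal(block_beta(s, s), 1)
  set.seed(21)
  for (i in 1:100) {
    r <- rbinom(20, 1, 0.5); s <- rbinom(20, 1, 0.5)
    if (all(s == 0)) next
    fit <- stats::lm.fit(matrix(as.numeric(s)), as.numeric(r))
    expect_equal(block_beta(r, s), unname(fit$coefficients))
  }
  expect_error(block_beta(c(1, 0), c(0, 0)), "all zero")
})

test_that("block correlation matches its closed-form anchors", {
  s <- c(1, 0, 1, 0)
  expect_equal(block_correlation(s, s), 1)
  expect_equal(block_correlation(1 - s, s), -1)
  expect_equal(block_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_error(block_correlation(c(1, 1), c(1, 1)), "constant")
})

test_that("the slope-difference Z matches textbook OLS and is antisymmetric", {
  g <- c(0.12, 0.28, 0.55, 0.66)
  b <- c(0.22, 0.18, 0.25, 0.19)
  res <- trend_z(g, b)
  ols <- function(y) {   # closed-form simple regression oracle
    x <- 1:4; bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    resid <- y - (mean(y) - bx * mean(x)) - bx * x
    se <- sqrt(sum(resid^2) / 2 / sum((x - mean(x))^2))
    c(bx, se)
  }
  og <- ols(g); ob <- ols(b)
  expect_equal(res$beta_good, og[1]); expect_equal(res$se_good, og[2])
  expect_equal(res$z, (og[1] - ob[1]) / sqrt(og[2]^2 + ob[2]^2))
  expect_equal(trend_z(b, g)$z, -res$z)
  expect_equal(trend_z(g, g)$z, 0)
})

test_that("evaluating ideal sessions gives the perfect-communication limits", {
  logs <- lapply(1:3, function(i) ideal_session(seed = i))
  res <- evaluate(logs)
  expect_equal(res$mean_accuracy, 1)
  expect_equal(res$mean_auc$triad, 1)
  expect_equal(res$mean_auc$good, 1)
  # Receiver == good Sender in every round, so MI is the entropy of the
  # shared decision vector: 8 rotations in 32 trial x round samples
  # (round 2 after a correct round 1 is always "do not rotate")
  expect_equal(res$mean_mi$good, -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_lt(res$mean_auc$bad, 0.7)
  expect_gt(res$mean_mi$good, res$mean_mi$bad)
})

test_that("an empty exclusion mask changes nothing", {
  logs <- lapply(1:2, function(i)
    run_session(make_session_plan(i), seed = i, simulate_eeg = FALSE))
  res1 <- evaluate(logs)
  logs2 <- lapply(logs, function(l) { l$excluded_flag <- FALSE; l })
  expect_equal(evaluate(logs2), res1)
})

test_that("masked trials are dropped from every statistic", {
  log <- run_session(make_session_plan(4), seed = 4, simulate_eeg = FALSE)
  log$excluded_flag <- log$trial %in% 8:12
  res <- evaluate(list(log,
    run_session(make_session_plan(5), seed = 5, simulate_eeg = FALSE)))
  expect_equal(res$pooled$n, 11L + 16L)
  expect_equal(res$mi$good[[1]]$n_samples, 22L)
})
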