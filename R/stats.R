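#' Session accuracy
#'
#' Proportion of cleared trials among trials not excluded by the log's
#' exclusion mask (equivalently the proportion of correct net block
#' rotations).
#'
#' @param log A `"session_log"` from [run_session()] or
#'   [read_session_log()].
#' @return Proportion in \[0, 1\].
#' @export
accuracy <- function(log) {
  final <- log[log$round == 2L & !log$excluded_flag, ]
  if (nrow(final) == 0L) stop("no included resolved trials in this log")
  mean(final$outcome == "cleared")
}

#' One-sided exact binomial test
#'
#' Upper-tail probability of at least `successes` successes in `n`
#' Bernoulli trials with success probability `p0`, i.e. the p-value for
#' performance above chance.
#'
#' @param successes,n Counts with `0 <= successes <= n`.
#' @param p0 Null success probability (0.5).
#' @return The exact p-value.
#' @export
#' @examples
#' binomial_test(16, 16)  # 1 / 65536
binomial_test <- function(successes, n, p0 = 0.5) {
  stopifnot(successes >= 0, successes <= n)
  stats::pbinom(successes - 1, n, p0, lower.tail = FALSE)
}

#' Compare epoch powers at the correct vs incorrect frequency
#'
#' Two-sample t-test on per-epoch band powers: during the SSVEP task, the
#' power at the frequency corresponding to the correct answer should
#' exceed the power at the other target frequency. The statistic is
#' positive when the correct-frequency powers are larger.
#'
#' @param epoch_powers_correct,epoch_powers_incorrect Numeric vectors of
#'   per-epoch power values (µV²/Hz), at least 2 each.
#' @param var.equal Passed to [stats::t.test()]; pooled variance by
#'   default.
#' @return List with `t`, `df`, `p` (two-sided) and `direction`.
#' @export
power_comparison <- function(epoch_powers_correct, epoch_powers_incorrect,
                             var.equal = TRUE) {
  stopifnot(length(epoch_powers_correct) >= 2L,
            length(epoch_powers_incorrect) >= 2L)
  if (stats::sd(epoch_powers_correct) == 0 &&
      stats::sd(epoch_powers_incorrect) == 0) {
    if (all(epoch_powers_correct == epoch_powers_incorrect))
      return(list(t = 0, df = NA_real_, p = 1,
                  direction = "degenerate variance"))
    stop("degenerate (zero-variance) groups with different means")
  }
  tt <- stats::t.test(epoch_powers_correct, epoch_powers_incorrect,
                      var.equal = var.equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       direction = if (tt$statistic > 0) "correct > incorrect"
                   else "correct <= incorrect")
}

#' Single-operating-point ROC and AUC
#'
#' A binary (non-scored) classifier has one operating point; its ROC is
#' the polyline (0,0) -> (FPR, TPR) -> (1,1) and the area under it is
#' `(1 + TPR - FPR) / 2`. Random uniform responding gives 0.5 in
#' expectation; an ideal observer gives 1.
#'
#' @param decisions,truth Equal-length 0/1 vectors; `truth` must contain
#'   both classes.
#' @return An object of class `"roc_result"`: list with `tpr`, `fpr`,
#'   `auc`.
#' @export
roc_single_point <- function(decisions, truth) {
  decisions <- as.integer(decisions); truth <- as.integer(truth)
  stopifnot(length(decisions) == length(truth),
            all(decisions %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  if (length(unique(truth)) < 2L)
    stop("truth contains a single class; TPR/FPR undefined")
  tpr <- mean(decisions[truth == 1L] == 1L)
  fpr <- mean(decisions[truth == 0L] == 1L)
  structure(list(tpr = tpr, fpr = fpr, auc = (1 + tpr - fpr) / 2),
            class = "roc_result")
}

#' Angular (arcsine-square-root) transformation
#'
#' Variance-stabilizing transform for proportions, applied before
#' parametric tests on accuracy, AUC and MI values.
#'
#' @param x Proportion(s) in \[0, 1\].
#' @return `asin(sqrt(x))` in radians.
#' @export
angular_transform <- function(x) {
  if (any(x < 0 | x > 1)) stop("proportions must lie in [0, 1]")
  asin(sqrt(x))
}

#' Parametric and non-parametric tests on proportion-valued metrics
#'
#' Runs the paired pair of tests used for bounded metrics (AUC, MI): a
#' t-test on angular-transformed values and a Wilcoxon test with
#' continuity correction on the untransformed values. With a scalar
#' `reference` this is a one-sample t-test / signed-rank test against the
#' reference; with a second group it is a two-sample comparison (paired
#' when `paired = TRUE`, the natural pairing across triads).
#'
#' @param values Numeric vector of proportions (length >= 2).
#' @param reference Scalar null value, or a second vector of proportions.
#' @param paired For the two-group case, whether the groups are paired.
#' @return List with `t_test` (statistic, df, p on transformed data) and
#'   `wilcoxon` (statistic, p on raw data), plus a `degenerate` flag when
#'   all transformed differences are identical.
#' @export
transformed_tests <- function(values, reference = 0.5, paired = TRUE) {
  stopifnot(length(values) >= 2L)
  tv <- angular_transform(values)
  two_sample <- length(reference) > 1L
  degenerate <- if (two_sample) {
    tr <- angular_transform(reference)
    stats::sd(if (paired) tv - tr else c(tv - mean(tv), tr - mean(tr))) == 0
  } else stats::sd(tv) == 0
  if (degenerate) {
    # zero-variance data: the t statistic is 0 when the (mean) difference
    # from the reference is exactly 0, otherwise unbounded
    delta <- if (two_sample) {
      if (paired) mean(tv - angular_transform(reference))
      else mean(tv) - mean(angular_transform(reference))
    } else mean(tv) - angular_transform(reference)
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    return(list(t_test = list(statistic = stat, df = NA_real_, p = NA_real_),
                wilcoxon = list(statistic = NA_real_, p = NA_real_),
                degenerate = TRUE))
  }
  if (two_sample) {
    tt <- stats::t.test(tv, angular_transform(reference), paired = paired)
    wt <- suppressWarnings(stats::wilcox.test(values, reference,
                                              paired = paired, correct = TRUE))
  } else {
    tt <- stats::t.test(tv, mu = angular_transform(reference))
    wt <- suppressWarnings(stats::wilcox.test(values, mu = reference,
                                              correct = TRUE))
  }
  list(t_test = list(statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value),
       wilcoxon = list(statistic = unname(wt$statistic), p = wt$p.value),
       degenerate = FALSE)
}

#' Plug-in mutual information of two binary decision vectors
#'
#' MI in bits from the empirical 2x2 joint distribution,
#' \deqn{MI(R,S) = \sum_{r,s} p_{R,S}(r,s) \log_2
#'   \frac{p_{R,S}(r,s)}{p_R(r)\,p_S(s)},}
#' with 0 log 0 terms contributing 0. For binary variables MI lies in
#' \[0, 1\]: 0 at empirical independence (chance communication), 1 for
#' identical balanced vectors (perfect communication).
#'
#' @param r,s Equal-length 0/1 vectors (Receiver and Sender decisions).
#' @return An object of class `"mi_result"`: list with `mi` (bits),
#'   `joint_counts` (2x2 table), `n_samples` and the small-sample `bias`
#'   approximation from [mi_bias()].
#' @export
mutual_information <- function(r, s) {
  r <- as.integer(r); s <- as.integer(s)
  if (length(r) != length(s)) stop("decision vectors differ in length")
  stopifnot(length(r) >= 1L, all(r %in% c(0L, 1L)), all(s %in% c(0L, 1L)))
  n <- length(r)
  counts <- matrix(0, 2, 2, dimnames = list(r = c("0", "1"), s = c("0", "1")))
  for (i in seq_len(n)) counts[r[i] + 1L, s[i] + 1L] <- counts[r[i] + 1L, s[i] + 1L] + 1
  p_joint <- counts / n
  p_r <- rowSums(p_joint); p_s <- colSums(p_joint)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    pij <- p_joint[i, j]
    if (pij > 0) mi <- mi + pij * log2(pij / (p_r[i] * p_s[j]))
  }
  mi <- max(0, mi)  # clip tiny negative rounding residue
  structure(list(mi = mi, joint_counts = counts, n_samples = n,
                 bias = mi_bias(2, n)),
            class = "mi_result")
}

#' Small-sample bias of the plug-in MI estimate
#'
#' First-order approximation of the bias of the plug-in mutual-information
#' estimator, `b = -N_R / (2 * N_S * log(2))` bits, where `N_R` is the
#' number of possible responses and `N_S` the number of samples. For the
#' binary channel with 32 samples per participant pair this evaluates to
#' -0.045 bits.
#'
#' @param n_responses Number of possible responses `N_R` (2 for a binary
#'   decision).
#' @param n_samples Number of samples `N_S` (> 0).
#' @return The bias in bits (negative).
#' @export
#' @examples
#' mi_bias(2, 32)
mi_bias <- function(n_responses, n_samples) {
  stopifnot(n_samples > 0)
  -n_responses / (2 * n_samples * log(2))
}

#' No-intercept regression weight between two decision vectors
#'
#' The pseudoinverse least-squares weight `beta = (S'S)^{-1} S'R` for the
#' Receiver decision vector regressed on a Sender decision vector; for 0/1
#' vectors this is `sum(s * r) / sum(s^2)`.
#'
#' @param r,s Equal-length 0/1 vectors; `s` must not be all zero.
#' @return The scalar weight.
#' @export
block_beta <- function(r, s) {
  r <- as.numeric(r); s <- as.numeric(s)
  if (length(r) != length(s)) stop("decision vectors differ in length")
  if (all(s == 0)) stop("Sender vector is all zero; beta undefined (S'S singular)")
  sum(s * r) / sum(s * s)
}

#' Pearson correlation of two decision vectors
#'
#' Standard Pearson coefficient on the 0/1 encodings; undefined (and
#' rejected) when either vector is constant.
#'
#' @param r,s Equal-length, non-constant 0/1 vectors.
#' @return Correlation in \[-1, 1\].
#' @export
block_correlation <- function(r, s) {
  r <- as.numeric(r); s <- as.numeric(s)
  if (length(r) != length(s)) stop("decision vectors differ in length")
  if (stats::sd(r) == 0 || stats::sd(s) == 0)
    stop("correlation undefined for a constant decision vector")
  stats::cor(r, s)
}

#' Slope-difference Z between two learning trends
#'
#' Fits an ordinary least-squares linear trend of each metric series
#' against block number and compares the good- and bad-Sender slopes with
#' the Paternoster statistic
#' \deqn{Z = (\beta_g - \beta_b) / \sqrt{SE\beta_g^2 + SE\beta_b^2}.}
#'
#' @param metric_by_block_good,metric_by_block_bad Numeric series of the
#'   same metric over consecutive blocks (length >= 3).
#' @return An object of class `"trend_result"`: list with `beta_good`,
#'   `beta_bad`, `se_good`, `se_bad`, `z`, and a `degenerate` flag set
#'   when either fit has zero residual variance (Z is then infinite or
#'   undefined).
#' @export
trend_z <- function(metric_by_block_good, metric_by_block_bad) {
  g <- metric_by_block_good; b <- metric_by_block_bad
  stopifnot(length(g) >= 3L, length(b) >= 3L)
  fit <- function(y) {
    x <- seq_along(y)
    m <- stats::lm(y ~ x)
    cf <- suppressWarnings(summary(m))$coefficients  # exact fits warn
    list(beta = cf["x", "Estimate"], se = cf["x", "Std. Error"])
  }
  fg <- fit(g); fb <- fit(b)
  denom <- sqrt(fg$se^2 + fb$se^2)
  degenerate <- !is.finite(denom) || denom == 0
  z <- if (degenerate) {
    if (fg$beta == fb$beta) 0 else sign(fg$beta - fb$beta) * Inf
  } else (fg$beta - fb$beta) / denom
  structure(list(beta_good = fg$beta, beta_bad = fb$beta,
                 se_good = fg$se, se_bad = fb$se, z = z,
                 degenerate = degenerate),
            class = "trend_result")
}

# Transmitted-decision column for a sender type ("good"/"bad") in one log.
sender_sent_col <- function(log, type) {
  bad <- attr(log, "plan")$bad_sender
  idx <- if (type == "bad") bad else 3L - bad
  log[[paste0("s", idx, "_sent")]]
}

#' Evaluate a set of session logs
#'
#' Runs the full evaluation suite over one session log per triad:
#' \itemize{
#'   \item per-triad and pooled accuracy, with the exact one-sided binomial
#'     p-value on pooled cleared trials;
#'   \item single-point ROC/AUC per triad (net block action vs required
#'     action) and per Sender type (transmitted decision vs the
#'     state-correct action over 16 trials x 2 rounds);
#'   \item plug-in MI per Receiver-Sender pair on the 32 trial x round
#'     samples (Receiver decision vs transmitted Sender decision), with
#'     the small-sample bias;
#'   \item block-wise learning curves: Receiver round-1 decisions
#'     concatenated across triads per 4-trial block, regressed on and
#'     correlated with each Sender type's transmitted round-1 decisions,
#'     and the slope-difference Z for both measures.
#' }
#' Exclusion masks are honoured before every statistic.
#'
#' @param logs A list of `"session_log"` objects (one per triad).
#' @param n_blocks Number of consecutive trial blocks for the learning
#'   analysis (4 blocks of 4 trials).
#' @return An object of class `"triad_result"`.
#' @export
evaluate <- function(logs, n_blocks = 4L) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  stopifnot(length(logs) >= 1L)

  acc <- vapply(logs, accuracy, numeric(1))
  finals <- lapply(logs, function(l) l[l$round == 2L & !l$excluded_flag, ])
  pooled_cleared <- sum(vapply(finals, function(f) sum(f$outcome == "cleared"), numeric(1)))
  pooled_n <- sum(vapply(finals, nrow, numeric(1)))

  triad_roc <- lapply(finals, function(f) {
    # net action actually taken: equals truth iff the trial cleared
    taken <- ifelse(f$outcome == "cleared", f$truth, 1L - f$truth)
    roc_single_point(taken, f$truth)
  })

  sender_roc <- function(type) lapply(logs, function(l) {
    inc <- !l$excluded_flag
    roc_single_point(sender_sent_col(l, type)[inc], l$correct_action[inc])
  })
  mi_pair <- function(type) lapply(logs, function(l) {
    inc <- !l$excluded_flag
    mutual_information(l$receiver_decision[inc], sender_sent_col(l, type)[inc])
  })

  roc <- list(triad = triad_roc, good = sender_roc("good"), bad = sender_roc("bad"))
  mi <- list(good = mi_pair("good"), bad = mi_pair("bad"))

  # learning curves on concatenated round-1 decisions
  block_of <- function(trial) ceiling(trial / (max(vapply(logs, function(l)
    max(l$trial), numeric(1))) / n_blocks))
  curve <- function(type, measure) {
    vapply(seq_len(n_blocks), function(b) {
      r <- unlist(lapply(logs, function(l) {
        sel <- l$round == 1L & !l$excluded_flag & block_of(l$trial) == b
        l$receiver_decision[sel]
      }))
      s <- unlist(lapply(logs, function(l) {
        sel <- l$round == 1L & !l$excluded_flag & block_of(l$trial) == b
        sender_sent_col(l, type)[sel]
      }))
      if (measure == "beta") block_beta(r, s) else block_correlation(r, s)
    }, numeric(1))
  }
  learning <- list(
    beta = list(good = curve("good", "beta"), bad = curve("bad", "beta")),
    correlation = list(good = curve("good", "cor"), bad = curve("bad", "cor")))
  trend <- list(
    beta = trend_z(learning$beta$good, learning$beta$bad),
    correlation = trend_z(learning$correlation$good, learning$correlation$bad))

  structure(list(
    accuracy = acc, mean_accuracy = mean(acc),
    pooled = list(cleared = pooled_cleared, n = pooled_n,
                  binomial_p = binomial_test(pooled_cleared, pooled_n)),
    roc = roc,
    mean_auc = list(
      triad = mean(vapply(triad_roc, `[[`, numeric(1), "auc")),
      good = mean(vapply(roc$good, `[[`, numeric(1), "auc")),
      bad = mean(vapply(roc$bad, `[[`, numeric(1), "auc"))),
    mi = mi,
    mean_mi = list(good = mean(vapply(mi$good, `[[`, numeric(1), "mi")),
                   bad = mean(vapply(mi$bad, `[[`, numeric(1), "mi"))),
    mi_bias = mi_bias(2, if (length(finals) > 0) 2L * nrow(finals[[1]]) else NA_integer_),
    learning = learning, trend = trend,
    n_triads = length(logs)),
    class = "triad_result")
}

#' @export
print.triad_result <- function(x, ...) {
  cat(sprintf("<triad_result> %d triad(s)\n", x$n_triads))
  cat(sprintf("  mean accuracy %.4f (pooled %d/%d, binomial p = %.3g)\n",
              x$mean_accuracy, x$pooled$cleared, x$pooled$n, x$pooled$binomial_p))
  cat(sprintf("  mean AUC: triad %.3f, good Sender %.3f, bad Sender %.3f\n",
              x$mean_auc$triad, x$mean_auc$good, x$mean_auc$bad))
  cat(sprintf("  mean MI (bits): good %.3f, bad %.3f (bias %.3f)\n",
              x$mean_mi$good, x$mean_mi$bad, x$mi_bias))
  cat(sprintf("  learning trend Z: beta %.2f, correlation %.2f\n",
              x$trend$beta$z, x$trend$correlation$z))
  invisible(x)
}
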