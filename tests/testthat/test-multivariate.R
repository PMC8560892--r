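test_that("IRLS fit matches the closed-form 2x2 and reference glm", {
  fit <- fit_logistic(cbind(female = c(1, 1, 0, 0)), c(1, 0, 1, 0),
                      weights = c(94, 9, 43, 15))
  expect_true(fit$converged)
  expect_equal(round_half_up(exp(fit$coefficients[["female"]]), 2), 3.64)

  # independent cross-check on individual-level data
  set.seed(23)
  n <- 400
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x[, "a"] - 0.6 * x[, "b"]))
  fit <- fit_logistic(x, y)
  ref <- glm(y ~ a + b, family = binomial(), data = data.frame(x, y))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(ref))),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("log-likelihood never decreases across IRLS iterations", {
  set.seed(31)
  for (i in 1:10) {
    n <- 150
    x <- cbind(u = rnorm(n), v = runif(n))
    y <- rbinom(n, 1, plogis(rnorm(1) + x[, 1]))
    fit <- suppressWarnings(fit_logistic(x, y))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("degenerate designs are reported, not silently fitted", {
  x <- cbind(a = rnorm(50))
  expect_error(fit_logistic(x, rep(1, 50)), "no variation")
  x2 <- cbind(a = rnorm(50), b = 0)
  x2 <- cbind(x2, c = x2[, "a"] * 2)
  y <- rbinom(50, 1, 0.5)
  expect_error(fit_logistic(x2, y), "collinear")
  # perfect separation flagged
  xs <- cbind(s = c(rep(0, 20), rep(1, 20)))
  ys <- c(rep(0, 20), rep(1, 20))
  expect_warning(fs <- fit_logistic(xs, ys), "separation|converge")
  expect_true(fs$separation || !fs$converged)
})

test_that("planted coefficients are recovered with nominal CI coverage", {
  reps <- 200
  n <- 5000
  truth <- c(a = 0.5, b = -0.7)
  set.seed(202)
  est <- matrix(NA_real_, reps, 2)
  covered <- matrix(NA, reps, 2)
  for (r in seq_len(reps)) {
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
    y <- rbinom(n, 1, plogis(-0.5 + x %*% truth))
    fit <- fit_logistic(x, y)
    se <- sqrt(diag(fit$vcov))[c("a", "b")]
    est[r, ] <- fit$coefficients[c("a", "b")]
    covered[r, ] <- abs(est[r, ] - truth) < qnorm(0.975) * se
  }
  for (j in 1:2) {
    mcse <- sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - truth[j]), 2 * mcse + 1e-3)
    expect_gt(mean(covered[, j]), 0.90)
    expect_lt(mean(covered[, j]), 0.99)
  }
})

test_that("forward selection finds a planted predictor first", {
  set.seed(71)
  n <- 2000
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  y <- rbinom(n, 1, plogis(-0.2 + 1.5 * x[, "v3"]))
  sel <- forward_select(x, y)
  expect_identical(sel$selected[1], "v3")
  expect_true("v3" %in% sel$reported)
  expect_identical(sel$trace$entered[1], "v3")
})

test_that("forward selection under the null admits variables at ~alpha rate", {
  set.seed(73)
  reps <- 300
  n <- 300
  k <- 4
  admitted <- logical(reps)
  for (r in seq_len(reps)) {
    x <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("n", 1:k)))
    y <- rbinom(n, 1, 0.5)
    sel <- suppressMessages(forward_select(x, y))
    admitted[r] <- length(sel$selected) > 0
  }
  # P(any of 4 independent nulls enters at 0.05) ~ 1 - 0.95^4 = 0.185
  expect_gt(mean(admitted), 0.10)
  expect_lt(mean(admitted), 0.28)
})

test_that("empty candidate set returns an intercept-only fit", {
  y <- rbinom(40, 1, 0.5)
  x <- matrix(numeric(0), 40, 0)
  expect_message(sel <- forward_select(x, y), "intercept-only")
  expect_length(sel$selected, 0)
  expect_identical(names(sel$fit$coefficients), "(Intercept)")
})

test_that("Hosmer-Lemeshow matches a hand-computed 3-group toy", {
  # groups engineered through distinct fitted values
  fitted <- c(rep(0.2, 4), rep(0.5, 4), rep(0.8, 4))
  y <- c(1, 0, 0, 0,   1, 1, 0, 0,   1, 1, 1, 0)
  hl <- hosmer_lemeshow(fitted, y, n_groups = 3)
  # per group: O = 1, 2, 3; E = 0.8, 2.0, 3.2; n = 4
  hand <- (1 - 0.8)^2 / (0.8 * (1 - 0.8 / 4)) +
    (2 - 2)^2 / (2 * (1 - 2 / 4)) +
    (3 - 3.2)^2 / (3.2 * (1 - 3.2 / 4))
  expect_equal(hl$statistic, hand, tolerance = 1e-12)
  expect_equal(hl$df, 1)
  expect_equal(hl$p_value, pchisq(hand, 1, lower.tail = FALSE))
})

test_that("perfectly calibrated groups give statistic 0 and p 1", {
  fitted <- rep(c(0.25, 0.5, 0.75), each = 4)
  y <- c(1, 0, 0, 0,  1, 1, 0, 0,  1, 1, 1, 0)
  hl <- hosmer_lemeshow(fitted, y, n_groups = 3)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)
})

test_that("HL p-values are near-uniform for a well-specified model", {
  set.seed(404)
  reps <- 500
  n <- 500
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- cbind(z = rnorm(n))
    y <- rbinom(n, 1, plogis(-0.3 + 0.9 * x[, 1]))
    fit <- fit_logistic(x, y)
    pvals[r] <- hosmer_lemeshow(fit$fitted, y)$p_value
  }
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("rank-based AUC equals the brute-force pairwise oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both")

  brute_auc <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  }
  set.seed(55)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    p <- round(runif(n), 2)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(p, y), brute_auc(p, y), tolerance = 1e-12)
  }
})

test_that("joint cutoff maximises min(sensitivity, specificity)", {
  # perfectly separated scores: smallest separating threshold returned
  p <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 1, 1)
  cut <- joint_cutoff(p, y)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
  expect_equal(cut$cutoff, 0.8)
  expect_false(cut$degenerate)

  # all-tied scores are degenerate
  tied <- joint_cutoff(rep(0.5, 8), rep(c(0, 1), 4))
  expect_true(tied$degenerate)

  # exhaustive sweep oracle on random fixtures
  set.seed(66)
  for (i in 1:15) {
    n <- 20
    p <- round(runif(n), 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    cut <- joint_cutoff(p, y)
    best <- max(sapply(sort(unique(p)), function(t)
      min(mean(p[y == 1] >= t), mean(p[y == 0] < t))))
    expect_equal(min(cut$sensitivity, cut$specificity), best,
                 tolerance = 1e-12)
  }
})

test_that("model diagnostics bundle is internally consistent", {
  set.seed(88)
  n <- 600
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-0.4 + 1.1 * x[, "a"] + 0.8 * x[, "b"]))
  fit <- fit_logistic(x, y)
  d <- model_diagnostics(fit, y)
  expect_gte(d$auc, 0.5); expect_lte(d$auc, 1)
  expect_true(d$auc_ci[["low"]] <= d$auc && d$auc <= d$auc_ci[["high"]])
  expect_equal(d$hl_df, 8)
  expect_lt(d$omnibus_p, 0.001)
  expect_true(d$sensitivity >= 0 && d$sensitivity <= 1)
  expect_true(d$specificity >= 0 && d$specificity <= 1)
  # CI around each adjusted OR contains the point estimate
  ors <- fit$odds_ratios
  expect_true(all(ors[, "ci_low"] <= ors[, "or"] &
                    ors[, "or"] <= ors[, "ci_high"]))
})
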