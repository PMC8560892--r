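#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into `n_groups` groups of increasing fitted risk
#' (deciles of risk by default), keeping tied fitted probabilities in the
#' same group, and compares observed with expected outcome counts:
#' `C = sum_g (O_g - E_g)^2 / (E_g * (1 - E_g / n_g))`, referred to a
#' chi-square with `n_groups - 2` degrees of freedom. A group whose
#' expected count is zero is merged with its neighbour (with a message).
#'
#' @param fitted Fitted probabilities.
#' @param y Binary outcomes.
#' @param n_groups Number of risk groups, at least 3; default 10.
#' @return List with `statistic`, `df`, `p_value`, and the per-group
#'   `table` (observed, expected, size).
#' @export
hosmer_lemeshow <- function(fitted, y, n_groups = 10) {
  stopifnot(length(fitted) == length(y), n_groups >= 3)
  y <- as.numeric(y)
  # quantile breaks; ties collapse breaks so tied probabilities share a group
  breaks <- unique(stats::quantile(fitted, probs = seq(0, 1,
                                                       length.out = n_groups + 1),
                                   type = 2, names = FALSE))
  if (length(breaks) < 3)
    stop("fitted probabilities too concentrated to form risk groups",
         call. = FALSE)
  grp <- cut(fitted, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  obs <- tapply(y, grp, sum)
  exp_ <- tapply(fitted, grp, sum)
  size <- tapply(rep(1, length(y)), grp, sum)
  # merge groups with zero expected events into the neighbour above
  while (any(exp_ == 0) && length(exp_) > 3) {
    i <- which(exp_ == 0)[1]
    j <- if (i == length(exp_)) i - 1L else i + 1L
    obs[j] <- obs[j] + obs[i]; exp_[j] <- exp_[j] + exp_[i]
    size[j] <- size[j] + size[i]
    obs <- obs[-i]; exp_ <- exp_[-i]; size <- size[-i]
    message("merged a risk group with zero expected events into its neighbour")
  }
  g <- length(obs)
  statistic <- sum((obs - exp_)^2 / (exp_ * (1 - exp_ / size)))
  df <- g - 2
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       table = data.frame(group = seq_len(g), size = as.integer(size),
                          observed = as.numeric(obs),
                          expected = as.numeric(exp_)))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with ties given half credit.
#'
#' @param fitted Scores or fitted probabilities.
#' @param y Binary outcomes; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 0.75
roc_auc <- function(fitted, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(fitted)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hanley-McNeil standard error for an AUC confidence interval.
auc_ci <- function(auc, n1, n0, level = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm((1 + level) / 2)
  c(low = max(0, auc - z * se), high = min(1, auc + z * se))
}

#' Cutoff simultaneously maximising sensitivity and specificity
#'
#' Sweeps every achievable threshold (classify positive when the fitted
#' probability is at least the threshold) and returns the one maximising
#' the minimum of sensitivity and specificity; ties are broken toward the
#' larger sensitivity + specificity sum, then toward the smaller
#' threshold. The Youden criterion (maximising sensitivity + specificity
#' - 1) is available as an alternative.
#'
#' @param fitted Fitted probabilities.
#' @param y Binary outcomes; both classes must be present.
#' @param method `"min"` (default) or `"youden"`.
#' @return List with `cutoff`, `sensitivity`, `specificity`, and
#'   `degenerate` (`TRUE` when no threshold separates anything, e.g. all
#'   scores tied).
#' @export
joint_cutoff <- function(fitted, y, method = c("min", "youden")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  thresholds <- sort(unique(fitted))
  sens <- vapply(thresholds, function(t) mean(fitted[y == 1] >= t),
                 numeric(1))
  spec <- vapply(thresholds, function(t) mean(fitted[y == 0] < t),
                 numeric(1))
  objective <- if (method == "min") pmin(sens, spec) else sens + spec - 1
  best <- max(objective)
  cand <- which(objective == best)
  cand <- cand[order(-(sens[cand] + spec[cand]), thresholds[cand])]
  i <- cand[1]
  list(cutoff = thresholds[i], sensitivity = sens[i], specificity = spec[i],
       degenerate = best <= 0)
}

#' Calibration and discrimination diagnostics of a logistic fit
#'
#' The footnote block of a published predictor table: omnibus likelihood
#' ratio test, Hosmer-Lemeshow calibration, AUC with a Hanley-McNeil
#' confidence interval, and the joint sensitivity/specificity cutoff.
#'
#' @param fit A [fit_logistic()] object.
#' @param y The binary outcome the model was fitted to.
#' @param n_groups Hosmer-Lemeshow risk groups (default 10).
#' @param level Confidence level for the AUC interval.
#' @return A list of class `model_diagnostics`.
#' @export
model_diagnostics <- function(fit, y, n_groups = 10, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  y <- as.numeric(y)
  lr <- 2 * (fit$loglik - fit$null_loglik)
  df <- length(fit$coefficients) - 1L
  omnibus_p <- if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE)
               else NA_real_
  hl <- hosmer_lemeshow(fit$fitted, y, n_groups)
  auc <- roc_auc(fit$fitted, y)
  ci <- auc_ci(auc, sum(y == 1), sum(y == 0), level)
  cut <- joint_cutoff(fit$fitted, y)
  structure(
    list(omnibus_lr = lr, omnibus_df = df, omnibus_p = omnibus_p,
         hl_statistic = hl$statistic, hl_df = hl$df, hl_p = hl$p_value,
         auc = auc, auc_ci = ci,
         cutoff = cut$cutoff, sensitivity = cut$sensitivity,
         specificity = cut$specificity),
    class = "model_diagnostics"
  )
}

#' @export
print.model_diagnostics <- function(x, ...) {
  cat(sprintf("Omnibus LR test: chi2 = %.3f (df %d), p = %.4g\n",
              x$omnibus_lr, x$omnibus_df, x$omnibus_p))
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f (df %d), p = %.3f\n",
              x$hl_statistic, x$hl_df, x$hl_p))
  cat(sprintf("AUC = %.3f [%.3f; %.3f]\n", x$auc, x$auc_ci[["low"]],
              x$auc_ci[["high"]]))
  cat(sprintf("Cutoff %.4f: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
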