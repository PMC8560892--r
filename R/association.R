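#' 2x2 contingency table for an exposure-outcome pair
#'
#' Orientation follows the unadjusted-odds-ratio columns of a medication
#' review: `a` exposed with the outcome, `b` unexposed with the outcome,
#' `c` exposed without, `d` unexposed without. The odds ratio is then
#' `(a * d) / (b * c)`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A list of class `contingency_2x2`.
#' @export
#' @examples
#' contingency_2x2(94, 43, 9, 15)  # female vs male exposure, PIM outcome
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("all four cells must be non-negative integers", call. = FALSE)
  structure(stats::setNames(as.list(as.integer(cells)), names(cells)),
            class = "contingency_2x2")
}

has_zero_cell <- function(t) {
  any(unlist(t[c("a", "b", "c", "d")]) == 0L)
}

#' Cross-product odds ratio of a 2x2 table
#'
#' Returns `(a*d)/(b*c)`. A zero cell leaves the odds ratio undefined and
#' returns `NA` (reported as a dash, as published tables do); the
#' Haldane-Anscombe correction adding 0.5 to every cell is available but
#' off by default.
#'
#' @param t A [contingency_2x2()].
#' @param correction Add 0.5 to every cell (opt-in, for zero cells).
#' @return Numeric odds ratio, or `NA_real_` when undefined.
#' @export
#' @examples
#' odds_ratio(contingency_2x2(94, 43, 9, 15))  # 3.64 at printed precision
odds_ratio <- function(t, correction = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"))
  k <- if (correction) 0.5 else 0
  if (!correction && has_zero_cell(t)) return(NA_real_)
  ((t$a + k) * (t$d + k)) / ((t$b + k) * (t$c + k))
}

log_or_se <- function(t, k = 0) {
  sqrt(1 / (t$a + k) + 1 / (t$b + k) + 1 / (t$c + k) + 1 / (t$d + k))
}

#' Woolf confidence interval for a 2x2 odds ratio
#'
#' Wald-type interval on the log scale:
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t A [contingency_2x2()].
#' @param level Confidence level in (0, 1), default 0.95.
#' @param correction Haldane-Anscombe 0.5 correction (opt-in).
#' @return Numeric vector `c(low, high)`, `NA`s when a zero cell leaves the
#'   interval undefined.
#' @export
#' @examples
#' woolf_ci(contingency_2x2(94, 43, 9, 15))  # (1.48, 8.98)
woolf_ci <- function(t, level = 0.95, correction = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"), level > 0, level < 1)
  or <- odds_ratio(t, correction = correction)
  if (is.na(or)) return(c(low = NA_real_, high = NA_real_))
  k <- if (correction) 0.5 else 0
  z <- stats::qnorm((1 + level) / 2)
  se <- log_or_se(t, k)
  c(low = exp(log(or) - z * se), high = exp(log(or) + z * se))
}

#' Wald test p-value for a 2x2 odds ratio
#'
#' Two-sided p from `z = log(OR) / SE` against the standard normal.
#'
#' @param t A [contingency_2x2()].
#' @param correction Haldane-Anscombe 0.5 correction (opt-in).
#' @return Numeric p-value, `NA_real_` when the OR is undefined.
#' @export
#' @examples
#' wald_p(contingency_2x2(94, 43, 9, 15))  # 0.005 at printed precision
wald_p <- function(t, correction = FALSE) {
  or <- odds_ratio(t, correction = correction)
  if (is.na(or)) return(NA_real_)
  k <- if (correction) 0.5 else 0
  z <- log(or) / log_or_se(t, k)
  2 * stats::pnorm(-abs(z))
}

association_row <- function(covariate, outcome, t, type = "binary") {
  or <- odds_ratio(t)
  ci <- woolf_ci(t)
  data.frame(
    covariate = covariate, outcome = outcome, type = type,
    a = t$a, b = t$b, c = t$c, d = t$d,
    or_point = or, ci_low = ci[["low"]], ci_high = ci[["high"]],
    p_wald = wald_p(t), defined = !is.na(or),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Univariate association screen across covariates and both outcomes
#'
#' For each covariate and each outcome (at least one PIM; at least one PPO)
#' computes the unadjusted association: binary covariates through the 2x2
#' cross-product odds ratio with Woolf interval and Wald p; continuous
#' covariates through a single-covariate logistic regression, giving a
#' per-unit odds ratio. Zero cells leave a row flagged `defined = FALSE`
#' (rendered as a dash), with no continuity correction.
#'
#' @param cohort List of [patient_record()]s.
#' @param results Matching list of `screening_result`s.
#' @param covariates Character vector of covariate names (columns of
#'   [cohort_covariates()]); defaults to all of them except `id`.
#' @return A data frame with one row per covariate per outcome.
#' @export
associate_all <- function(cohort, results, covariates = NULL) {
  covs <- cohort_covariates(cohort)
  if (is.null(covariates))
    covariates <- setdiff(names(covs), "id")
  missing <- setdiff(covariates, names(covs))
  if (length(missing))
    stop("covariate(s) absent from cohort: ", paste(missing, collapse = ", "),
         call. = FALSE)
  outcomes <- list(
    pim = vapply(results, function(r) r$n_pims >= 1L, logical(1)),
    ppo = vapply(results, function(r) r$n_ppos >= 1L, logical(1))
  )
  rows <- list()
  for (nm in covariates) {
    x <- covs[[nm]]
    binary <- is.logical(x) || all(x %in% c(0, 1))
    for (out in names(outcomes)) {
      y <- outcomes[[out]]
      if (binary) {
        x <- as.logical(x)
        t <- contingency_2x2(sum(x & y), sum(!x & y),
                             sum(x & !y), sum(!x & !y))
        rows[[length(rows) + 1L]] <- association_row(nm, out, t)
      } else {
        fit <- try(fit_logistic(cbind(x = as.numeric(x)), as.integer(y)),
                   silent = TRUE)
        ok <- !inherits(fit, "try-error") && fit$converged
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = nm, outcome = out, type = "continuous",
          a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
          or_point = if (ok) fit$odds_ratios["x", "or"] else NA_real_,
          ci_low = if (ok) fit$odds_ratios["x", "ci_low"] else NA_real_,
          ci_high = if (ok) fit$odds_ratios["x", "ci_high"] else NA_real_,
          p_wald = if (ok) fit$p_values[["x"]] else NA_real_,
          defined = ok, row.names = NULL, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
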