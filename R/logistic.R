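#' Maximum-likelihood logistic regression via IRLS
#'
#' Fits a binomial model with logit link by iteratively reweighted least
#' squares. An intercept is always added; `x` holds the covariate columns
#' only. Convergence is declared when the largest score component falls
#' below `1e-8` or the relative change in log-likelihood falls below
#' `1e-10`, within 25 iterations. Quasi-separation (coefficients diverging
#' with fitted probabilities pinned at 0/1) is detected and the fit is
#' flagged rather than silently returned.
#'
#' @param x Numeric matrix of covariates (no intercept column), with column
#'   names.
#' @param y Binary outcome vector (0/1 or logical).
#' @param weights Optional non-negative case weights (e.g. grouped-data
#'   frequencies).
#' @param level Confidence level for the odds-ratio intervals.
#' @return A list of class `logistic_fit`: `coefficients`, `vcov`, `z`,
#'   `p_values`, `odds_ratios` (matrix with `or`, `ci_low`, `ci_high` rows
#'   per covariate), `loglik`, `loglik_trace`, `null_loglik`, `converged`,
#'   `separation`, `n_iterations`, `fitted`, `n`.
#' @export
#' @examples
#' # grouped 2x2 data: exposure female, outcome >=1 PIM
#' x <- cbind(female = c(1, 1, 0, 0))
#' y <- c(1, 0, 1, 0)
#' w <- c(94, 9, 43, 15)
#' fit <- fit_logistic(x, y, weights = w)
#' exp(fit$coefficients["female"])  # cross-product odds ratio, 3.64
fit_logistic <- function(x, y, weights = NULL, level = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  n <- length(y)
  if (nrow(x) != n) stop("x and y dimensions differ", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (length(unique(y[w > 0])) < 2L)
    stop("outcome has no variation", call. = FALSE)

  design <- cbind(rep(1, n), x)
  colnames(design) <- c("(Intercept)", colnames(x))
  p <- ncol(design)
  if (sum(w > 0) <= p)
    stop("more parameters than observations", call. = FALSE)
  qrd <- qr(design * sqrt(w))
  if (qrd$rank < p) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  beta <- rep(0, p)
  loglik <- function(b) {
    eta <- drop(design %*% b)
    sum(w * (y * eta - log1p(exp(eta))))
  }
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(design %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(design, w * (y - mu)))
    irls_w <- w * mu * (1 - mu)
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    info <- crossprod(design * sqrt(irls_w))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    # step-halving keeps the likelihood non-decreasing
    new_ll <- loglik(beta + step)
    halvings <- 0L
    while (new_ll < ll && halvings < 20L) {
      step <- step / 2
      new_ll <- loglik(beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    trace <- c(trace, new_ll)
    rel_change <- abs(new_ll - ll) / (abs(ll) + 1e-12)
    ll <- new_ll
    if (rel_change < 1e-10) { converged <- TRUE; break }
    if (iter >= 25L) break
  }
  eta <- drop(design %*% beta)
  mu <- stats::plogis(eta)
  if (max(abs(beta)) > 15 &&
      all(abs(y - mu)[w > 0] < 1e-6 | mu[w > 0] %in% c(0, 1))) {
    separation <- TRUE
  }
  if (!converged || separation)
    warning(if (separation) "quasi-separation detected; fit flagged"
            else "IRLS did not converge within 25 iterations",
            call. = FALSE)

  irls_w <- w * mu * (1 - mu)
  info <- crossprod(design * sqrt(pmax(irls_w, 0)))
  vcov <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, p, p, dimnames = list(colnames(design),
                                           colnames(design))))
  dimnames(vcov) <- list(colnames(design), colnames(design))
  se <- sqrt(diag(vcov))
  z <- beta / se
  pvals <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(z) <- names(pvals) <- colnames(design)
  zq <- stats::qnorm((1 + level) / 2)
  covars <- setdiff(colnames(design), "(Intercept)")
  ors <- matrix(NA_real_, length(covars), 3,
                dimnames = list(covars, c("or", "ci_low", "ci_high")))
  if (length(covars)) {
    ors[, "or"] <- exp(beta[covars])
    ors[, "ci_low"] <- exp(beta[covars] - zq * se[covars])
    ors[, "ci_high"] <- exp(beta[covars] + zq * se[covars])
  }
  # intercept-only log-likelihood for the omnibus LR test
  p0 <- sum(w * y) / sum(w)
  null_ll <- sum(w * (y * log(p0) + (1 - y) * log(1 - p0)))

  structure(
    list(coefficients = beta, vcov = vcov, z = z, p_values = pvals,
         odds_ratios = ors, loglik = ll, loglik_trace = trace,
         null_loglik = null_ll, converged = converged,
         separation = separation, n_iterations = iter, fitted = mu,
         weights = w, n = n),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: %d coefficients, logLik %.3f, %s in %d iter%s>\n",
              length(x$coefficients), x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations,
              if (x$separation) ", separation flagged" else ""))
  tab <- cbind(estimate = x$coefficients, z = x$z, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Forward selection of logistic-regression covariates by Wald test
#'
#' Starting from the intercept-only model, repeatedly fits each remaining
#' candidate on top of the current model and admits the one with the
#' smallest Wald p-value, provided it is below `p_enter`; stops when no
#' candidate qualifies. The final report keeps covariates with Wald
#' `p < p_report` (the reporting convention of the study tables this
#' mirrors).
#'
#' @param x Candidate covariate matrix (named columns).
#' @param y Binary outcome.
#' @param p_enter Entry threshold on the Wald p-value (default 0.05).
#' @param p_report Reporting threshold on the Wald p-value (default 0.1).
#' @return A list of class `forward_selection`: `fit` (the final
#'   [fit_logistic()] object; intercept-only when nothing entered),
#'   `selected` (covariates in entry order), `reported` (selected
#'   covariates with final p < `p_report`), `trace` (data frame of steps).
#' @export
forward_select <- function(x, y, p_enter = 0.05, p_report = 0.1) {
  x <- as.matrix(x)
  candidates <- colnames(x)
  selected <- character()
  trace <- list()
  if (!length(candidates)) {
    fit <- fit_logistic(x[, 0, drop = FALSE], y)
    message("empty candidate set: returning intercept-only model")
    return(structure(list(fit = fit, selected = character(),
                          reported = character(),
                          trace = data.frame()),
                     class = "forward_selection"))
  }
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    pvals <- vapply(remaining, function(nm) {
      f <- tryCatch(
        suppressWarnings(
          fit_logistic(x[, c(selected, nm), drop = FALSE], y)),
        error = function(e) NULL)
      if (is.null(f) || !f$converged || f$separation) return(NA_real_)
      f$p_values[[nm]]
    }, numeric(1))
    if (all(is.na(pvals))) break
    best <- remaining[which.min(pvals)]
    best_p <- min(pvals, na.rm = TRUE)
    if (best_p >= p_enter) break
    selected <- c(selected, best)
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(selected), entered = best, p_entry = best_p,
      stringsAsFactors = FALSE)
  }
  fit <- if (length(selected))
    fit_logistic(x[, selected, drop = FALSE], y)
  else {
    message("no candidate met the entry criterion; intercept-only model")
    fit_logistic(x[, 0, drop = FALSE], y)
  }
  reported <- selected[fit$p_values[selected] < p_report]
  structure(
    list(fit = fit, selected = selected, reported = reported,
         trace = if (length(trace)) do.call(rbind, trace) else data.frame()),
    class = "forward_selection"
  )
}
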