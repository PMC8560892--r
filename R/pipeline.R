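#' Render a screening summary as report text
#'
#' Produces the familiar two-column layout of a medication-review report:
#' the distribution of patients by number of PIMs and PPOs (buckets 0-6 and
#' 7+), the prevalence of at least one, mean and SD, median with quartiles,
#' then per-section and per-criterion frequencies. Percentages print with
#' one decimal, rounded half-up.
#'
#' @param summary A `screening_summary` from [summarize_screening()].
#' @return Character vector of report lines.
#' @export
render_summary <- function(summary) {
  stopifnot(inherits(summary, "screening_summary"))
  fmt_n_pct <- function(n, pct) sprintf("%d (%.1f)", n, pct)
  block <- function(tool, label) {
    s <- summary[[tool]]
    lines <- c(sprintf("== %s ==", label),
               "Number per patient  n (%)")
    buckets <- names(s$distribution)
    for (b in buckets) {
      n <- s$distribution[[b]]
      lines <- c(lines, sprintf("  %-3s %s", b,
                                fmt_n_pct(n, pct1(n, summary$n_total))))
    }
    lines <- c(
      lines,
      sprintf("  Total (>=1) %s", fmt_n_pct(s$prevalence_n,
                                            s$prevalence_pct)),
      if (!is.na(s$mean))
        sprintf("  Mean +/- SD %.1f +/- %.1f", s$mean, s$sd),
      if (!is.na(s$median))
        sprintf("  Median (P25; P75) %g (%g; %g)", s$median, s$p25, s$p75),
      "Per section  n (%)")
    for (i in seq_len(nrow(s$section_freq)))
      lines <- c(lines, sprintf("  %-3s %s", s$section_freq$section[i],
                                fmt_n_pct(s$section_freq$n[i],
                                          s$section_freq$pct[i])))
    lines <- c(lines, "Per criterion  n (%)")
    for (i in seq_len(nrow(s$criterion_freq)))
      lines <- c(lines, sprintf("  %-10s %s", s$criterion_freq$id[i],
                                fmt_n_pct(s$criterion_freq$n[i],
                                          s$criterion_freq$pct[i])))
    lines
  }
  c(sprintf("Cohort size: %d", summary$n_total),
    block("pim", "PIMs (STOPP criteria)"),
    block("ppo", "PPOs (START criteria)"))
}

#' Render the univariate association table
#'
#' @param assoc Data frame from [associate_all()].
#' @return Character vector of delimited lines (tab-separated), undefined
#'   odds ratios rendered as a dash.
#' @export
render_association <- function(assoc) {
  fmt <- function(defined, or, lo, hi, p) {
    ifelse(defined,
           sprintf("%.2f (%.2f; %.2f)\t%.3f",
                   round_half_up(or, 2), round_half_up(lo, 2),
                   round_half_up(hi, 2), round_half_up(p, 3)),
           "—\t—")
  }
  c("covariate\toutcome\tOR (95%CI)\tp",
    sprintf("%s\t%s\t%s", assoc$covariate, assoc$outcome,
            fmt(assoc$defined, assoc$or_point, assoc$ci_low,
                assoc$ci_high, assoc$p_wald)))
}

#' Run the full medication-review pipeline
#'
#' Generates (or reads) a cohort, screens it against a criteria catalog,
#' summarises the screening, computes the univariate association screen for
#' both outcomes, and fits a forward-selection logistic model per outcome
#' using the univariate-significant covariates as candidates. All artifacts
#' are written under `out_dir` with a provenance header (seed, catalog,
#' package version); outputs carry no timestamps, so re-running with the
#' same configuration reproduces them byte for byte.
#'
#' @param out_dir Output directory, created if needed.
#' @param n Cohort size to simulate (ignored when `cohort_file` is given).
#' @param seed Root seed for the whole run.
#' @param cohort_file Optional path to an existing cohort file to analyse
#'   instead of simulating.
#' @param catalog_file Path to the criteria catalog.
#' @param p_enter,p_report Forward-selection thresholds.
#' @param candidate_mode `"univariate"` (candidates = covariates with
#'   univariate Wald p < 0.05) or `"all"` (all covariates with defined,
#'   non-degenerate associations).
#' @param verbose Log one line per stage.
#' @return Invisibly, a list with the cohort, screening results, summary,
#'   association table, and per-outcome `forward_selection` objects plus
#'   diagnostics.
#' @export
run_pipeline <- function(out_dir, n = 2000, seed = 1, cohort_file = NULL,
                         catalog_file = catalog_path(), p_enter = 0.05,
                         p_report = 0.1,
                         candidate_mode = c("univariate", "all"),
                         verbose = TRUE) {
  candidate_mode <- match.arg(candidate_mode)
  if (!file.exists(catalog_file))
    stop("catalog file not found: ", catalog_file, call. = FALSE)
  if (!is.null(cohort_file) && !file.exists(cohort_file))
    stop("cohort file not found: ", cohort_file, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (verbose) message(sprintf(...))
  header <- c(sprintf("# seed: %d", as.integer(seed)),
              sprintf("# catalog: %s", basename(catalog_file)),
              sprintf("# stoppstart version: %s",
                      as.character(utils::packageVersion("stoppstart"))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  catalog <- stage("catalog", load_catalog(catalog_file))
  cohort <- stage("cohort", {
    if (is.null(cohort_file)) {
      ch <- generate_cohort(cohort_config(n = n, seed = seed))
      write_cohort(ch, file.path(out_dir, "cohort.csv"))
      ch
    } else read_cohort(cohort_file)
  })
  log_line("cohort: %d patients", length(cohort))

  results <- stage("screen", screen_cohort(cohort, catalog))
  write_screening(results, file.path(out_dir, "screening.csv"))
  log_line("screen: %d results", length(results))

  summary <- stage("summarize", summarize_screening(results, catalog))
  writeLines(c(header, render_summary(summary)),
             file.path(out_dir, "summary.txt"))

  assoc <- stage("associate", associate_all(cohort, results))
  writeLines(c(header, render_association(assoc)),
             file.path(out_dir, "associations.tsv"))
  n_undef <- sum(!assoc$defined)
  if (n_undef) log_line("associate: %d undefined odds ratio(s)", n_undef)

  covs <- cohort_covariates(cohort)
  outcomes <- list(
    pim = vapply(results, function(r) r$n_pims >= 1L, logical(1)),
    ppo = vapply(results, function(r) r$n_ppos >= 1L, logical(1))
  )
  models <- list()
  for (out in names(outcomes)) {
    y <- outcomes[[out]]
    if (length(unique(y)) < 2L) {
      log_line("fit[%s]: outcome constant, skipped", out)
      next
    }
    rows <- assoc[assoc$outcome == out & assoc$defined, ]
    candidates <- if (candidate_mode == "univariate")
      rows$covariate[rows$p_wald < 0.05]
    else rows$covariate
    models[[out]] <- stage(paste0("fit_", out), {
      sel <- forward_select(as.matrix(covs[, candidates, drop = FALSE]),
                            as.integer(y), p_enter, p_report)
      diag <- if (length(sel$selected))
        tryCatch(model_diagnostics(sel$fit, as.integer(y)),
                 error = function(e) {
                   log_line("fit[%s]: diagnostics unavailable (%s)", out,
                            conditionMessage(e))
                   NULL
                 })
      else NULL
      lines <- c(header, sprintf("outcome: %s", out),
                 sprintf("candidates: %s", paste(candidates, collapse = ", ")),
                 sprintf("selected: %s",
                         paste(sel$selected, collapse = ", ")),
                 sprintf("reported (p < %.2g): %s", p_report,
                         paste(sel$reported, collapse = ", ")),
                 "coefficient\tadjusted OR (95%CI)\tp")
      for (nm in sel$selected) {
        or <- sel$fit$odds_ratios[nm, ]
        lines <- c(lines, sprintf(
          "%s\t%.2f (%.2f; %.2f)\t%.3f", nm,
          round_half_up(or[["or"]], 2), round_half_up(or[["ci_low"]], 2),
          round_half_up(or[["ci_high"]], 2),
          round_half_up(sel$fit$p_values[[nm]], 3)))
      }
      if (!is.null(diag))
        lines <- c(lines, utils::capture.output(print(diag)))
      writeLines(lines, file.path(out_dir, sprintf("model_%s.txt", out)))
      log_line("fit[%s]: %d of %d candidates selected", out,
               length(sel$selected), length(candidates))
      list(selection = sel, diagnostics = diag)
    })
  }
  invisible(list(cohort = cohort, results = results, summary = summary,
                 associations = assoc, models = models))
}
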