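#' Summarise cohort screening results
#'
#' Aggregates per-patient screening results into the shape medication-review
#' studies report: the distribution of patients by number of PIMs and PPOs
#' (buckets 0, 1, ..., 6 and 7-or-more), the prevalence of at least one,
#' mean, SD and median with quartiles of the per-patient counts, and
#' per-criterion and per-section frequencies (a patient counts once per
#' section however many of its criteria fired).
#'
#' @param results List of `screening_result`s covering distinct patients.
#' @param catalog The `criteria_catalog` the results were produced with.
#' @param n_total Cohort size used as the percentage denominator; defaults
#'   to `length(results)`.
#' @return A list of class `screening_summary` with components `n_total`,
#'   and for each tool (`pim`, `ppo`): `distribution` (named counts for
#'   buckets `0`..`6`, `7+`), `prevalence_n`, `prevalence_pct`, `mean`,
#'   `sd`, `median`, `p25`, `p75`, `criterion_freq` and `section_freq`
#'   (data frames with `n` and `pct`).
#' @export
summarize_screening <- function(results, catalog, n_total = length(results)) {
  ids <- vapply(results, function(r) r$patient_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate patient_id(s) in screening results: ",
         paste(dup, collapse = ", "), call. = FALSE)
  structure(
    list(
      n_total = n_total,
      pim = summarize_tool(results, catalog, "STOPP", n_total),
      ppo = summarize_tool(results, catalog, "START", n_total)
    ),
    class = "screening_summary"
  )
}

summarize_tool <- function(results, catalog, tool, n_total) {
  counts <- if (tool == "STOPP")
    vapply(results, function(r) r$n_pims, integer(1))
  else
    vapply(results, function(r) r$n_ppos, integer(1))
  fired <- lapply(results, function(r)
    if (tool == "STOPP") r$stopp_ids else r$start_ids)

  buckets <- c(as.character(0:6), "7+")
  distribution <- setNames(integer(length(buckets)), buckets)
  if (length(counts)) {
    bucketed <- ifelse(counts >= 7L, "7+", as.character(counts))
    tb <- table(bucketed)
    distribution[names(tb)] <- as.integer(tb)
  }
  prevalence_n <- sum(counts >= 1L)

  rules <- Filter(function(r) r$tool == tool, catalog$rules)
  rule_ids <- vapply(rules, function(r) r$id, character(1))
  sections <- vapply(rules, function(r) r$section, character(1))

  crit_n <- vapply(rule_ids, function(id)
    sum(vapply(fired, function(f) id %in% f, logical(1))), integer(1))
  criterion_freq <- data.frame(
    id = rule_ids, section = sections, n = as.integer(crit_n),
    pct = pct1(crit_n, n_total), row.names = NULL, stringsAsFactors = FALSE
  )

  sec_levels <- unique(sections)
  sec_n <- vapply(sec_levels, function(s) {
    in_sec <- rule_ids[sections == s]
    sum(vapply(fired, function(f) length(intersect(f, in_sec)) > 0L,
               logical(1)))
  }, integer(1))
  section_freq <- data.frame(
    section = sec_levels, n = as.integer(sec_n),
    pct = pct1(sec_n, n_total), row.names = NULL, stringsAsFactors = FALSE
  )

  desc <- if (length(counts)) describe_continuous(counts)
          else list(mean = NA_real_, sd = NA_real_, median = NA_real_,
                    p25 = NA_real_, p75 = NA_real_)
  list(
    distribution = distribution,
    prevalence_n = prevalence_n,
    prevalence_pct = pct1(prevalence_n, n_total),
    mean = desc$mean, sd = desc$sd, median = desc$median,
    p25 = desc$p25, p75 = desc$p75,
    criterion_freq = criterion_freq,
    section_freq = section_freq
  )
}

#' Rebuild screening results from a count distribution
#'
#' Published medication-review tables report how many patients had 0, 1, 2,
#' ... criteria fire without patient-level data. This helper materialises a
#' list of minimal `screening_result`s with the given per-patient counts so
#' the distribution can be fed through [summarize_screening()]; fired-id
#' sets are filled with placeholder ids.
#'
#' @param pim_counts,ppo_counts Integer vectors, one element per patient.
#' @return List of `screening_result`s.
#' @export
screening_from_counts <- function(pim_counts,
                                  ppo_counts = integer(length(pim_counts))) {
  stopifnot(length(pim_counts) == length(ppo_counts))
  lapply(seq_along(pim_counts), function(i) {
    np <- as.integer(pim_counts[i]); no <- as.integer(ppo_counts[i])
    structure(
      list(patient_id = sprintf("p%04d", i),
           stopp_ids = if (np) sprintf("STOPP-X%d", seq_len(np)) else character(),
           start_ids = if (no) sprintf("START-X%d", seq_len(no)) else character(),
           n_pims = np, n_ppos = no),
      class = "screening_result"
    )
  })
}
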