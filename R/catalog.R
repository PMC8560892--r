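#' Load a STOPP/START criteria catalog
#'
#' Reads a YAML catalog declaring drug classes (ATC prefix sets, optionally
#' with exclusions) and machine-evaluable criterion rules, validates it, and
#' returns a `criteria_catalog`. The catalog shipped with the package covers
#' the STOPP and START criteria observed in a post-acute/long-term care
#' medication review; sections with no observed criteria (STOPP E and J,
#' START D and I) are deliberate extension points.
#'
#' @param path Path to a catalog file; defaults to the shipped catalog.
#' @return A list of class `criteria_catalog` with elements `drug_classes`
#'   (named list of `list(include, exclude)` prefix sets) and `rules` (list
#'   of `criterion_rule` objects).
#' @export
#' @examples
#' cat <- default_catalog()
#' length(cat$rules)
load_catalog <- function(path = catalog_path()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || is.null(raw$rules) || !length(raw$rules)) {
    warning("catalog '", path, "' contains no rules", call. = FALSE)
    return(structure(list(drug_classes = normalize_classes(raw$drug_classes),
                          rules = list()),
                     class = "criteria_catalog"))
  }
  classes <- normalize_classes(raw$drug_classes)
  rules <- lapply(raw$rules, as_criterion_rule)
  ids <- vapply(rules, function(r) r$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate criterion id(s) in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  catalog <- structure(list(drug_classes = classes, rules = rules),
                       class = "criteria_catalog")
  for (r in rules) validate_condition(r$condition, catalog, r$id)
  catalog
}

#' @rdname load_catalog
#' @export
default_catalog <- function() {
  load_catalog(catalog_path())
}

catalog_path <- function() {
  system.file("extdata", "stopp_start_catalog.yaml", package = "stoppstart",
              mustWork = TRUE)
}

#' Write a catalog back to YAML
#'
#' Round-trips through [load_catalog()]: the saved file reloads to a
#' catalog with identical rules and drug classes.
#'
#' @param catalog A `criteria_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "criteria_catalog"))
  classes <- lapply(catalog$drug_classes, function(cl) {
    if (length(cl$exclude)) list(include = cl$include, exclude = cl$exclude)
    else cl$include
  })
  rules <- lapply(catalog$rules, function(r) {
    list(id = r$id, tool = r$tool, section = r$section,
         section_label = r$section_label, description = r$description,
         condition = r$condition)
  })
  yaml::write_yaml(list(drug_classes = classes, rules = rules), path)
  invisible(path)
}

normalize_classes <- function(classes) {
  if (is.null(classes)) return(list())
  lapply(classes, function(cl) {
    if (is.list(cl) && !is.null(cl$include))
      list(include = as.character(cl$include),
           exclude = as.character(cl$exclude %||% character()))
    else
      list(include = as.character(unlist(cl)), exclude = character())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_criterion_rule <- function(x) {
  needed <- c("id", "tool", "section", "description", "condition")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("catalog rule ", x$id %||% "<unnamed>", " is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!x$tool %in% c("STOPP", "START"))
    stop("rule ", x$id, ": tool must be STOPP or START", call. = FALSE)
  section <- x$section
  # YAML 1.1 reads a bare N/Y as a boolean; section letters hit this
  if (is.logical(section)) section <- if (section) "Y" else "N"
  structure(
    list(id = as.character(x$id), tool = x$tool,
         section = as.character(section),
         section_label = x$section_label %||% "",
         description = x$description, condition = x$condition),
    class = "criterion_rule"
  )
}

#' @export
print.criteria_catalog <- function(x, ...) {
  tools <- vapply(x$rules, function(r) r$tool, character(1))
  cat(sprintf("<criteria_catalog: %d rules (%d STOPP, %d START), %d drug classes>\n",
              length(x$rules), sum(tools == "STOPP"), sum(tools == "START"),
              length(x$drug_classes)))
  invisible(x)
}

condition_primitives <- function() {
  c("all", "any", "not", "has_drug_class", "lacks_drug_class",
    "drug_class_count_ge", "duplicate_drug_class", "co_prescribed",
    "has_condition", "qualifier", "flag", "age_gt")
}

# Structural validation: every node is a known primitive; every referenced
# drug class, condition label, qualifier and patient flag is declared.
validate_condition <- function(node, catalog, rule_id) {
  if (!is.list(node) || length(node) != 1L || is.null(names(node)))
    stop("rule ", rule_id, ": each condition node must be a single named ",
         "primitive or combinator", call. = FALSE)
  key <- names(node)
  body <- node[[1]]
  if (!key %in% condition_primitives())
    stop("rule ", rule_id, ": unknown condition primitive '", key, "'",
         call. = FALSE)
  check_class <- function(name) {
    if (!name %in% names(catalog$drug_classes))
      stop("rule ", rule_id, ": unknown drug class '", name, "'",
           call. = FALSE)
  }
  switch(key,
    all = ,
    any = lapply(body, validate_condition, catalog = catalog,
                 rule_id = rule_id),
    not = validate_condition(body, catalog, rule_id),
    has_drug_class = ,
    lacks_drug_class = check_class(body$class),
    drug_class_count_ge = {
      check_class(body$class)
      if (is.null(body$min_count) || body$min_count < 1)
        stop("rule ", rule_id, ": drug_class_count_ge needs min_count >= 1",
             call. = FALSE)
    },
    duplicate_drug_class = NULL,
    co_prescribed = {
      check_class(body$class_a)
      check_class(body$class_b)
    },
    has_condition = {
      if (!body %in% condition_vocabulary())
        stop("rule ", rule_id, ": unknown condition label '", body, "'",
             call. = FALSE)
    },
    qualifier = {
      if (!body %in% qualifier_vocabulary())
        stop("rule ", rule_id, ": unknown qualifier '", body, "'",
             call. = FALSE)
    },
    flag = {
      if (!body %in% patient_flag_fields())
        stop("rule ", rule_id, ": unknown patient flag '", body, "'",
             call. = FALSE)
    },
    age_gt = {
      if (!is.numeric(body))
        stop("rule ", rule_id, ": age_gt needs a numeric threshold",
             call. = FALSE)
    }
  )
  invisible(TRUE)
}
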