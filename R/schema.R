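#' Deficit schemas for the frailty index
#'
#' A deficit schema is the ordered list of binary health-deficit items from
#' which the deficit-accumulation frailty index is computed. Standard
#' guidance requires at least 30 items; the schema carried here maps each
#' item name to the cohort column that holds its 0/1 indicator.
#'
#' @param items Character vector of unique item names.
#' @param descriptions Optional character vector of item descriptions,
#'   recycled to `""` when absent.
#' @param columns Optional character vector of cohort column names holding
#'   each indicator; defaults to `paste0("def_", items)`.
#'
#' @return A tibble of class `deficit_schema` with columns `item`,
#'   `description`, and `column`.
#' @export
#' @examples
#' sch <- deficit_schema(paste0("item", 1:31))
#' nrow(sch)
deficit_schema <- function(items, descriptions = NULL, columns = NULL) {
  stopifnot(is.character(items), length(items) > 0)
  if (is.null(descriptions)) descriptions <- rep("", length(items))
  if (is.null(columns)) columns <- paste0("def_", items)
  stopifnot(length(descriptions) == length(items),
            length(columns) == length(items))
  out <- tibble::tibble(item = items, description = descriptions,
                        column = columns)
  class(out) <- c("deficit_schema", class(out))
  out
}

#' Packaged 31-item deficit schema
#'
#' A generic deficit-accumulation schema of 31 items: chronic comorbidities,
#' sensory and mobility deficits, and baseline-disability flags derived from
#' the pre-stroke modified Rankin Scale. It exists so the pipeline is
#' runnable out of the box; studies substitute their own item list, which is
#' what determines the index actually measured.
#'
#' @return A `deficit_schema` tibble with 31 rows.
#' @export
default_deficit_schema <- function() {
  items <- c(
    "hypertension", "diabetes", "dyslipidemia", "hypothyroidism",
    "prior_mi", "heart_failure", "kidney_failure", "prior_stroke",
    "prior_tia", "atrial_fibrillation", "peripheral_artery_disease",
    "copd", "asthma", "cancer", "depression", "dementia", "anemia",
    "obesity", "osteoporosis", "arthritis", "liver_disease",
    "hearing_impairment", "visual_impairment", "gait_problem",
    "weight_loss", "fatigue", "polypharmacy", "low_albumin",
    "elevated_creatinine", "baseline_mrs_ge1", "baseline_mrs_ge2"
  )
  desc <- c(
    "Systemic arterial hypertension", "Diabetes mellitus", "Dyslipidemia",
    "Hypothyroidism", "Previous myocardial infarction", "Heart failure",
    "Chronic kidney failure", "Previous ischemic stroke",
    "Previous transient ischemic attack", "Atrial fibrillation",
    "Peripheral arterial disease", "Chronic obstructive pulmonary disease",
    "Asthma", "History of cancer", "Depression", "Dementia", "Anemia",
    "Obesity", "Osteoporosis", "Arthritis or arthrosis",
    "Chronic liver disease", "Hearing impairment", "Visual impairment",
    "Gait or mobility problem", "Unintentional weight loss",
    "Self-reported exhaustion", "Five or more regular medications",
    "Low serum albumin", "Elevated serum creatinine",
    "Pre-stroke disability: baseline mRS >= 1",
    "Pre-stroke disability: baseline mRS >= 2"
  )
  deficit_schema(items, desc)
}

#' Validate a deficit schema
#'
#' Checks the guideline constraints: at least 30 items and no duplicated
#' item names. Returns the violations rather than erroring so callers can
#' decide whether a nonstandard schema is acceptable.
#'
#' @param schema A `deficit_schema` tibble.
#' @return A character vector of violations; empty when the schema is valid.
#' @export
#' @examples
#' validate_schema(default_deficit_schema())  # character(0)
#' validate_schema(deficit_schema(paste0("x", 1:29)))
validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema), all(c("item", "column") %in% names(schema)))
  violations <- character(0)
  if (nrow(schema) < 30) {
    violations <- c(violations,
                    sprintf("schema has %d items; minimum 30 required",
                            nrow(schema)))
  }
  dup <- unique(schema$item[duplicated(schema$item)])
  if (length(dup) > 0) {
    violations <- c(violations,
                    sprintf("duplicate item name: %s", dup))
  }
  dupc <- unique(schema$column[duplicated(schema$column)])
  if (length(dupc) > 0) {
    violations <- c(violations,
                    sprintf("duplicate source column: %s", dupc))
  }
  violations
}

#' Read a deficit schema from YAML or JSON
#'
#' The file holds a list of items, each with a `name` and optionally a
#' `description` and a `column` (the cohort column carrying the 0/1
#' indicator; defaults to `def_<name>`). A top-level `items:` key wrapping
#' the list is also accepted.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schema file.
#' @return A `deficit_schema` tibble.
#' @export
read_deficit_schema <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$items)) raw <- raw$items
  items <- purrr::map_chr(raw, function(x) {
    if (is.character(x) && length(x) == 1) x else as.character(x$name)
  })
  desc <- purrr::map_chr(raw, function(x) {
    if (is.list(x) && !is.null(x$description)) as.character(x$description) else ""
  })
  cols <- purrr::map_chr(raw, function(x) {
    if (is.list(x) && !is.null(x$column)) as.character(x$column) else NA_character_
  })
  cols <- ifelse(is.na(cols), paste0("def_", items), cols)
  deficit_schema(items, desc, cols)
}

#' Write a deficit schema to YAML
#'
#' @param schema A `deficit_schema` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deficit_schema <- function(schema, path) {
  items <- purrr::pmap(schema, function(item, description, column, ...) {
    list(name = item, description = description, column = column)
  })
  yaml::write_yaml(list(items = items), path)
  invisible(path)
}
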