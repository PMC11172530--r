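# Patient data model: FHIR-style JSON bundles, the tri-state parameter
# container, and the rule-table-driven extraction of the 16 decision-relevant
# clinical parameters.

KNOWN_RESOURCE_KINDS <- c("patient-demographics", "condition", "observation",
                          "procedure", "diagnostic-report", "episode-of-care")

#' Construct a parameter value with explicit availability
#'
#' Every clinical parameter carries a tri-state availability: `present`
#' (a value was recorded), `unknown` (a resource exists but carries no usable
#' value), or `absent` (no resource at all). Missing data is a first-class
#' state in the pathway: decision points abort rather than guess.
#'
#' @param value the typed payload, or `NULL` when not present
#' @param availability one of `"present"`, `"unknown"`, `"absent"`
#' @param unit optional unit string for numeric payloads (e.g. `"mm"`)
#' @return an object of class `param_value`
#' @export
param_value <- function(value = NULL,
                        availability = if (is.null(value)) "absent" else "present",
                        unit = NULL) {
  availability <- match.arg(availability, c("present", "unknown", "absent"))
  if (availability == "present" && is.null(value))
    stop("availability 'present' requires a value", call. = FALSE)
  if (availability != "present" && !is.null(value))
    stop("a set value requires availability 'present'", call. = FALSE)
  structure(list(value = value, availability = availability, unit = unit),
            class = "param_value")
}

is_present <- function(pv) inherits(pv, "param_value") && pv$availability == "present"

#' @export
print.param_value <- function(x, ...) {
  if (x$availability == "present") {
    cat(format(x$value), if (!is.null(x$unit)) x$unit, "\n")
  } else {
    cat("<", x$availability, ">\n", sep = "")
  }
  invisible(x)
}

#' Construct the 16-parameter clinical feature container
#'
#' @param ... named `param_value` entries; unnamed parameters default to
#'   availability `absent`
#' @return an object of class `clinical_parameters`: a named list with
#'   exactly the 16 fields of [parameter_names()]
#' @export
clinical_parameters <- function(...) {
  given <- list(...)
  if (length(given) && (is.null(names(given)) || any(names(given) == "")))
    stop("all arguments must be named", call. = FALSE)
  extra <- setdiff(names(given), parameter_names())
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  out <- setNames(vector("list", 16L), parameter_names())
  for (nm in parameter_names()) {
    pv <- given[[nm]]
    if (is.null(pv)) pv <- param_value(NULL, "absent")
    if (!inherits(pv, "param_value")) pv <- param_value(pv)
    out[[nm]] <- validate_param_payload(nm, pv)
  }
  structure(out, class = "clinical_parameters")
}

validate_param_payload <- function(name, pv) {
  if (!is_present(pv)) return(pv)
  v <- pv$value
  if (name %in% names(PARAM_VOCAB)) {
    if (!is.character(v) || length(v) != 1L || !(v %in% PARAM_VOCAB[[name]]))
      stop(sprintf("'%s' must be one of {%s}, got %s", name,
                   paste(PARAM_VOCAB[[name]], collapse = ", "),
                   deparse(v)), call. = FALSE)
  } else if (name %in% c("tumor_thickness_breslow", "mitotic_rate",
                         "age_at_primary_diagnosis")) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("'%s' must be a non-negative number", name), call. = FALSE)
  } else if (name == "date_of_first_diagnosis") {
    if (!inherits(v, "Date")) pv$value <- parse_iso_date(as.character(v))
  }
  pv
}

#' @export
print.clinical_parameters <- function(x, ...) {
  cat("<clinical_parameters>\n")
  for (nm in names(x)) {
    pv <- x[[nm]]
    val <- if (pv$availability == "present") {
      paste(format(pv$value), pv$unit %||% "")
    } else sprintf("<%s>", pv$availability)
    cat(sprintf("  %-34s %s\n", nm, val))
  }
  invisible(x)
}

# ---- bundles -----------------------------------------------------------

new_bundle <- function(patient_id, resources, individualized = FALSE) {
  structure(list(patient_id = patient_id,
                 individualized = isTRUE(individualized),
                 resources = resources),
            class = "patient_bundle")
}

validate_bundle <- function(bundle, path = "<bundle>") {
  pid <- bundle$patient_id
  if (!is.character(pid) || length(pid) != 1L || !nzchar(pid))
    stop(sprintf("%s: patient_id must be a non-empty string", path),
         call. = FALSE)
  res <- bundle$resources
  if (!is.list(res)) stop(sprintf("%s: 'resources' must be a list", path),
                          call. = FALSE)
  kinds <- vapply(res, function(r) as.character(r$kind %||% NA_character_),
                  character(1))
  if (sum(kinds == "patient-demographics", na.rm = TRUE) != 1L)
    stop(sprintf("%s: bundle must contain exactly one patient-demographics entry",
                 path), call. = FALSE)
  for (i in seq_along(res)) {
    d <- res[[i]]$date
    if (!is.null(d)) parse_iso_date(as.character(d))
    bd <- res[[i]]$birth_date
    if (!is.null(bd)) parse_iso_date(as.character(bd))
  }
  invisible(bundle)
}

#' Read a FHIR-style patient bundle from a JSON file
#'
#' One file per patient. Resource kinds outside the supported set
#' (`patient-demographics`, `condition`, `observation`, `procedure`,
#' `diagnostic-report`, `episode-of-care`) are retained but flagged as
#' unmapped in the `unmapped_kinds` attribute.
#'
#' @param path path to a JSON bundle file
#' @return a validated `patient_bundle`
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("malformed JSON in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  b <- new_bundle(raw$patient_id %||% "", raw$resources %||% list(),
                  raw$individualized %||% FALSE)
  validate_bundle(b, path)
  kinds <- vapply(b$resources, function(r) as.character(r$kind %||% ""),
                  character(1))
  attr(b, "unmapped_kinds") <- sort(unique(kinds[!kinds %in% KNOWN_RESOURCE_KINDS]))
  b
}

#' Write a patient bundle as JSON
#'
#' Inverse of [read_bundle()]: `read_bundle(write_bundle(b, f))` is
#' semantically identical to `b`.
#'
#' @param bundle a `patient_bundle`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  jsonlite::write_json(
    list(patient_id = bundle$patient_id,
         individualized = bundle$individualized,
         resources = bundle$resources),
    path, auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- extraction rule table ---------------------------------------------

#' Read an extraction-rule table
#'
#' The mapping from parameter names to bundle resources (resource kind +
#' code + value type) is configuration, not code, so the clinical content
#' can be revised without touching the engine. The shipped default
#' (`system.file("extdata", "default_mapping.json", package = "melpathsim")`)
#' covers all 16 parameters; it is a reconstruction by parameter name, as
#' the source SOP's own query catalogue is not public.
#'
#' @param path path to a mapping JSON file; default: the shipped mapping
#' @return a `data.frame` with class `extraction_mapping`
#' @export
read_mapping <- function(path = system.file("extdata", "default_mapping.json",
                                            package = "melpathsim")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- raw$parameters
  need <- c("parameter", "resource_kind", "code", "value_type")
  m <- do.call(rbind, lapply(rules, function(r) {
    miss <- setdiff(need, names(r))
    if (length(miss))
      stop("mapping rule missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    data.frame(parameter = r$parameter, resource_kind = r$resource_kind,
               code = r$code, value_type = r$value_type,
               unit = r$unit %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  missing_params <- setdiff(parameter_names(), m$parameter)
  if (length(missing_params))
    stop("mapping does not cover parameter(s): ",
         paste(missing_params, collapse = ", "), call. = FALSE)
  if (anyDuplicated(m$parameter))
    stop("duplicate mapping rule for: ",
         paste(unique(m$parameter[duplicated(m$parameter)]), collapse = ", "),
         call. = FALSE)
  structure(m, class = c("extraction_mapping", "data.frame"))
}

coerce_extracted_value <- function(value, value_type) {
  switch(value_type,
    quantity = as.numeric(value),
    integer = as.numeric(value),
    code = as.character(value),
    date = parse_iso_date(as.character(value)),
    boolean = isTRUE(value) || identical(value, "true"),
    stop("unknown value_type: ", value_type, call. = FALSE))
}

#' Extract the 16 clinical parameters from a bundle
#'
#' For each parameter the mapping names the resource kind and code to look
#' for. When several dated candidates exist the most recent effective date
#' wins; two candidates with the same date but conflicting values raise an
#' ambiguity error (silent resolution would hide exactly the data-quality
#' faults the pipeline is meant to surface). A matching resource with a
#' `null` value yields availability `unknown`; no matching resource yields
#' `absent`. Age at primary diagnosis falls back to whole completed years
#' between the demographics birth date and the date of first diagnosis when
#' not recorded directly.
#'
#' @param bundle a validated `patient_bundle`
#' @param mapping an `extraction_mapping` (default: shipped mapping)
#' @return a `clinical_parameters` object
#' @export
extract_parameters <- function(bundle, mapping = read_mapping()) {
  stopifnot(inherits(bundle, "patient_bundle"))
  if (!inherits(mapping, "extraction_mapping"))
    stop("'mapping' must come from read_mapping()", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(mapping))) {
    rule <- mapping[i, ]
    out[[rule$parameter]] <- extract_one(bundle, rule)
  }
  # derived fallback for age: birth date -> completed years at first diagnosis
  if (!is_present(out$age_at_primary_diagnosis) &&
      is_present(out$date_of_first_diagnosis)) {
    demo <- Filter(function(r) identical(r$kind, "patient-demographics"),
                   bundle$resources)[[1]]
    if (!is.null(demo$birth_date)) {
      age <- completed_years(parse_iso_date(demo$birth_date),
                             out$date_of_first_diagnosis$value)
      out$age_at_primary_diagnosis <- param_value(as.numeric(age), unit = "years")
    }
  }
  # sex lives on the demographics entry, not a coded observation
  if (!is_present(out$sex)) {
    demo <- Filter(function(r) identical(r$kind, "patient-demographics"),
                   bundle$resources)[[1]]
    if (!is.null(demo$sex)) out$sex <- param_value(as.character(demo$sex))
  }
  do.call(clinical_parameters, out)
}

extract_one <- function(bundle, rule) {
  cand <- Filter(function(r) {
    identical(as.character(r$kind %||% ""), rule$resource_kind) &&
      identical(as.character(r$code %||% ""), rule$code)
  }, bundle$resources)
  if (length(cand) == 0) return(param_value(NULL, "absent"))
  dates <- vapply(cand, function(r) as.character(r$date %||% NA_character_),
                  character(1))
  d <- suppressWarnings(as.Date(dates, format = "%Y-%m-%d"))
  # undated candidates sort before any dated one
  ord_key <- ifelse(is.na(d), -Inf, as.numeric(d))
  latest <- which(ord_key == max(ord_key))
  if (length(latest) > 1L) {
    vals <- lapply(cand[latest], function(r) r$value)
    uniq <- unique(vapply(vals, function(v) paste(deparse(v), collapse = ""),
                          character(1)))
    if (length(uniq) > 1L)
      stop(sprintf(
        "ambiguous extraction for '%s' (patient %s): %d candidates dated %s with conflicting values: %s",
        rule$parameter, bundle$patient_id, length(latest),
        dates[latest[1]], paste(uniq, collapse = " vs ")), call. = FALSE)
  }
  winner <- cand[[latest[1]]]
  if (is.null(winner$value)) return(param_value(NULL, "unknown"))
  v <- coerce_extracted_value(winner$value, rule$value_type)
  unit <- if (!is.na(rule$unit)) rule$unit else winner$unit
  param_value(v, unit = unit)
}
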