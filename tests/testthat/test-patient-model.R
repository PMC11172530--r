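test_that("a minimal bundle reads and validates", {
  p <- write_bundle_json(minimal_bundle_list())
  b <- read_bundle(p)
  expect_s3_class(b, "patient_bundle")
  expect_equal(b$patient_id, "PT01")
  expect_length(b$resources, 1L)
})

test_that("bundles round-trip through write/read semantically intact", {
  bl <- minimal_bundle_list(extra = list(
    make_resource("observation", "breslow-thickness", 2.1, unit = "mm"),
    make_resource("condition", "ajcc-tumor-stage", "IIIB")))
  b1 <- read_bundle(write_bundle_json(bl))
  out <- tempfile(fileext = ".json")
  write_bundle(b1, out)
  b2 <- read_bundle(out)
  expect_equal(b2$patient_id, b1$patient_id)
  expect_equal(b2$resources, b1$resources)
  expect_equal(b2$individualized, b1$individualized)
})

test_that("invalid bundles are rejected with informative errors", {
  no_demo <- list(patient_id = "PT02", resources = list(
    make_resource("observation", "breslow-thickness", 1.0)))
  expect_error(read_bundle(write_bundle_json(no_demo)),
               "patient-demographics")
  empty_id <- minimal_bundle_list(patient_id = "")
  expect_error(read_bundle(write_bundle_json(empty_id)), "patient_id")
  bad_json <- tempfile(fileext = ".json")
  writeLines('{"patient_id": "PT03", "resources": [', bad_json)
  expect_error(read_bundle(bad_json), "malformed JSON")
  bad_date <- minimal_bundle_list(extra = list(
    make_resource("observation", "breslow-thickness", 1.0,
                  date = "not-a-date")))
  expect_error(read_bundle(write_bundle_json(bad_date)), "ISO 8601")
})

test_that("unknown resource kinds are retained and flagged", {
  bl <- minimal_bundle_list(extra = list(
    make_resource("medication-request", "x", "y")))
  b <- read_bundle(write_bundle_json(bl))
  expect_length(b$resources, 2L)
  expect_equal(attr(b, "unmapped_kinds"), "medication-request")
})

test_that("extraction maps direct observations and flags absence", {
  bl <- minimal_bundle_list(extra = list(
    make_resource("observation", "breslow-thickness", 2.1, unit = "mm")))
  params <- extract_parameters(read_bundle(write_bundle_json(bl)))
  expect_equal(params$tumor_thickness_breslow$value, 2.1)
  expect_equal(params$tumor_thickness_breslow$availability, "present")
  expect_equal(params$tumor_thickness_breslow$unit, "mm")
  # no thickness resource at all -> absent, never an error
  params2 <- extract_parameters(read_bundle(write_bundle_json(
    minimal_bundle_list())))
  expect_equal(params2$tumor_thickness_breslow$availability, "absent")
  # a resource with a null value -> unknown
  bl3 <- minimal_bundle_list(extra = list(
    list(kind = "observation", code = "breslow-thickness", value = NULL,
         date = "2021-03-15", status = "final")))
  params3 <- extract_parameters(read_bundle(write_bundle_json(bl3)))
  expect_equal(params3$tumor_thickness_breslow$availability, "unknown")
})

test_that("repeated observations resolve by most recent effective date", {
  # brute-force oracle: scan candidates for max date
  dates <- c("2020-01-01", "2021-01-01", "2019-06-15")
  values <- c(1.0, 2.0, 0.5)
  oracle <- values[which.max(as.Date(dates))]
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    bl <- minimal_bundle_list(extra = lapply(perm, function(i)
      make_resource("observation", "breslow-thickness", values[i],
                    date = dates[i], unit = "mm")))
    params <- extract_parameters(read_bundle(write_bundle_json(bl)))
    expect_equal(params$tumor_thickness_breslow$value, oracle)
  }
})

test_that("identical-date conflicting candidates raise an ambiguity error", {
  bl <- minimal_bundle_list(extra = list(
    make_resource("observation", "breslow-thickness", 1.0, date = "2021-01-01"),
    make_resource("observation", "breslow-thickness", 2.0, date = "2021-01-01")))
  expect_error(extract_parameters(read_bundle(write_bundle_json(bl))),
               "ambiguous.*tumor_thickness_breslow.*1.*2")
  # same date, same value: not ambiguous
  bl2 <- minimal_bundle_list(extra = list(
    make_resource("observation", "breslow-thickness", 1.5, date = "2021-01-01"),
    make_resource("observation", "breslow-thickness", 1.5, date = "2021-01-01")))
  expect_equal(
    extract_parameters(read_bundle(write_bundle_json(bl2)))$tumor_thickness_breslow$value,
    1.5)
})

test_that("a mapping not covering all 16 parameters is a configuration error", {
  raw <- jsonlite::fromJSON(system.file("extdata", "default_mapping.json",
                                        package = "melpathsim"),
                            simplifyVector = FALSE)
  raw$parameters <- raw$parameters[-1]
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, p, auto_unbox = TRUE)
  expect_error(read_mapping(p), "does not cover.*age_at_primary_diagnosis")
})

test_that("age falls back to completed years from birth date to first diagnosis", {
  bl <- minimal_bundle_list(extra = list(
    make_resource("condition", "melanoma-first-diagnosis", "2021-03-15")))
  # birth 1966-01-10, diagnosis 2021-03-15 -> 55 completed years
  params <- extract_parameters(read_bundle(write_bundle_json(bl)))
  expect_equal(params$age_at_primary_diagnosis$value, 55)
  # an explicitly recorded age wins over the derivation
  bl2 <- minimal_bundle_list(extra = list(
    make_resource("condition", "melanoma-first-diagnosis", "2021-03-15"),
    make_resource("observation", "age-at-primary-diagnosis", 60)))
  params2 <- extract_parameters(read_bundle(write_bundle_json(bl2)))
  expect_equal(params2$age_at_primary_diagnosis$value, 60)
})

test_that("extraction is total and deterministic over random bundles", {
  set.seed(42)
  mapping <- read_mapping()
  for (i in 1:25) {
    codes <- c("breslow-thickness", "ulceration-status", "braf-status",
               "ajcc-tumor-stage", "melanoma-first-diagnosis", "slne-status")
    vals <- list(round(runif(1, 0, 8), 2), sample(c("yes", "no"), 1),
                 sample(c("mutation", "wildtype"), 1),
                 sample(c("IIIA", "IIIB", "IIIC"), 1),
                 "2020-06-01", sample(c("positive", "negative"), 1))
    kinds <- c("observation", "observation", "observation", "condition",
               "condition", "procedure")
    keep <- runif(6) > 0.4
    extra <- lapply(which(keep), function(j)
      make_resource(kinds[j], codes[j], vals[[j]]))
    b <- read_bundle(write_bundle_json(minimal_bundle_list(extra = extra)))
    p1 <- extract_parameters(b, mapping)
    p2 <- extract_parameters(b, mapping)
    avail <- vapply(p1, function(x) x$availability, character(1))
    expect_true(all(avail %in% c("present", "unknown", "absent")))
    expect_length(avail, 16L)
    expect_identical(p1, p2)
  }
})

test_that("the parameter container enforces its 16-field contract", {
  p <- make_params()
  expect_length(p, 16L)
  expect_named(p, parameter_names())
  expect_error(clinical_parameters(tumor_stage = param_value("III-X")),
               "must be one of")
  expect_error(clinical_parameters(tumor_thickness_breslow = param_value(-1)),
               "non-negative")
  expect_error(clinical_parameters(not_a_field = param_value(1)),
               "unknown parameter")
  expect_error(param_value(NULL, "present"), "requires a value")
  expect_error(param_value(1, "absent"), "availability 'present'")
})
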