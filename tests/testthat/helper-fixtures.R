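# Shared fixture builders: all fixtures are constructed in code.

# A fully specified stage IIIB patient with an SLNE indication; the
# reference case walked by hand through the shipped graph.
make_params <- function(...) {
  defaults <- list(
    age_at_primary_diagnosis = param_value(55, unit = "years"),
    sex = param_value("male"),
    date_of_first_diagnosis = param_value(as.Date("2021-03-15")),
    tumor_thickness_breslow = param_value(2.5, unit = "mm"),
    ulceration_status = param_value("yes"),
    resection_status = param_value("R0"),
    mitotic_rate = param_value(2, unit = "1/mm2"),
    melanoma_setting = param_value("primary"),
    pT = param_value("T3a"),
    lymph_node_sonography = param_value("remarkable"),
    metastasis_detection_clinical = param_value("no"),
    metastasis_detection_radiological = param_value("no"),
    tumor_stage = param_value("IIIB"),
    braf_status = param_value("mutation"),
    slne_status = param_value("positive"),
    capsular_breakthrough = param_value("no"))
  do.call(clinical_parameters, modifyList(defaults, list(...)))
}

absent <- function() param_value(NULL, "absent")

make_resource <- function(kind, code, value, date = "2021-03-15",
                          unit = NULL) {
  r <- list(kind = kind, code = code, value = value, date = date,
            status = "final")
  if (!is.null(unit)) r$unit <- unit
  r
}

minimal_bundle_list <- function(patient_id = "PT01", extra = list()) {
  list(patient_id = patient_id,
       individualized = FALSE,
       resources = c(list(list(kind = "patient-demographics",
                               code = "demographics", sex = "male",
                               birth_date = "1966-01-10",
                               date = "2021-03-15", status = "final")),
                     extra))
}

write_bundle_json <- function(bundle_list, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(bundle_list, path, auto_unbox = TRUE, null = "null")
  path
}

write_graph_json <- function(graph_list, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(graph_list, path, auto_unbox = TRUE, null = "null")
  path
}

# smallest valid graph: start -> end, zero decision points
toy_linear_graph <- function() {
  list(name = "toy", version = "1", entry = "start",
       nodes = list(
         list(id = "start", kind = "start", `next` = "end"),
         list(id = "end", kind = "end", end_class = "regular",
              label = "done")))
}

# one-gateway toy graph branching on Breslow thickness
toy_decision_graph <- function() {
  list(name = "toy-dp", version = "1", entry = "start",
       nodes = list(
         list(id = "start", kind = "start", `next` = "D1"),
         list(id = "D1", kind = "decision", question = "thick?",
              required_params = list("tumor_thickness_breslow"),
              rules = list(
                list(branch = "thick",
                     when = list(param = "tumor_thickness_breslow",
                                 op = "gt", value = 1)),
                list(branch = "thin", when = TRUE)),
              branches = list(thick = "end_a", thin = "end_b")),
         list(id = "end_a", kind = "end", end_class = "regular", label = "a"),
         list(id = "end_b", kind = "end", end_class = "regular", label = "b")))
}

# follow-up loop graph: the loop edge is marked and guarded by a
# year-bound predicate, the only legal form of cycle
toy_loop_graph <- function() {
  list(name = "toy-loop", version = "1", entry = "start",
       nodes = list(
         list(id = "start", kind = "start", `next` = "DY"),
         list(id = "DY", kind = "decision", question = "year >= 3?",
              required_params = list("date_of_first_diagnosis"),
              rules = list(
                list(branch = "yes",
                     when = list(param = "date_of_first_diagnosis",
                                 op = "followup_ge", value = 3)),
                list(branch = "no", when = TRUE)),
              branches = list(yes = "end", no = "task_year")),
         list(id = "task_year", kind = "task", label = "next year",
              followup_loop = TRUE, `next` = "DY"),
         list(id = "end", kind = "end", end_class = "regular",
              label = "done")))
}

# random parameter instance: every field independently present / unknown /
# absent, with in-vocabulary values when present
random_params <- function() {
  vocab <- list(
    sex = c("female", "male"),
    ulceration_status = c("yes", "no", "unknown"),
    resection_status = c("R0", "R1"),
    melanoma_setting = c("primary", "locoregional", "distant-metastatic",
                         "non-resectable"),
    pT = c("T0", "T1a", "T1b", "T2a", "T2b", "T3a", "T3b", "T4a", "T4b"),
    lymph_node_sonography = c("unremarkable", "remarkable"),
    metastasis_detection_clinical = c("yes", "no"),
    metastasis_detection_radiological = c("yes", "no"),
    tumor_stage = c("0", "IA", "IB", "IIA", "IIB", "IIC",
                    "IIIA", "IIIB", "IIIC", "IIID", "IV"),
    braf_status = c("mutation", "wildtype", "unknown"),
    slne_status = c("positive", "negative", "not-performed"),
    capsular_breakthrough = c("yes", "no"))
  args <- list()
  for (nm in parameter_names()) {
    state <- sample(c("present", "unknown", "absent"), 1,
                    prob = c(0.6, 0.2, 0.2))
    if (state != "present") {
      args[[nm]] <- param_value(NULL, state)
    } else if (nm %in% names(vocab)) {
      args[[nm]] <- param_value(sample(vocab[[nm]], 1))
    } else if (nm == "date_of_first_diagnosis") {
      args[[nm]] <- param_value(as.Date("2018-01-01") +
                                  sample.int(2000, 1))
    } else {
      args[[nm]] <- param_value(round(runif(1, 0, 10), 2))
    }
  }
  do.call(clinical_parameters, args)
}

# random one-decision-point survey table for oracle checks
random_survey <- function(dp = "DPX", n_params = 8) {
  data.frame(
    dp = dp,
    parameter = paste0("p", seq_len(n_params)),
    display_name = paste0("p", seq_len(n_params)),
    algorithm_usage = sample(c("explicit", "implicit", "unused", "additional"),
                             n_params, replace = TRUE),
    relevance_pct = round(runif(n_params, 0, 100), 1),
    respondents = 9,
    stringsAsFactors = FALSE)
}
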