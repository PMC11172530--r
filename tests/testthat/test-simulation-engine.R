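golden_node_sequence <- c(
  # hand-walked path of the reference stage IIIB patient (make_params())
  # through the shipped graph: SLNE indication -> positive sentinel ->
  # tumor conference -> targeted adjuvant therapy -> year-3 follow-up
  "start", "DP1", "DP2", "DP3", "task_safety_margin_excision", "DP4",
  "DP5", "DP7", "DP8", "task_tumor_markers_check", "DP9", "DP12", "DP13",
  "DP14", "DP15", "chk_individualized", "DP16", "task_adjuvant_option",
  "task_study_screening", "task_followup_plan", "join_dp16", "DP17",
  "DP18", "task_staging_imaging", "DP10.2", "DP19", "DP20", "DP21",
  "task_adjuvant_admin", "task_followup_care", "DP23", "DP24", "DP25",
  "DP27", "end_ongoing_followup")

test_that("a trivial graph yields a two-step completed trace", {
  g <- load_graph(write_graph_json(toy_linear_graph()))
  tr <- traverse(make_params(), g)
  expect_equal(nrow(tr$steps), 2L)
  expect_equal(tr$steps$step_kind, c("task", "end-event"))
  expect_equal(tr$status, "completed")
})

test_that("the reference patient follows the hand-walked golden path", {
  g <- load_graph()
  tr <- traverse(make_params(), g, simulation_config(), patient_id = "GOLD01")
  visited <- tr$steps$node_id[tr$steps$step_kind %in%
                                c("task", "gateway", "end-event")]
  expect_equal(visited, golden_node_sequence)
  branches <- tr$steps$branch_label[tr$steps$step_kind == "outgoing-sequence"]
  expect_equal(branches, c(
    "slne-consultation", "yes", "r0", "r0", "no", "gt-0.75",
    "slne-indicated", "remarkable", "no", "yes", "positive", "no",
    "adjuvant-therapy", "study-inclusion", "guideline-compliant-followup",
    "indicated", "targeted-therapy", "yes", "no", "targeted",
    "dabrafenib-trametinib", "stage-iii-or-higher", "year-1-3", "no", "no"))
  expect_equal(tr$status, "completed")
})

test_that("gateway visits snapshot every declared parameter", {
  g <- load_graph()
  tr <- traverse(make_params(), g)
  st <- tr$steps
  dp2_rows <- st[st$node_id == "DP2" & st$step_kind == "parameters-used", ]
  expect_setequal(dp2_rows$parameter_name,
                  c("ulceration_status", "tumor_thickness_breslow"))
  expect_equal(dp2_rows$availability, rep("present", 2))
  expect_true("2.5" %in% dp2_rows$parameter_value)
  # each single-select gateway emits exactly one outgoing sequence
  gw_ids <- st$node_id[st$step_kind == "gateway"]
  for (id in setdiff(gw_ids, "DP16"))
    expect_equal(sum(st$step_kind == "outgoing-sequence" & st$node_id == id),
                 1L, label = id)
  expect_equal(sum(st$step_kind == "outgoing-sequence" & st$node_id == "DP16"),
               3L)
  expect_true(all(diff(st$ordinal) == 1L))
})

test_that("missing thickness aborts at the first gateway that needs it", {
  g <- load_graph()
  tr <- traverse(make_params(tumor_thickness_breslow = absent(),
                             ulceration_status = param_value("no")), g)
  expect_equal(tr$status, "aborted-missing-data")
  expect_equal(tr$missing_params, "tumor_thickness_breslow")
  # DP1 declares a cannot-determine branch, so the trace leaves through it
  st <- tr$steps
  expect_equal(st$branch_label[st$step_kind == "outgoing-sequence"],
               "cannot-determine")
  expect_equal(st$node_id[nrow(st)], "end_data_incomplete")
})

test_that("the individualized override routes to the preliminary end", {
  g <- load_graph()
  tr <- traverse(make_params(), g, individualized = TRUE)
  expect_equal(tr$status, "preliminary-end")
  expect_equal(tr$steps$node_id[nrow(tr$steps)], "end_individualized")
  expect_false("DP16" %in% tr$steps$node_id)
})

test_that("cohort simulation conserves flow and visits DP1 once per patient", {
  g <- load_graph()
  spec <- default_spec(seed = 11)
  bundles <- generate_cohort(spec)
  sim <- simulate_cohort(bundles, g)
  expect_equal(sim$summary$cohort_size, 67L)
  expect_equal(unname(sim$summary$decision_point_visits["DP1"]), 67L)
  expect_true(check_flow_conservation(sim$summary, g))
  expect_length(sim$errors, 0L)
  # empty cohort
  sim0 <- simulate_cohort(list(), g)
  expect_equal(sim0$summary$cohort_size, 0L)
  expect_length(sim0$traces, 0L)
  expect_equal(sum(sim0$summary$node_visits), 0L)
})

test_that("patients lacking thickness abort and are counted exactly", {
  g <- load_graph()
  spec <- default_spec(seed = 3)
  spec$missingness[["tumor_thickness_breslow"]] <- 1
  bundles <- generate_cohort(spec)
  sim <- simulate_cohort(bundles, g)
  # MUP patients (pT = T0) never need thickness; everyone else who is not
  # routed by ulceration alone must abort on it
  statuses <- vapply(sim$traces, function(t) t$status, character(1))
  needs_thickness <- vapply(sim$traces, function(t)
    "tumor_thickness_breslow" %in% t$missing_params, logical(1))
  expect_equal(sum(statuses == "aborted-missing-data"), sum(needs_thickness))
  pts <- vapply(bundles, function(b)
    extract_parameters(b)$pT$value, character(1))
  names(pts) <- vapply(bundles, function(b) b$patient_id, character(1))
  expect_true(all(statuses[pts[names(statuses)] == "T0"] != "aborted-missing-data"))
  expect_true(sum(statuses == "aborted-missing-data") > 0)
  expect_true(check_flow_conservation(sim$summary, g))
})

test_that("cohort output is invariant under patient permutation and rerun", {
  g <- load_graph()
  bundles <- generate_cohort(default_spec(n = 67, seed = 5))
  sim1 <- simulate_cohort(bundles, g)
  set.seed(99)
  sim2 <- simulate_cohort(sample(bundles), g)
  sim3 <- simulate_cohort(bundles, g)
  expect_identical(sim1$summary, sim2$summary)
  expect_identical(sim1$traces, sim2$traces)
  expect_identical(sim1$summary, sim3$summary)
})

test_that("adding missingness never lengthens a patient's trace", {
  g <- load_graph()
  base <- make_params()
  tr_full <- traverse(base, g)
  set.seed(13)
  for (i in 1:12) {
    degraded <- base
    drop <- sample(parameter_names(), sample(1:4, 1))
    args <- setNames(lapply(drop, function(x) absent()), drop)
    degraded <- do.call(make_params, args)
    tr <- traverse(degraded, g)
    expect_lte(nrow(tr$steps), nrow(tr_full$steps))
  }
})

test_that("the summary recomputed from traces equals the incremental one", {
  g <- load_graph()
  bundles <- generate_cohort(default_spec(seed = 21))
  sim <- simulate_cohort(bundles, g)
  oracle <- summarize_traces(sim$traces, g)
  expect_equal(oracle$node_visits, sim$summary$node_visits)
  expect_equal(oracle$branch_counts, sim$summary$branch_counts)
  expect_equal(oracle$end_event_counts, sim$summary$end_event_counts)
  expect_equal(oracle$decision_point_visits, sim$summary$decision_point_visits)
  expect_equal(oracle$status_counts, sim$summary$status_counts)
})

test_that("trace CSV export is schema-stable and byte-identical across runs", {
  g <- load_graph(write_graph_json(toy_decision_graph()))
  tr <- traverse(make_params(), g, patient_id = "T1")
  p1 <- tempfile(fileext = ".csv")
  write_traces_csv(list(tr), p1)
  df <- read_traces_csv(p1)
  expect_equal(names(df),
               c("patient_id", "ordinal", "step_kind", "node_id",
                 "branch_label", "parameter_name", "parameter_value",
                 "availability"))
  expect_equal(sum(df$step_kind == "parameters-used"), 1L)
  p2 <- tempfile(fileext = ".csv")
  write_traces_csv(list(tr), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the reference patient's trace matches the committed golden CSV", {
  g <- load_graph()
  tr <- traverse(make_params(), g, simulation_config(), patient_id = "GOLD01")
  p <- tempfile(fileext = ".csv")
  write_traces_csv(list(tr), p)
  golden <- test_path("golden_trace.csv")
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(golden, "raw", file.size(golden)))
})

test_that("a year-guarded follow-up loop advances and terminates", {
  g <- load_graph(write_graph_json(toy_loop_graph()))
  cfg <- simulation_config(reference_date = "2023-10-26")
  params <- make_params(
    date_of_first_diagnosis = param_value(as.Date("2023-01-01")))  # year 1
  tr <- traverse(params, g, cfg)
  expect_equal(tr$status, "completed")
  # two loop passes lift the simulated year from 1 to 3
  expect_equal(sum(tr$steps$node_id == "task_year" &
                     tr$steps$step_kind == "task"), 2L)
  expect_equal(sum(tr$steps$node_id == "DY" &
                     tr$steps$step_kind == "gateway"), 3L)
})
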