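# Pathway traversal: walks one patient's clinical parameters through the
# graph, recording every task, gateway, consulted parameter, chosen branch
# and end event as an execution-trace row, then aggregates cohort-level
# pass counts with flow-conservation accounting.

TRACE_COLS <- c("patient_id", "ordinal", "step_kind", "node_id",
                "branch_label", "parameter_name", "parameter_value",
                "availability")

format_param_value <- function(pv) {
  if (!is_present(pv)) return(NA_character_)
  v <- pv$value
  if (inherits(v, "Date")) format(v, "%Y-%m-%d") else as.character(v)
}

trace_row <- function(patient_id, ordinal, step_kind, node_id,
                      branch_label = NA_character_,
                      parameter_name = NA_character_,
                      parameter_value = NA_character_,
                      availability = NA_character_) {
  data.frame(patient_id = patient_id, ordinal = ordinal,
             step_kind = step_kind, node_id = node_id,
             branch_label = branch_label, parameter_name = parameter_name,
             parameter_value = parameter_value, availability = availability,
             stringsAsFactors = FALSE)
}

#' Traverse one patient through the pathway graph
#'
#' Deterministic for fixed inputs. Every visited gateway contributes one
#' `parameters-used` trace row per declared required parameter (the
#' parameter snapshot). Traversal halts at the first missing-data outcome:
#' when the gateway declares a `missing_branch` the trace leaves through it
#' to its (preliminary) end event, otherwise it ends in place; either way
#' the terminal status is `aborted-missing-data`. Traversing a marked
#' follow-up loop edge advances the simulated follow-up year by one; a step
#' budget guards against malformed cyclic configs.
#'
#' @param params a `clinical_parameters` object
#' @param graph a validated `pathway_graph`
#' @param config a `sim_config`
#' @param patient_id id recorded in the trace rows
#' @param individualized route the patient to the preliminary end at the
#'   individualized-treatment checkpoint (the study does not publish how
#'   such patients were detected, so this is an explicit per-patient flag)
#' @return an `execution_trace`: list with `patient_id`, `steps`
#'   (a data.frame of trace rows), `status` (one of `completed`,
#'   `preliminary-end`, `aborted-missing-data`) and `missing_params`
#' @export
traverse <- function(params, graph, config = simulation_config(),
                     patient_id = "patient", individualized = FALSE) {
  stopifnot(inherits(params, "clinical_parameters"),
            inherits(graph, "pathway_graph"))
  steps <- list()
  n_steps <- 0L
  add <- function(...) {
    n_steps <<- n_steps + 1L
    steps[[n_steps]] <<- trace_row(patient_id, n_steps, ...)
  }
  budget <- 20L * length(graph$nodes) + 100L
  cur <- graph$entry
  aborted <- FALSE
  missing_params <- character(0)
  status <- NULL
  visited_path <- character(0)
  while (is.null(status)) {
    if (n_steps > budget)
      stop(sprintf("step budget exceeded; probable unguarded cycle near: %s",
                   paste(utils::tail(visited_path, 8), collapse = " -> ")),
           call. = FALSE)
    node <- graph$nodes[[cur]]
    visited_path <- c(visited_path, cur)
    if (node$kind %in% c("start", "task")) {
      add("task", node$id)
      if (isTRUE(node$followup_loop))
        config$year_offset <- (config$year_offset %||% 0L) + 1L
      cur <- node$`next`
    } else if (node$kind == "checkpoint") {
      add("task", node$id)
      cur <- if (isTRUE(individualized)) node$preliminary else node$`next`
    } else if (node$kind == "decision") {
      add("gateway", node$id)
      for (p in as.character(unlist(node$required_params)))
        add("parameters-used", node$id, parameter_name = p,
            parameter_value = format_param_value(params[[p]]),
            availability = params[[p]]$availability)
      res <- evaluate_decision(node, params, config)
      if (res$outcome == "missing") {
        aborted <- TRUE
        missing_params <- res$missing_params
        if (!is.null(node$missing_branch)) {
          add("outgoing-sequence", node$id, branch_label = node$missing_branch)
          cur <- node$branches[[node$missing_branch]]
        } else {
          add("end-event", node$id)
          status <- "aborted-missing-data"
        }
      } else if (isTRUE(node$multi_select)) {
        for (lab in res$branches) {
          add("outgoing-sequence", node$id, branch_label = lab)
          branch_task <- graph$nodes[[node$branches[[lab]]]]
          add("task", branch_task$id)
        }
        cur <- node$join
      } else {
        lab <- res$branches
        add("outgoing-sequence", node$id, branch_label = lab)
        cur <- node$branches[[lab]]
      }
    } else if (node$kind == "end") {
      add("end-event", node$id)
      status <- if (aborted) "aborted-missing-data"
                else if (identical(node$end_class, "preliminary")) "preliminary-end"
                else "completed"
    }
  }
  structure(list(patient_id = patient_id,
                 steps = do.call(rbind, steps[seq_len(n_steps)]),
                 status = status,
                 missing_params = missing_params),
            class = "execution_trace")
}

#' @export
print.execution_trace <- function(x, ...) {
  cat(sprintf("<execution_trace %s: %d steps, %s>\n",
              x$patient_id, nrow(x$steps), x$status))
  invisible(x)
}

node_dp_tags <- function(graph) {
  dec <- Filter(function(n) n$kind == "decision", graph$nodes)
  setNames(vapply(dec, function(n) as.character(n$dp %||% n$id), character(1)),
           vapply(dec, function(n) n$id, character(1)))
}

#' Simulate a whole cohort through the pathway
#'
#' One trace per patient. Patients are processed in patient-id order so the
#' output is invariant under permutation of the input bundles. An
#' extraction ambiguity in one bundle is collected under its patient id and
#' the run continues for the other patients.
#'
#' @param bundles list of `patient_bundle` objects
#' @param graph a validated `pathway_graph`
#' @param mapping an `extraction_mapping`
#' @param config a `sim_config`
#' @return a `cohort_simulation`: list with `traces` (named by patient id),
#'   `summary` (a `cohort_summary`), and `errors` (named extraction errors)
#' @export
simulate_cohort <- function(bundles, graph, mapping = read_mapping(),
                            config = simulation_config()) {
  ids <- vapply(bundles, function(b) b$patient_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate patient_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bundles <- bundles[order(ids)]
  ids <- sort(ids)
  traces <- list()
  errors <- list()
  # incremental counters, cross-checked against summarize_traces() in tests
  dp_tags <- node_dp_tags(graph)
  node_visits <- integer(0)
  branch_counts <- integer(0)
  abort_counts <- integer(0)
  end_counts <- integer(0)
  status_counts <- c(completed = 0L, `preliminary-end` = 0L,
                     `aborted-missing-data` = 0L)
  bump <- function(tab, key) {
    cur <- if (key %in% names(tab)) tab[[key]] else 0L
    tab[[key]] <- cur + 1L
    tab
  }
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    params <- tryCatch(extract_parameters(b, mapping), error = function(e) e)
    if (inherits(params, "error")) {
      errors[[b$patient_id]] <- conditionMessage(params)
      next
    }
    tr <- traverse(params, graph, config, patient_id = b$patient_id,
                   individualized = b$individualized)
    traces[[b$patient_id]] <- tr
    st <- tr$steps
    for (j in seq_len(nrow(st))) {
      k <- st$step_kind[j]; nd <- st$node_id[j]
      if (k == "gateway") node_visits <- bump(node_visits, nd)
      if (k == "outgoing-sequence")
        branch_counts <- bump(branch_counts, paste0(nd, "::", st$branch_label[j]))
      if (k == "end-event") end_counts <- bump(end_counts, nd)
    }
    if (tr$status == "aborted-missing-data") {
      gw <- st$node_id[max(which(st$step_kind == "gateway"))]
      dp_node <- graph$nodes[[gw]]
      if (is.null(dp_node$missing_branch)) abort_counts <- bump(abort_counts, gw)
    }
    status_counts[tr$status] <- status_counts[tr$status] + 1L
  }
  summ <- new_cohort_summary(length(bundles), dp_tags, node_visits,
                             branch_counts, abort_counts, end_counts,
                             status_counts)
  structure(list(traces = traces, summary = summ, errors = errors),
            class = "cohort_simulation")
}

new_cohort_summary <- function(n, dp_tags, node_visits, branch_counts,
                               abort_counts, end_counts, status_counts) {
  tags <- unique(unname(dp_tags))
  dp_visits <- if (length(tags)) {
    setNames(vapply(tags, function(tag) {
      as.integer(sum(node_visits[names(dp_tags)[dp_tags == tag]], na.rm = TRUE))
    }, integer(1)), tags)
  } else setNames(integer(0), character(0))
  sort_named <- function(x) {
    if (!length(x)) return(setNames(integer(0), character(0)))
    x[order(names(x))]
  }
  structure(list(cohort_size = n,
                 decision_point_visits = sort_named(dp_visits),
                 node_visits = sort_named(node_visits),
                 branch_counts = sort_named(branch_counts),
                 abort_counts = sort_named(abort_counts),
                 end_event_counts = sort_named(end_counts),
                 status_counts = status_counts),
            class = "cohort_summary")
}

#' Recompute a cohort summary directly from traces
#'
#' Independent aggregation over the combined trace table; used as the
#' oracle against the engine's incrementally maintained summary.
#'
#' @param traces list of `execution_trace` objects
#' @param graph the `pathway_graph` they were produced on
#' @return a `cohort_summary`
#' @export
summarize_traces <- function(traces, graph) {
  all_steps <- do.call(rbind, lapply(traces, function(t) t$steps))
  dp_tags <- node_dp_tags(graph)
  count_of <- function(df, key) {
    if (is.null(df) || nrow(df) == 0) return(integer(0))
    tab <- table(key)
    setNames(as.integer(tab), names(tab))
  }
  gw <- all_steps[all_steps$step_kind == "gateway", , drop = FALSE]
  og <- all_steps[all_steps$step_kind == "outgoing-sequence", , drop = FALSE]
  ee <- all_steps[all_steps$step_kind == "end-event", , drop = FALSE]
  node_visits <- count_of(gw, gw$node_id)
  branch_counts <- count_of(og, paste0(og$node_id, "::", og$branch_label))
  # in-place aborts: end-events recorded at a decision node
  dec_ids <- names(dp_tags)
  ab <- ee[ee$node_id %in% dec_ids, , drop = FALSE]
  abort_counts <- count_of(ab, ab$node_id)
  end_counts <- count_of(ee[!ee$node_id %in% dec_ids, , drop = FALSE],
                         ee$node_id[!ee$node_id %in% dec_ids])
  statuses <- vapply(traces, function(t) t$status, character(1))
  status_counts <- c(completed = sum(statuses == "completed"),
                     `preliminary-end` = sum(statuses == "preliminary-end"),
                     `aborted-missing-data` = sum(statuses == "aborted-missing-data"))
  new_cohort_summary(length(traces), dp_tags, node_visits, branch_counts,
                     abort_counts, end_counts, status_counts)
}

#' Check flow conservation at every single-select gateway
#'
#' At each single-select decision node, the number of incoming visits must
#' equal the branch outflow plus the in-place missing-data aborts at that
#' node. Violations indicate an engine or config defect.
#'
#' @param summary a `cohort_summary`
#' @param graph the corresponding `pathway_graph`
#' @return `TRUE` invisibly; otherwise stops listing every violated node
#' @export
check_flow_conservation <- function(summary, graph) {
  bad <- character(0)
  for (n in graph$nodes) {
    if (n$kind != "decision" || isTRUE(n$multi_select)) next
    visits <- summary$node_visits[n$id] %||% 0L
    visits <- if (is.na(visits)) 0L else visits
    keys <- paste0(n$id, "::", names(n$branches))
    outflow <- sum(summary$branch_counts[keys], na.rm = TRUE)
    aborts <- summary$abort_counts[n$id]
    aborts <- if (is.null(aborts) || is.na(aborts)) 0L else aborts
    if (visits != outflow + aborts)
      bad <- c(bad, sprintf("%s: %d visits != %d branch + %d abort",
                            n$id, visits, outflow, aborts))
  }
  if (length(bad))
    stop("flow conservation violated at:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: n=%d; %d decision points visited>\n",
              x$cohort_size, length(x$decision_point_visits)))
  cat("status counts:",
      paste(names(x$status_counts), x$status_counts, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Write execution traces to a CSV file
#'
#' One row per trace step, RFC-4180 quoting, stable column order, and
#' byte-identical output across runs for identical inputs.
#'
#' @param traces list of `execution_trace` objects (or a `cohort_simulation`)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "cohort_simulation")) traces <- traces$traces
  if (length(traces) == 0L)
    stop("no traces to write", call. = FALSE)
  combined <- do.call(rbind, lapply(traces, function(t) t$steps))
  combined <- combined[, TRACE_COLS]
  rownames(combined) <- NULL
  data.table::fwrite(combined, path, quote = "auto", eol = "\n",
                     na = "", bom = FALSE)
  invisible(path)
}

#' Read a traces CSV written by [write_traces_csv()]
#'
#' @param path CSV path
#' @return data.frame of trace steps
#' @export
read_traces_csv <- function(path) {
  df <- data.table::fread(path, colClasses = list(character = setdiff(
    TRACE_COLS, "ordinal")), data.table = FALSE, na.strings = "")
  df$ordinal <- as.integer(df$ordinal)
  df[, TRACE_COLS]
}
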