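# The SOP-derived clinical algorithm as a validated, declaratively
# configured graph: typed nodes (start, task, decision, checkpoint, end),
# labeled branches, and a small three-valued predicate language evaluated
# against a patient's clinical parameters.

#' Simulation configuration
#'
#' @param reference_date calendar date at which follow-up years are
#'   evaluated; default 2023-10-26, the study's reference date
#' @param seed non-negative integer seed for downstream cohort generation
#' @param graph_version optional version tag recorded in manifests
#' @return a `sim_config` object
#' @export
simulation_config <- function(reference_date = "2023-10-26", seed = 1L,
                              graph_version = NULL) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer",
                                     call. = FALSE)
  structure(list(reference_date = parse_iso_date(reference_date),
                 seed = seed,
                 graph_version = graph_version,
                 missing_data_policy = "abort_with_preliminary_end",
                 year_offset = 0L),
            class = "sim_config")
}

#' Follow-up year index at a reference date
#'
#' Year n of follow-up begins on the (n-1)-th anniversary of the first
#' diagnosis, so the day of the 5th anniversary already belongs to year 6.
#' This makes the "sixth follow-up year or higher" and "sixth to 10th year"
#' gateway boundaries well-defined.
#'
#' @param date_of_first_diagnosis `Date` (or ISO string)
#' @param reference_date `Date` (or ISO string), not before the diagnosis
#' @return positive integer year index
#' @export
follow_up_year <- function(date_of_first_diagnosis, reference_date) {
  if (!inherits(date_of_first_diagnosis, "Date"))
    date_of_first_diagnosis <- parse_iso_date(date_of_first_diagnosis)
  if (!inherits(reference_date, "Date"))
    reference_date <- parse_iso_date(reference_date)
  if (any(reference_date < date_of_first_diagnosis))
    stop("reference date precedes date of first diagnosis", call. = FALSE)
  completed_years(date_of_first_diagnosis, reference_date) + 1L
}

# ---- condition language -------------------------------------------------
#
# A condition is TRUE, FALSE, a leaf {param, op, value}, or a combinator
# {all: [...]}, {any: [...]}, {not: ...}. Evaluation is Kleene three-valued:
# an unavailable parameter yields NA unless the combinator's outcome is
# already forced (FALSE in an all(), TRUE in an any()). A decision therefore
# aborts only when a parameter actually needed to decide is missing — it
# never guesses.

LEAF_OPS <- c("eq", "ne", "gt", "ge", "lt", "le", "in",
              "stage_ge", "stage_lt",
              "followup_ge", "followup_le", "followup_between")

eval_condition <- function(cond, params, config) {
  if (isTRUE(cond)) return(list(val = TRUE, missing = character(0)))
  if (isFALSE(cond)) return(list(val = FALSE, missing = character(0)))
  if (!is.list(cond)) stop("invalid condition: ", deparse(cond), call. = FALSE)
  if (!is.null(cond$all) || !is.null(cond$any)) {
    parts <- lapply(cond$all %||% cond$any, eval_condition,
                    params = params, config = config)
    vals <- vapply(parts, function(p) p$val, logical(1))
    miss <- unique(unlist(lapply(parts, function(p) p$missing)))
    if (!is.null(cond$all)) {
      v <- if (any(!vals, na.rm = TRUE)) FALSE else if (anyNA(vals)) NA else TRUE
    } else {
      v <- if (any(vals, na.rm = TRUE)) TRUE else if (anyNA(vals)) NA else FALSE
    }
    return(list(val = v, missing = if (is.na(v)) miss else character(0)))
  }
  if (!is.null(cond$not)) {
    p <- eval_condition(cond$not, params, config)
    return(list(val = !p$val, missing = p$missing))
  }
  eval_leaf(cond, params, config)
}

eval_leaf <- function(leaf, params, config) {
  if (is.null(leaf$param) || is.null(leaf$op))
    stop("condition leaf needs 'param' and 'op': ",
         jsonlite::toJSON(leaf, auto_unbox = TRUE), call. = FALSE)
  if (!leaf$op %in% LEAF_OPS)
    stop("unknown condition op: ", leaf$op, call. = FALSE)
  pv <- params[[leaf$param]]
  if (is.null(pv)) stop("condition references unknown parameter: ",
                        leaf$param, call. = FALSE)
  if (!is_present(pv)) return(list(val = NA, missing = leaf$param))
  v <- pv$value
  ref <- leaf$value
  val <- switch(leaf$op,
    eq = if (is.numeric(v)) isTRUE(v == as.numeric(ref))
         else identical(as.character(v), as.character(ref)),
    ne = if (is.numeric(v)) isTRUE(v != as.numeric(ref))
         else !identical(as.character(v), as.character(ref)),
    gt = isTRUE(as.numeric(v) > as.numeric(ref)),
    ge = isTRUE(as.numeric(v) >= as.numeric(ref)),
    lt = isTRUE(as.numeric(v) < as.numeric(ref)),
    le = isTRUE(as.numeric(v) <= as.numeric(ref)),
    `in` = as.character(v) %in% as.character(unlist(ref)),
    stage_ge = stage_rank(as.character(v)) >= stage_rank(as.character(ref)),
    stage_lt = stage_rank(as.character(v)) < stage_rank(as.character(ref)),
    followup_ge = effective_fy(v, config) >= as.numeric(ref),
    followup_le = effective_fy(v, config) <= as.numeric(ref),
    followup_between = {
      y <- effective_fy(v, config)
      b <- as.numeric(unlist(ref))
      y >= b[1] && y <= b[2]
    })
  list(val = val, missing = character(0))
}

effective_fy <- function(diagnosis_date, config) {
  follow_up_year(diagnosis_date, config$reference_date) +
    (config$year_offset %||% 0L)
}

collect_condition_params <- function(cond) {
  if (is.logical(cond)) return(character(0))
  if (!is.list(cond)) return(character(0))
  if (!is.null(cond$all) || !is.null(cond$any))
    return(unique(unlist(lapply(cond$all %||% cond$any,
                                collect_condition_params))))
  if (!is.null(cond$not)) return(collect_condition_params(cond$not))
  as.character(cond$param %||% character(0))
}

# ---- graph loading & validation ----------------------------------------

#' Load and validate a pathway graph configuration
#'
#' The graph is a JSON document listing typed nodes. Validation collects
#' every violated invariant (dangling branch targets, duplicate ids,
#' unreachable nodes, unguarded cycles, predicates referencing undeclared
#' parameters, decisions without a terminal catch-all rule, ...) and reports
#' them all at once.
#'
#' @param path path to a graph JSON file; default: the shipped 27-decision
#'   melanoma pathway
#' @return a validated `pathway_graph`
#' @export
load_graph <- function(path = system.file("extdata", "default_graph.json",
                                          package = "melpathsim")) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("malformed graph JSON in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  g <- structure(list(name = raw$name %||% "pathway",
                      version = raw$version %||% "0",
                      entry = raw$entry,
                      nodes = raw$nodes),
                 class = "pathway_graph")
  names(g$nodes) <- vapply(g$nodes, function(n) as.character(n$id),
                           character(1))
  errs <- validate_graph(g)
  if (length(errs))
    stop("invalid pathway graph '", path, "':\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  g
}

node_targets <- function(node) {
  switch(node$kind,
    start = as.character(node$`next`),
    task = as.character(node$`next`),
    checkpoint = c(as.character(node$`next`), as.character(node$preliminary)),
    decision = as.character(unlist(node$branches)),
    end = character(0),
    stop("unknown node kind: ", node$kind, call. = FALSE))
}

validate_graph <- function(g) {
  errs <- character(0)
  ids <- names(g$nodes)
  if (anyDuplicated(ids))
    errs <- c(errs, paste("duplicate node id:",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  kinds <- vapply(g$nodes, function(n) as.character(n$kind %||% ""), character(1))
  if (sum(kinds == "start") != 1L)
    errs <- c(errs, sprintf("graph must have exactly one start node (found %d)",
                            sum(kinds == "start")))
  if (is.null(g$entry) || !g$entry %in% ids || kinds[g$entry] != "start")
    errs <- c(errs, "entry must name the start node")
  edges <- list()
  for (n in g$nodes) {
    tg <- tryCatch(node_targets(n), error = function(e) {
      errs <<- c(errs, conditionMessage(e)); character(0)
    })
    bad <- setdiff(tg, ids)
    if (length(bad))
      errs <- c(errs, sprintf("node '%s' has edge(s) to nonexistent node(s): %s",
                              n$id, paste(bad, collapse = ", ")))
    for (t in intersect(tg, ids)) edges[[length(edges) + 1L]] <- c(n$id, t)
    if (n$kind == "decision") errs <- c(errs, validate_decision_node(n, g))
    if (n$kind %in% c("start", "task") && length(tg) != 1L)
      errs <- c(errs, sprintf("%s node '%s' must have exactly one successor",
                              n$kind, n$id))
    if (n$kind == "end" &&
        !identical(n$end_class %||% "regular", "regular") &&
        !identical(n$end_class, "preliminary"))
      errs <- c(errs, sprintf("end node '%s' has unknown end_class", n$id))
  }
  if (length(edges) && !length(errs)) {
    em <- do.call(rbind, edges)
    ig <- igraph::graph_from_edgelist(em, directed = TRUE)
    missing_iso <- setdiff(ids, igraph::V(ig)$name)
    reach <- igraph::subcomponent(ig, g$entry, mode = "out")$name
    unreach <- c(setdiff(ids, reach), missing_iso)
    unreach <- setdiff(unreach, g$entry)
    if (length(unreach))
      errs <- c(errs, sprintf("unreachable node(s): %s",
                              paste(sort(unique(unreach)), collapse = ", ")))
    # cycles are only legal through an explicitly marked, year-guarded
    # follow-up loop edge (a task with followup_loop = true)
    loop_tasks <- ids[vapply(g$nodes, function(n) isTRUE(n$followup_loop),
                             logical(1))]
    keep <- !(em[, 1] %in% loop_tasks)
    ig2 <- igraph::graph_from_edgelist(em[keep, , drop = FALSE],
                                       directed = TRUE)
    if (!igraph::is_dag(ig2))
      errs <- c(errs, "graph contains a cycle not routed through a marked follow-up loop edge")
    if (length(loop_tasks)) {
      has_guard <- any(vapply(g$nodes, function(n) {
        n$kind == "decision" &&
          any(grepl("^followup_", condition_ops(n)))
      }, logical(1)))
      if (!has_guard)
        errs <- c(errs, "follow-up loop present but no year-bound (followup_*) guard decision in the graph")
    }
    # every non-end node on some path must be able to terminate: with the
    # loop edges removed the graph is a DAG whose sinks must all be ends
    if (igraph::is_dag(ig2)) {
      outdeg <- igraph::degree(ig2, mode = "out")
      sinks <- names(outdeg)[outdeg == 0]
      # loop tasks look like sinks only because their back-edge was removed
      bad_sinks <- setdiff(sinks[kinds[sinks] != "end"], loop_tasks)
      if (length(bad_sinks))
        errs <- c(errs, sprintf("path dead-ends at non-end node(s): %s",
                                paste(bad_sinks, collapse = ", ")))
    }
  }
  errs
}

condition_ops <- function(node) {
  ops <- character(0)
  walk <- function(cond) {
    if (is.logical(cond) || !is.list(cond)) return()
    if (!is.null(cond$all) || !is.null(cond$any)) {
      lapply(cond$all %||% cond$any, walk); return()
    }
    if (!is.null(cond$not)) { walk(cond$not); return() }
    ops <<- c(ops, as.character(cond$op %||% ""))
  }
  for (r in node$rules) walk(r$when)
  ops
}

validate_decision_node <- function(n, g) {
  errs <- character(0)
  labs <- names(n$branches)
  if (length(labs) < 2L)
    errs <- c(errs, sprintf("decision '%s' must have at least 2 branches", n$id))
  if (anyDuplicated(labs))
    errs <- c(errs, sprintf("decision '%s' has duplicate branch labels", n$id))
  req <- as.character(unlist(n$required_params))
  bad_req <- setdiff(req, parameter_names())
  if (length(bad_req))
    errs <- c(errs, sprintf("decision '%s' requires unknown parameter(s): %s",
                            n$id, paste(bad_req, collapse = ", ")))
  rule_labs <- vapply(n$rules, function(r) as.character(r$branch), character(1))
  bad_labs <- setdiff(rule_labs, labs)
  if (length(bad_labs))
    errs <- c(errs, sprintf("decision '%s' rule(s) name undeclared branch(es): %s",
                            n$id, paste(bad_labs, collapse = ", ")))
  refd <- unique(unlist(lapply(n$rules, function(r)
    collect_condition_params(r$when))))
  undeclared <- setdiff(refd, req)
  if (length(undeclared))
    errs <- c(errs, sprintf(
      "decision '%s' predicate references parameter(s) not in required_params: %s",
      n$id, paste(undeclared, collapse = ", ")))
  if (isTRUE(n$multi_select)) {
    if (is.null(n$join) || !n$join %in% names(g$nodes))
      errs <- c(errs, sprintf("multi-select decision '%s' needs an existing 'join' node", n$id))
    else {
      for (lab in labs) {
        t <- g$nodes[[n$branches[[lab]]]]
        if (is.null(t) || t$kind != "task" || !identical(t$`next`, n$join))
          errs <- c(errs, sprintf(
            "multi-select decision '%s': branch '%s' must target a task whose successor is the join '%s'",
            n$id, lab, n$join))
      }
    }
    if (!any(vapply(n$rules, function(r) isTRUE(r$when), logical(1))))
      errs <- c(errs, sprintf(
        "multi-select decision '%s' needs at least one always-true rule", n$id))
  } else {
    if (length(n$rules) == 0L || !isTRUE(n$rules[[length(n$rules)]]$when))
      errs <- c(errs, sprintf(
        "decision '%s': final rule must be an always-true catch-all", n$id))
  }
  if (!is.null(n$missing_branch) && !n$missing_branch %in% labs)
    errs <- c(errs, sprintf(
      "decision '%s': missing_branch '%s' is not a declared branch",
      n$id, n$missing_branch))
  errs
}

#' Decision points of a graph
#'
#' Nodes of kind `decision`, keyed by decision-point tag. A tag may be
#' shared by more than one node: the MRI-compatibility gateway is consulted
#' twice on the default pathway (before sentinel excision and again before
#' adjuvant therapy), so its two node instances share one tag and cohort
#' pass counts at that tag count visits, not patients.
#'
#' @param graph a `pathway_graph`
#' @return character vector of unique decision-point tags
#' @export
decision_points <- function(graph) {
  dps <- vapply(Filter(function(n) n$kind == "decision", graph$nodes),
                function(n) as.character(n$dp %||% n$id), character(1))
  unique(unname(dps))
}

#' @export
print.pathway_graph <- function(x, ...) {
  kinds <- vapply(x$nodes, function(n) n$kind, character(1))
  cat(sprintf("<pathway_graph '%s' v%s: %d nodes (%d decision points, %d tasks, %d end events)>\n",
              x$name, x$version, length(x$nodes),
              length(decision_points(x)), sum(kinds == "task"),
              sum(kinds == "end")))
  invisible(x)
}

# ---- decision evaluation ------------------------------------------------

#' Evaluate a decision point against a patient's parameters
#'
#' Rules are tried in declared order; the first whose condition is TRUE
#' selects its branch. A condition that cannot be decided because a needed
#' parameter is unavailable yields the missing-data outcome listing the
#' unavailable parameters — the engine never guesses. Multi-select gateways
#' return every branch whose condition holds.
#'
#' @param dp a decision node from a validated `pathway_graph`
#' @param params a `clinical_parameters` object
#' @param config a `sim_config` (needed for follow-up-year predicates)
#' @return a list with `outcome` (`"branch"` or `"missing"`), `branches`
#'   (selected label(s)) and `missing_params`
#' @export
evaluate_decision <- function(dp, params, config = simulation_config()) {
  stopifnot(identical(dp$kind, "decision"),
            inherits(params, "clinical_parameters"))
  if (isTRUE(dp$multi_select)) {
    selected <- character(0)
    for (r in dp$rules) {
      ev <- eval_condition(r$when, params, config)
      if (is.na(ev$val))
        return(list(outcome = "missing", branches = character(0),
                    missing_params = ev$missing))
      if (ev$val) selected <- c(selected, r$branch)
    }
    return(list(outcome = "branch", branches = unique(selected),
                missing_params = character(0)))
  }
  for (r in dp$rules) {
    ev <- eval_condition(r$when, params, config)
    if (is.na(ev$val))
      return(list(outcome = "missing", branches = character(0),
                  missing_params = ev$missing))
    if (ev$val)
      return(list(outcome = "branch", branches = r$branch,
                  missing_params = character(0)))
  }
  # unreachable for validated graphs (catch-all rule enforced at load)
  stop(sprintf("decision '%s': no rule fired", dp$id), call. = FALSE)
}

# ---- DOT export ---------------------------------------------------------

#' Export a pathway graph to Graphviz DOT
#'
#' @param graph a `pathway_graph`
#' @param path output file; when `NULL` the DOT source is returned as a
#'   character scalar
#' @param counts optional named vector of per-node visit counts used to
#'   annotate the diagram (the cohort-flow figure analog)
#' @return DOT source, invisibly when written to `path`
#' @export
graph_to_dot <- function(graph, path = NULL, counts = NULL) {
  esc <- function(s) gsub('"', '\\\\"', s)
  lines <- c(sprintf('digraph "%s" {', esc(graph$name)),
             "  rankdir=TB;",
             "  node [fontsize=10];")
  shape <- c(start = "circle", task = "box", decision = "diamond",
             checkpoint = "box", end = "doublecircle")
  for (n in graph$nodes) {
    lab <- n$question %||% n$label %||% n$id
    if (!is.null(counts) && n$id %in% names(counts))
      lab <- sprintf("%s\\n[n=%d]", lab, counts[[n$id]])
    style <- if (identical(n$end_class, "preliminary"))
      ', style=dashed' else ''
    lines <- c(lines, sprintf('  "%s" [shape=%s, label="%s"%s];',
                              n$id, shape[[n$kind]], esc(lab), style))
  }
  for (n in graph$nodes) {
    if (n$kind == "decision") {
      for (lab in names(n$branches))
        lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                                  n$id, n$branches[[lab]], esc(lab)))
    } else if (n$kind == "checkpoint") {
      lines <- c(lines, sprintf('  "%s" -> "%s";', n$id, n$`next`),
                 sprintf('  "%s" -> "%s" [label="individualized", style=dashed];',
                         n$id, n$preliminary))
    } else if (n$kind %in% c("start", "task")) {
      lines <- c(lines, sprintf('  "%s" -> "%s";', n$id, n$`next`))
    }
  }
  lines <- c(lines, "}")
  src <- paste(lines, collapse = "\n")
  if (is.null(path)) return(src)
  writeLines(src, path)
  invisible(src)
}
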