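# Seeded synthetic cohort generator. Reproduces the study cohort's
# published baseline marginals (n = 67 stage III melanoma patients) exactly
# for count-based characteristics, so the full pipeline is testable without
# the restricted patient-level data. Only the marginals are published: joint
# structure is independent assignment except hard clinical constraints
# (pT = T0 marks melanoma of unknown primary; ulceration and Breslow
# thickness exist only when a primary tumor does; thickness is drawn inside
# its pT band).

#' Default cohort specification (study baseline marginals)
#'
#' Count-based marginals: 67 patients; sex 24 female / 43 male; stage
#' IIIA 2, IIIB 28, IIIC 35, IIID 2; BRAF 29 mutation / 37 wildtype /
#' 1 unknown; pT leaves T0 13, T1a 4, T1b 1, T2a 6, T2b 4, T3a 10, T3b 10,
#' T4a 6, T4b 13 (the printed T1-T4 rows are subtotals of their a/b
#' sub-rows); ulceration 25 yes / 26 no / 16 unknown. Age distribution
#' targets median 60 with interquartile range (48, 70). Twelve patients are
#' flagged for highly individualized treatment.
#'
#' @param n cohort size
#' @param seed generator seed
#' @param missingness named per-parameter missingness rates in `[0, 1]`
#'   (default: all zero — the study cohort's completeness was curated before
#'   simulation)
#' @return a validated `cohort_spec`
#' @export
default_spec <- function(n = 67L, seed = 1L, missingness = NULL) {
  spec <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    sex = c(female = 24L, male = 43L),
    stage = c(IIIA = 2L, IIIB = 28L, IIIC = 35L, IIID = 2L),
    braf = c(mutation = 29L, wildtype = 37L, unknown = 1L),
    pT = c(T0 = 13L, T1a = 4L, T1b = 1L, T2a = 6L, T2b = 4L,
           T3a = 10L, T3b = 10L, T4a = 6L, T4b = 13L),
    ulceration = c(yes = 25L, no = 26L, unknown = 16L),
    age = list(min = 25, q25 = 48, median = 60, q75 = 70, max = 90),
    diagnosis_window = c("2018-11-01", "2023-08-31"),
    n_individualized = 12L,
    # probability-based fields (not published as counts)
    p_sonography_remarkable = 0.45,
    p_slne_positive = 0.6,
    p_capsular_yes = 0.2,
    p_metastasis = 0.05,
    missingness = missingness %||% setNames(rep(0, 16), parameter_names())
  )
  validate_spec(structure(spec, class = "cohort_spec"))
}

validate_spec <- function(spec) {
  n <- spec$n
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer", call. = FALSE)
  for (marg in c("sex", "stage", "braf", "pT", "ulceration")) {
    if (sum(spec[[marg]]) != n)
      stop(sprintf("'%s' marginal counts sum to %d, not n = %d",
                   marg, sum(spec[[marg]]), n), call. = FALSE)
  }
  bad <- names(spec$missingness)[spec$missingness < 0 | spec$missingness > 1]
  if (length(bad))
    stop("missingness rate(s) outside [0,1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(spec$missingness), parameter_names())
  if (length(unknown))
    stop("missingness names unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (spec$n_individualized > n)
    stop("n_individualized exceeds n", call. = FALSE)
  parse_iso_date(spec$diagnosis_window)
  spec
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# piecewise-linear quantile sampler hitting the published median and IQR
sample_ages <- function(n, age) {
  u <- runif(n)
  q <- stats::approx(x = c(0, 0.25, 0.5, 0.75, 1),
                     y = c(age$min, age$q25, age$median, age$q75, age$max),
                     xout = u)$y
  as.integer(round(q))
}

shift_years <- function(date, k) {
  y <- as.integer(format(date, "%Y")) + k
  md <- format(date, "%m-%d")
  md[md == "02-29"] <- "02-28"
  as.Date(sprintf("%04d-%s", y, md))
}

permuted_counts <- function(counts) {
  sample(rep(names(counts), times = counts))
}

thickness_band <- function(pt) {
  # Breslow bands implied by the pT category definitions (mm)
  switch(substr(pt, 1, 2),
         T1 = c(0.2, 1.0), T2 = c(1.01, 2.0),
         T3 = c(2.01, 4.0), T4 = c(4.01, 8.0),
         c(NA_real_, NA_real_))
}

#' Generate a synthetic cohort of patient bundles
#'
#' Count-based marginals are matched exactly for every seed (assignment is
#' a permutation of the specified counts); probability-based fields are
#' Bernoulli draws; ages come from a piecewise-linear quantile model
#' targeting the spec's median/IQR. The same seed always yields the same
#' cohort. Per-parameter missingness removes the corresponding resource
#' from the bundle with the given rate (independently per patient).
#'
#' @param spec a `cohort_spec`, e.g. [default_spec()]
#' @return list of `patient_bundle` objects, length `spec$n`
#' @export
generate_cohort <- function(spec = default_spec()) {
  spec <- validate_spec(spec)
  n <- spec$n
  if (n == 0L) return(list())
  with_seed(spec$seed, {
    ids <- sprintf("SYN%03d", seq_len(n))
    sex <- permuted_counts(spec$sex)
    stage <- permuted_counts(spec$stage)
    braf <- permuted_counts(spec$braf)
    pt <- permuted_counts(spec$pT)
    is_mup <- pt == "T0"
    # ulceration: a missing primary cannot be assessed, so the "unknown"
    # budget is spent on MUP patients first
    ulc <- character(n)
    n_unknown <- spec$ulceration[["unknown"]]
    mup_idx <- which(is_mup)
    unk_mup <- utils::head(mup_idx, n_unknown)
    ulc[unk_mup] <- "unknown"
    remaining <- spec$ulceration
    remaining[["unknown"]] <- remaining[["unknown"]] - length(unk_mup)
    ulc[ulc == ""] <- sample(rep(names(remaining), times = remaining))
    ages <- sample_ages(n, spec$age)
    win <- parse_iso_date(spec$diagnosis_window)
    diag_dates <- win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, n,
                                      replace = TRUE) - 1L
    birth_offsets <- sample.int(300L, n, replace = TRUE) - 1L
    birth_dates <- shift_years(diag_dates, -ages) - birth_offsets
    thickness <- vapply(pt, function(p) {
      b <- thickness_band(p)
      if (anyNA(b)) NA_real_ else round(runif(1, b[1], b[2]), 2)
    }, numeric(1))
    sono <- ifelse(runif(n) < spec$p_sonography_remarkable,
                   "remarkable", "unremarkable")
    slne <- ifelse(is_mup, "not-performed",
                   ifelse(runif(n) < spec$p_slne_positive,
                          "positive", "negative"))
    capsular <- ifelse(runif(n) < spec$p_capsular_yes, "yes", "no")
    met_clin <- ifelse(runif(n) < spec$p_metastasis, "yes", "no")
    met_rad <- ifelse(runif(n) < spec$p_metastasis, "yes", "no")
    mitotic <- round(stats::rgamma(n, shape = 2, scale = 1.5), 1)
    individualized <- seq_len(n) %in% sample.int(n, spec$n_individualized)
    drop_param <- matrix(FALSE, n, 16,
                         dimnames = list(NULL, parameter_names()))
    for (p in parameter_names()) {
      r <- spec$missingness[[p]] %||% 0
      if (r > 0) drop_param[, p] <- runif(n) < r
    }
    lapply(seq_len(n), function(i) {
      build_synthetic_bundle(
        patient_id = ids[i], sex = sex[i], birth_date = birth_dates[i],
        diagnosis_date = diag_dates[i], stage = stage[i], pt = pt[i],
        braf = braf[i], ulceration = ulc[i], thickness = thickness[i],
        sonography = sono[i], slne = slne[i], capsular = capsular[i],
        met_clin = met_clin[i], met_rad = met_rad[i], mitotic = mitotic[i],
        is_mup = is_mup[i], individualized = individualized[i],
        drop = drop_param[i, ])
    })
  })
}

build_synthetic_bundle <- function(patient_id, sex, birth_date,
                                   diagnosis_date, stage, pt, braf,
                                   ulceration, thickness, sonography, slne,
                                   capsular, met_clin, met_rad, mitotic,
                                   is_mup, individualized, drop) {
  iso <- function(d) format(d, "%Y-%m-%d")
  res <- list(list(kind = "patient-demographics", code = "demographics",
                   sex = sex, birth_date = iso(birth_date),
                   date = iso(diagnosis_date), status = "final"))
  obs <- function(kind, code, value, unit = NULL, offset_days = 0L) {
    r <- list(kind = kind, code = code, value = value,
              date = iso(diagnosis_date + offset_days), status = "final")
    if (!is.null(unit)) r$unit <- unit
    r
  }
  add <- function(param, r) {
    if (!isTRUE(drop[[param]])) res[[length(res) + 1L]] <<- r
    res
  }
  res <- add("date_of_first_diagnosis",
             obs("condition", "melanoma-first-diagnosis", iso(diagnosis_date)))
  if (!is.na(thickness))
    res <- add("tumor_thickness_breslow",
               obs("observation", "breslow-thickness", thickness, unit = "mm"))
  res <- add("ulceration_status", obs("observation", "ulceration-status", ulceration))
  res <- add("resection_status",
             obs("procedure", "resection-status", "R0", offset_days = 7L))
  res <- add("mitotic_rate",
             obs("observation", "mitotic-rate", mitotic, unit = "1/mm2"))
  res <- add("melanoma_setting",
             obs("episode-of-care", "melanoma-setting",
                 if (is_mup) "locoregional" else "primary"))
  res <- add("pT", obs("observation", "pt-category", pt))
  res <- add("lymph_node_sonography",
             obs("diagnostic-report", "lymph-node-sonography", sonography,
                 offset_days = 10L))
  res <- add("metastasis_detection_clinical",
             obs("observation", "metastasis-detection-clinical", met_clin,
                 offset_days = 14L))
  res <- add("metastasis_detection_radiological",
             obs("diagnostic-report", "metastasis-detection-radiological",
                 met_rad, offset_days = 14L))
  res <- add("tumor_stage",
             obs("condition", "ajcc-tumor-stage", stage, offset_days = 40L))
  res <- add("braf_status",
             obs("observation", "braf-status", braf, offset_days = 21L))
  res <- add("slne_status",
             obs("procedure", "slne-status", slne, offset_days = 30L))
  res <- add("capsular_breakthrough",
             obs("observation", "capsular-breakthrough", capsular,
                 offset_days = 30L))
  new_bundle(patient_id, res, individualized = individualized)
}

#' Write a cohort of bundles as one JSON file per patient
#'
#' @param bundles list of `patient_bundle` objects
#' @param dir output directory (created if needed)
#' @return character vector of file paths, invisibly
#' @export
write_cohort <- function(bundles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(bundles, function(b) {
    p <- file.path(dir, paste0(b$patient_id, ".json"))
    write_bundle(b, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read all patient bundles from a directory
#'
#' @param dir directory of `*.json` bundle files
#' @return list of `patient_bundle` objects
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  bundles <- lapply(files, read_bundle)
  ids <- vapply(bundles, function(b) b$patient_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate patient_id across bundle files: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bundles
}

#' Machine-readable survey evaluation tables
#'
#' Returns the shipped transcriptions of the point-of-care survey results:
#' `relevance` (per decision point and parameter: algorithm usage mark,
#' survey relevance percentage, respondent count) and `concordance` (per
#' decision point and response option: the simulation's selection, the
#' survey count, respondent count). Transcribed values are unmodified,
#' including the respondent who answered only one option per block.
#'
#' @return list with data.frames `relevance` and `concordance`
#' @export
make_survey_fixture <- function() {
  rel <- utils::read.csv(system.file("extdata", "survey_relevance.csv",
                                     package = "melpathsim"),
                         stringsAsFactors = FALSE)
  conc <- utils::read.csv(system.file("extdata", "survey_concordance.csv",
                                      package = "melpathsim"),
                          stringsAsFactors = FALSE)
  conc$simulation_selected <- as.logical(conc$simulation_selected)
  list(relevance = rel, concordance = conc)
}
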