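#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half-up to a fixed number of decimals
#'
#' Survey percentages in the evaluation layer are reported rounded half-up
#' (so 30.769... prints as 30.8 and 84.615... as 84.6), unlike base
#' [round()], which rounds half to even.
#'
#' @param x numeric vector
#' @param digits number of decimal places (default 1)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against 0.05-style binary representation error
  floor(x * p + 0.5 + 1e-9) / p
}

#' Parse an ISO 8601 calendar date
#'
#' All dates in patient bundles and configs are plain `YYYY-MM-DD` calendar
#' dates; time-of-day has no meaning in the pathway (decision logic operates
#' at day granularity).
#'
#' @param x character scalar/vector
#' @return `Date` vector
#' @export
parse_iso_date <- function(x) {
  if (length(x) == 0) return(as.Date(character(0)))
  bad <- !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- bad | is.na(d)
  if (any(bad)) {
    stop("not a valid ISO 8601 calendar date: ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  d
}

# Completed whole years between two calendar dates (the "birthday" rule:
# the anniversary day itself counts as completed). Feb 29 anniversaries are
# treated as Mar 1 in non-leap years, i.e. not yet completed on Feb 28.
completed_years <- function(from, to) {
  stopifnot(inherits(from, "Date"), inherits(to, "Date"))
  if (any(to < from)) stop("'to' precedes 'from'", call. = FALSE)
  fy <- as.integer(format(from, "%Y"))
  ty <- as.integer(format(to, "%Y"))
  fmd <- format(from, "%m-%d")
  tmd <- format(to, "%m-%d")
  ifelse(tmd >= fmd, ty - fy, ty - fy - 1L)
}

# AJCC 8th-edition stage groups in increasing order of severity; ">= IIC"
# style comparisons use positions in this vector.
AJCC_STAGES <- c("0", "IA", "IB", "IIA", "IIB", "IIC",
                 "IIIA", "IIIB", "IIIC", "IIID", "IV")

stage_rank <- function(stage) {
  r <- match(stage, AJCC_STAGES)
  if (any(is.na(r))) {
    stop("unknown AJCC stage: ", paste(stage[is.na(r)], collapse = ", "),
         call. = FALSE)
  }
  r
}

# Closed vocabularies for coded parameters (Table 1 / survey wording).
PARAM_VOCAB <- list(
  sex = c("female", "male"),
  ulceration_status = c("yes", "no", "unknown"),
  resection_status = c("R0", "R1"),
  melanoma_setting = c("primary", "locoregional", "distant-metastatic",
                       "non-resectable"),
  pT = c("T0", "T1", "T1a", "T1b", "T2", "T2a", "T2b",
         "T3", "T3a", "T3b", "T4", "T4a", "T4b"),
  lymph_node_sonography = c("unremarkable", "remarkable"),
  metastasis_detection_clinical = c("yes", "no"),
  metastasis_detection_radiological = c("yes", "no"),
  tumor_stage = AJCC_STAGES,
  braf_status = c("mutation", "wildtype", "unknown"),
  slne_status = c("positive", "negative", "not-performed"),
  capsular_breakthrough = c("yes", "no")
)

#' Names of the 16 decision-relevant clinical parameters
#'
#' The fixed set of clinical features consumed by the pathway's decision
#' points, in canonical order.
#'
#' @return character vector of length 16
#' @export
parameter_names <- function() {
  c("age_at_primary_diagnosis", "sex", "date_of_first_diagnosis",
    "tumor_thickness_breslow", "ulceration_status", "resection_status",
    "mitotic_rate", "melanoma_setting", "pT", "lymph_node_sonography",
    "metastasis_detection_clinical", "metastasis_detection_radiological",
    "tumor_stage", "braf_status", "slne_status", "capsular_breakthrough")
}
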