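#' Load a clinical score table
#'
#' Reads a comma-separated table of per-patient clinical characteristics:
#' `patient_id`, `months_since_op`, `dbs_target` (`CM_Voi` or `VA_VL`),
#' `ipg_side` (`left`/`right`), `ygtss_tts`, `ygtss_global` and `puts`.
#' The Yale Global Tic Severity Scale total tic score (YGTSS TTS) can never
#' exceed the YGTSS global score (which adds the impairment component), and
#' all scores must be non-negative; violations are validation errors.
#'
#' @param path path to a CSV file with a header row.
#' @return A data frame of class `ClinicalTable`, one row per patient.
#' @export
load_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "months_since_op", "dbs_target", "ipg_side",
                "ygtss_tts", "ygtss_global", "puts")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("clinical table lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(df)) stop("clinical table is empty")
  scores <- c("ygtss_tts", "ygtss_global", "puts", "months_since_op")
  for (s in scores) {
    df[[s]] <- as.numeric(df[[s]])
    if (anyNA(df[[s]]) || any(df[[s]] < 0))
      stop("column `", s, "` must be numeric and non-negative")
  }
  if (any(df$ygtss_tts > df$ygtss_global))
    stop("ygtss_tts exceeds ygtss_global for patient(s): ",
         paste(df$patient_id[df$ygtss_tts > df$ygtss_global], collapse = ", "))
  ok_target <- df$dbs_target %in% c("CM_Voi", "VA_VL")
  if (!all(ok_target))
    stop("unknown dbs_target: ", paste(unique(df$dbs_target[!ok_target]),
                                       collapse = ", "))
  if (!all(df$ipg_side %in% c("left", "right")))
    stop("ipg_side must be 'left' or 'right'")
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Summarise a patient cohort
#'
#' Per-field mean, sample standard deviation (n-1 denominator), minimum and
#' maximum over the numeric columns of a clinical table.
#'
#' @param records a `ClinicalTable` (or any data frame of patient records).
#' @param fields numeric columns to summarise; defaults to all numeric ones.
#' @return A data frame with one row per field and columns
#'   `field`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_cohort <- function(records, fields = NULL) {
  if (nrow(records) < 2L)
    stop("cohort summary needs at least 2 records")
  if (is.null(fields))
    fields <- names(records)[vapply(records, is.numeric, TRUE)]
  rows <- lapply(fields, function(f) {
    v <- records[[f]]
    data.frame(field = f, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), n = length(v))
  })
  do.call(rbind, rows)
}
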