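#' @include notation.R
NULL

## Cohort files: CSV with header patient_id,system,score (UTF-8, comma
## separated) or JSON arrays of records. JSON records may carry the compact
## "score" string or an expanded "findings" array
## ({structure, degree, configuration} for uDISE;
##  {site, grade, flag, configuration} for foreign systems).

.validSystemId <- function(system) {
  system %in% c("UDISE", names(.SYSTEMS))
}

#' Read a cohort file
#'
#' Reads and structurally validates a cohort of scored examinations from
#' CSV (columns `patient_id`, `system`, `score`) or JSON. Patient ids must
#' be nonempty and unique; each record's system must be `UDISE` or one of
#' `foreignSystems()`. Payloads are not parsed here; use
#' [parseCohortRecord()] per record.
#'
#' @param path File path; format is taken from the extension unless given.
#' @param format `"csv"`, `"json"` or `NULL` (guess from extension).
#' @return A data frame with columns `patient_id`, `system`, `score`.
#' @export
readCohort <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  records <- if (format == "json") {
    docs <- jsonlite::read_json(path)
    if (!length(docs)) stop("empty cohort file: ", path, call. = FALSE)
    do.call(rbind, lapply(docs, function(rec) {
      score <- if (!is.null(rec$score)) rec$score
        else if (!is.null(rec$findings)) .findingsToScore(rec)
        else NA_character_
      data.frame(patient_id = if (is.null(rec$patient_id)) NA_character_
                   else as.character(rec$patient_id),
                 system = if (is.null(rec$system)) NA_character_
                   else as.character(rec$system),
                 score = score, stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("patient_id", "system", "score")
    if (!all(need %in% names(df))) {
      stop("cohort CSV must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df[, need]
  }
  if (!nrow(records)) stop("empty cohort file: ", path, call. = FALSE)
  if (anyNA(records$patient_id) || any(!nzchar(records$patient_id))) {
    stop("cohort records must carry a nonempty patient_id", call. = FALSE)
  }
  if (anyDuplicated(records$patient_id)) {
    stop("duplicate patient_id(s): ",
         paste(unique(records$patient_id[duplicated(records$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- !vapply(records$system, .validSystemId, logical(1))
  if (any(bad)) {
    stop("unknown system(s): ",
         paste(unique(records$system[bad]), collapse = ", "), call. = FALSE)
  }
  rownames(records) <- NULL
  records
}

## Expanded JSON findings -> compact score/token string
.findingsToScore <- function(rec) {
  if (identical(rec$system, "UDISE")) {
    prof <- udiseProfile(lapply(rec$findings, function(f)
      siteFinding(f$structure, f$degree,
                  if (is.null(f$configuration)) NA_character_
                  else f$configuration)))
    formatUdise(prof)
  } else {
    paste(vapply(rec$findings, function(f) {
      formatForeignToken(foreignToken(
        rec$system,
        site = if (is.null(f$site)) NA_character_ else f$site,
        grade = if (is.null(f$grade)) NA_integer_ else f$grade,
        flag = if (is.null(f$flag)) NA_character_ else f$flag,
        configuration = if (is.null(f$configuration)) NA_character_
          else f$configuration))
    }, character(1)), collapse = " ")
  }
}

#' Parse one cohort record's payload
#'
#' @param system `"UDISE"` or a foreign system id.
#' @param score The record's score string.
#' @return A [UdiseProfile-class] for `UDISE` records, otherwise a list of
#'   [ForeignToken-class] objects.
#' @export
parseCohortRecord <- function(system, score) {
  if (identical(system, "UDISE")) parseUdise(score)
  else parseForeign(system, score)
}

#' Write a cohort file
#'
#' @param profiles A list of [UdiseProfile-class] objects.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param ids Optional patient ids; defaults to `P0001`, `P0002`, ...
#' @return `path`, invisibly.
#' @export
writeCohort <- function(profiles, path, format = c("csv", "json"),
                        ids = NULL) {
  format <- match.arg(format)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(profiles))
  df <- data.frame(patient_id = ids, system = "UDISE",
                   score = vapply(profiles, formatUdise, character(1)),
                   stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}
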