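# UPDRS examinations and per-item change (delta) records.

#' Construct a UPDRS motor examination
#'
#' One clinician-scored examination: an integer score in 0..4 for every
#' attribute of the schema.
#'
#' @param patient_id Opaque patient identifier (coerced to character).
#' @param exam_date Examination date (`Date` or ISO-8601 string).
#' @param scores Named integer vector or list, one entry per schema attribute,
#'   each in 0..4.
#' @param schema An [updrs_schema()].
#' @return An object of class `updrs_exam`.
#' @export
updrs_exam <- function(patient_id, exam_date, scores, schema = updrs_schema()) {
  stopifnot(inherits(schema, "updrs_schema"))
  exam_date <- as.Date(exam_date)
  if (is.na(exam_date)) stop("invalid exam_date", call. = FALSE)
  scores <- unlist(scores)
  missing_attrs <- setdiff(schema$attributes, names(scores))
  extra <- setdiff(names(scores), schema$attributes)
  if (length(missing_attrs)) {
    stop("missing score for attribute(s): ", paste(missing_attrs, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra)) {
    stop("unknown attribute(s) in scores: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  scores <- scores[schema$attributes]
  check_scores(scores, where = paste0("exam of patient ", patient_id))
  structure(
    list(patient_id = as.character(patient_id), exam_date = exam_date,
         scores = as.integer(scores) |> stats::setNames(schema$attributes),
         schema = schema),
    class = "updrs_exam"
  )
}

check_scores <- function(scores, where = "scores") {
  v <- suppressWarnings(as.numeric(scores))
  if (anyNA(v) || any(v != as.integer(v))) {
    stop("non-integer UPDRS score in ", where, call. = FALSE)
  }
  if (any(v < 0 | v > 4)) {
    stop("UPDRS score out of range 0..4 in ", where, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.updrs_exam <- function(x, ...) {
  cat("UPDRS exam: patient ", x$patient_id, ", ", format(x$exam_date), "\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' Per-attribute change between two examinations
#'
#' Computes `current - historical` for every schema attribute. The result is
#' the condition part of one decision-table row; the expert decision (if any)
#' is attached later.
#'
#' @param historical,current `updrs_exam` objects sharing the same schema;
#'   `historical$exam_date` must not be after `current$exam_date`.
#' @return A `delta_record`: list with `deltas` (named integer vector, each in
#'   -4..4), `decision` (`NA` here), and provenance (`patient_id`,
#'   `historical_date`, `current_date`).
#' @examples
#' sch <- updrs_schema()
#' s <- stats::setNames(rep(1L, 21), sch$attributes)
#' e1 <- updrs_exam("p1", "2010-01-01", s, sch)
#' s["d23RH"] <- 3L
#' e2 <- updrs_exam("p1", "2010-09-01", s, sch)
#' compute_delta(e1, e2)$deltas[["d23RH"]] # 2
#' @export
compute_delta <- function(historical, current) {
  stopifnot(inherits(historical, "updrs_exam"), inherits(current, "updrs_exam"))
  if (!identical(historical$schema$attributes, current$schema$attributes)) {
    stop("schema mismatch between historical and current exam", call. = FALSE)
  }
  if (historical$exam_date > current$exam_date) {
    stop("historical exam is dated after the current exam", call. = FALSE)
  }
  delta_record(
    deltas = current$scores - historical$scores,
    patient_id = current$patient_id,
    historical_date = historical$exam_date,
    current_date = current$exam_date
  )
}

#' Construct a delta record
#'
#' @param deltas Named integer vector over the schema attributes, each value
#'   in -4..4 (UPDRS points of change, current minus historical).
#' @param decision Optional decision class in `{0, 1, 2}` (`NA` if unlabeled).
#' @param patient_id,expert_id,historical_date,current_date Optional
#'   provenance.
#' @return An object of class `delta_record`.
#' @export
delta_record <- function(deltas, decision = NA_integer_, patient_id = NA_character_,
                         expert_id = NA_character_, historical_date = NULL,
                         current_date = NULL) {
  deltas <- unlist(deltas)
  v <- suppressWarnings(as.numeric(deltas))
  if (anyNA(v) || any(v != as.integer(v)) || any(abs(v) > 4)) {
    stop("deltas must be integers in -4..4", call. = FALSE)
  }
  decision <- check_decision(decision, allow_na = TRUE)
  structure(
    list(deltas = stats::setNames(as.integer(v), names(deltas)),
         decision = decision,
         patient_id = as.character(patient_id),
         expert_id = as.character(expert_id),
         historical_date = historical_date,
         current_date = current_date),
    class = "delta_record"
  )
}

check_decision <- function(decision, allow_na = FALSE) {
  if (length(decision) != 1L) stop("decision must be a single value", call. = FALSE)
  if (is.na(decision)) {
    if (allow_na) return(NA_integer_)
    stop("decision is missing", call. = FALSE)
  }
  d <- suppressWarnings(as.integer(decision))
  if (is.na(d) || d != as.numeric(decision) || !(d %in% 0:2)) {
    stop("decision must be 0 (stable), 1 (warning) or 2 (alarm)", call. = FALSE)
  }
  d
}

#' @export
print.delta_record <- function(x, ...) {
  lab <- if (is.na(x$decision)) "unlabeled" else
    paste0(x$decision, " ('", decision_labels()[x$decision + 1L], "')")
  cat("Delta record (", lab, ")\n", sep = "")
  nz <- x$deltas[x$deltas != 0L]
  if (length(nz)) print(nz) else cat("  no change on any item\n")
  invisible(x)
}
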