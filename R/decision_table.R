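# Decision tables: the rough-set information system built from expert-labeled
# delta records. Represented as a data.frame with one integer column per delta
# attribute, a `decision` column in {0,1,2}, and optional `patient_id` /
# `expert_id` provenance columns.

.reserved_cols <- c("decision", "patient_id", "expert_id")

#' Construct / validate a decision table
#'
#' @param df Data frame with one integer column per condition attribute
#'   (values in -4..4), a `decision` column in `{0,1,2}` and optional
#'   `patient_id` and `expert_id` columns.
#' @param attrs Character vector of condition-attribute column names. Defaults
#'   to all non-reserved columns of `df`.
#' @return `df` with class `decision_table` and attribute `attrs`.
#' @export
decision_table <- function(df, attrs = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(attrs)) attrs <- setdiff(names(df), .reserved_cols)
  if (!length(attrs)) stop("decision table has no condition attributes", call. = FALSE)
  missing_attrs <- setdiff(attrs, names(df))
  if (length(missing_attrs)) {
    stop("missing attribute column(s): ", paste(missing_attrs, collapse = ", "),
         call. = FALSE)
  }
  if (!"decision" %in% names(df)) stop("missing 'decision' column", call. = FALSE)
  for (a in attrs) {
    v <- df[[a]]
    if (anyNA(v) || !is.numeric(v) || any(v != as.integer(v)) || any(abs(v) > 4)) {
      stop("column '", a, "' must hold integer deltas in -4..4", call. = FALSE)
    }
    df[[a]] <- as.integer(v)
  }
  d <- df$decision
  if (anyNA(d) || !is.numeric(d) || any(d != as.integer(d)) || !all(d %in% 0:2)) {
    stop("'decision' must be 0, 1 or 2 for every record", call. = FALSE)
  }
  df$decision <- as.integer(d)
  rownames(df) <- NULL
  structure(df, attrs = attrs, class = c("decision_table", "data.frame"))
}

#' Condition-attribute names of a decision table
#' @param table A `decision_table`.
#' @return Character vector of attribute column names.
#' @export
table_attrs <- function(table) {
  a <- attr(table, "attrs")
  if (is.null(a)) a <- setdiff(names(table), .reserved_cols)
  a
}

#' @export
print.decision_table <- function(x, ...) {
  cat("Decision table: ", nrow(x), " records x ", length(table_attrs(x)),
      " condition attributes\n", sep = "")
  cat("class counts:", paste0(0:2, ":", tabulate(x$decision + 1L, 3L), collapse = "  "), "\n")
  NextMethod()
}

#' Build a decision table from expert votes
#'
#' Flattens expert votes into one training object per (exam pair, expert) --
#' votes are deliberately *not* majority-aggregated, so conflicting experts
#' produce an inconsistent table that the rough-set layer handles through
#' its boundary regions.
#'
#' @param records List of `delta_record`s (one per exam pair), or a data frame
#'   of delta columns.
#' @param votes Data frame with columns `pair` (index into `records`),
#'   `expert_id` and `decision`. Each (pair, expert) combination may appear at
#'   most once.
#' @return A `decision_table` with `nrow(votes)` rows (no deduplication; see
#'   [deduplicate()]).
#' @export
build_decision_table <- function(records, votes) {
  stopifnot(is.data.frame(votes),
            all(c("pair", "expert_id", "decision") %in% names(votes)))
  if (inherits(records, "delta_record")) records <- list(records)
  if (is.data.frame(records)) {
    deltas <- as.data.frame(records)
    attrs <- setdiff(names(deltas), .reserved_cols)
    pids <- rep(NA_character_, nrow(deltas))
  } else {
    attrs <- names(records[[1L]]$deltas)
    deltas <- as.data.frame(do.call(rbind, lapply(records, function(r) r$deltas)))
    names(deltas) <- attrs
    pids <- vapply(records, function(r) r$patient_id, character(1))
  }
  if (any(votes$pair < 1L | votes$pair > nrow(deltas))) {
    stop("vote refers to a nonexistent pair", call. = FALSE)
  }
  key <- paste(votes$pair, votes$expert_id)
  if (anyDuplicated(key)) {
    stop("duplicated (pair, expert) vote", call. = FALSE)
  }
  for (d in votes$decision) check_decision(d)
  out <- deltas[votes$pair, , drop = FALSE]
  out$decision <- as.integer(votes$decision)
  out$patient_id <- pids[votes$pair]
  out$expert_id <- as.character(votes$expert_id)
  decision_table(out, attrs)
}

#' Remove repeated entries from a decision table
#'
#' A duplicate is a row identical to an earlier one on all condition
#' attributes and the decision -- and, when expert provenance is present, on
#' the expert as well: each expert contributes one decision table, and
#' repeated entries are removed *within* each expert's table. Rows that agree
#' on the deltas but differ in decision are always all kept; such conflicts
#' are the inconsistency that rough sets are there to handle. Idempotent;
#' first-occurrence order is preserved.
#'
#' @param table A `decision_table`.
#' @return The deduplicated `decision_table`.
#' @export
deduplicate <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  attrs <- table_attrs(table)
  keycols <- c(attrs, "decision", intersect("expert_id", names(table)))
  key <- do.call(paste, c(unclass(table)[keycols], sep = "\r"))
  out <- table[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, attrs = attrs, class = class(table))
}

#' Histogram of expert votes for one exam pair
#'
#' @param votes Nonempty vector of decisions in `{0,1,2}`.
#' @return An object of class `vote_histogram`: list with `counts` (named
#'   vector over classes "0","1","2") and `n_experts`.
#' @examples
#' vote_histogram(c(0, 1, 1, 2))$counts # 1, 2, 1
#' @export
vote_histogram <- function(votes) {
  if (!length(votes)) stop("empty vote list", call. = FALSE)
  votes <- vapply(votes, check_decision, integer(1))
  counts <- stats::setNames(tabulate(votes + 1L, nbins = 3L), as.character(0:2))
  structure(list(counts = counts, n_experts = length(votes)),
            class = "vote_histogram")
}

#' @export
print.vote_histogram <- function(x, ...) {
  lab <- decision_labels()
  cat("Expert vote histogram (", x$n_experts, " experts)\n", sep = "")
  for (k in 0:2) {
    cat(sprintf("  %d (%s): %d\n", k, lab[k + 1L], x$counts[[as.character(k)]]))
  }
  invisible(x)
}

# ---- CSV input / output ----------------------------------------------------

#' Read / write UPDRS exams as CSV
#'
#' Exams CSV dialect: header `patient_id,exam_date,<attribute columns in
#' schema order>`, integer scores 0..4, UTF-8, comma-separated.
#'
#' @param path File path.
#' @param schema An [updrs_schema()].
#' @return `read_exams_csv()` returns a list of `updrs_exam`s.
#' @export
read_exams_csv <- function(path, schema = updrs_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "exam_date", schema$attributes)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("exams CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    for (a in schema$attributes) {
      v <- df[[a]][i]
      if (is.na(suppressWarnings(as.numeric(v))) || as.numeric(v) != as.integer(v)) {
        stop("non-integer score at row ", i, ", column '", a, "'", call. = FALSE)
      }
      if (as.numeric(v) < 0 || as.numeric(v) > 4) {
        stop("score out of range 0..4 at row ", i, ", column '", a, "'", call. = FALSE)
      }
    }
    updrs_exam(df$patient_id[i], df$exam_date[i],
               stats::setNames(as.integer(unlist(df[i, schema$attributes])),
                               schema$attributes),
               schema)
  })
}

#' @rdname read_exams_csv
#' @param exams List of `updrs_exam`s.
#' @export
write_exams_csv <- function(exams, path) {
  stopifnot(length(exams) > 0L, inherits(exams[[1L]], "updrs_exam"))
  attrs <- exams[[1L]]$schema$attributes
  df <- data.frame(
    patient_id = vapply(exams, function(e) e$patient_id, character(1)),
    exam_date = vapply(exams, function(e) format(e$exam_date), character(1)),
    stringsAsFactors = FALSE
  )
  for (a in attrs) df[[a]] <- vapply(exams, function(e) e$scores[[a]], integer(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a decision table as CSV
#'
#' Decision-table CSV dialect: header `<delta columns>,decision[,patient_id,
#' expert_id]`, integer values; deltas in -4..4, decision in `{0,1,2}`.
#' The round trip `read_table_csv(write_table_csv(x))` is lossless.
#'
#' @param path File path.
#' @param attrs Optional attribute column names; defaults to every
#'   non-reserved column found in the file.
#' @return `read_table_csv()` returns a `decision_table`.
#' @export
read_table_csv <- function(path, attrs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"decision" %in% names(df)) {
    stop("decision-table CSV is missing the 'decision' column", call. = FALSE)
  }
  use <- if (is.null(attrs)) setdiff(names(df), .reserved_cols) else attrs
  missing_cols <- setdiff(use, names(df))
  if (length(missing_cols)) {
    stop("decision-table CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (a in c(use, "decision")) {
    v <- suppressWarnings(as.numeric(df[[a]]))
    bad <- which(is.na(v) | v != as.integer(v))
    if (length(bad)) {
      stop("non-integer value at row ", bad[1L], ", column '", a, "'", call. = FALSE)
    }
    rng <- if (a == "decision") c(0, 2) else c(-4, 4)
    bad <- which(v < rng[1L] | v > rng[2L])
    if (length(bad)) {
      stop("value out of range at row ", bad[1L], ", column '", a, "'", call. = FALSE)
    }
  }
  if ("patient_id" %in% names(df)) df$patient_id <- as.character(df$patient_id)
  if ("expert_id" %in% names(df)) df$expert_id <- as.character(df$expert_id)
  decision_table(df, use)
}

#' @rdname read_table_csv
#' @param table A `decision_table`.
#' @export
write_table_csv <- function(table, path) {
  stopifnot(inherits(table, "decision_table"))
  cols <- c(table_attrs(table), "decision", intersect(c("patient_id", "expert_id"), names(table)))
  utils::write.csv(as.data.frame(table)[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
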