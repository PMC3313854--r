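# Applying rule sets to delta records, the 50:50 split protocol, and the
# three collapsed-class efficiency cases.

#' Classify a delta record with a rule set
#'
#' All matching rules are collected. If they agree on one class the result is
#' `unique`; if several classes match, the class with the largest sum of
#' confidence x support over its matching rules wins (`vote`); if no rule
#' matches, the rules with the highest fraction of satisfied conditions are
#' taken and the same weighted vote is applied among them (`partial_match`).
#' Any remaining tie resolves to the most severe class
#' (`severity_tiebreak`) -- a missed alert is costlier than a false one.
#'
#' @param ruleset A nonempty `rule_set`.
#' @param record A `delta_record`, or a named vector of deltas.
#' @return List of class `classification_result` with `predicted` (0/1/2),
#'   `matched_rules` (integer indices into `ruleset$rules`; empty for partial
#'   matches) and `resolution`.
#' @export
classify <- function(ruleset, record) {
  stopifnot(inherits(ruleset, "rule_set"))
  if (!length(ruleset$rules)) stop("empty rule set", call. = FALSE)
  deltas <- if (inherits(record, "delta_record")) record$deltas else unlist(record)
  df <- as.data.frame(as.list(deltas))
  names(df) <- names(deltas)

  full <- which(vapply(ruleset$rules, rule_matches, logical(1), df = df))
  if (length(full)) {
    classes <- vapply(ruleset$rules[full], function(r) r$decision, integer(1))
    if (length(unique(classes)) == 1L) {
      return(structure(list(predicted = classes[1L], matched_rules = full,
                            resolution = "unique"),
                       class = "classification_result"))
    }
    pick <- weighted_vote(ruleset$rules[full])
    return(structure(list(predicted = pick$class, matched_rules = full,
                          resolution = if (pick$tie) "severity_tiebreak" else "vote"),
                     class = "classification_result"))
  }

  # partial matching: highest fraction of satisfied conditions
  frac <- vapply(ruleset$rules, function(r) {
    if (!length(r$conditions)) return(1)
    mean(vapply(r$conditions, function(cond) {
      v <- deltas[[cond$attribute]]
      v > cond$low & v < cond$high
    }, logical(1)))
  }, numeric(1))
  best <- which(frac == max(frac))
  pick <- weighted_vote(ruleset$rules[best])
  structure(list(predicted = pick$class, matched_rules = integer(0),
                 resolution = "partial_match"),
            class = "classification_result")
}

weighted_vote <- function(rules) {
  w <- stats::setNames(numeric(3), as.character(0:2))
  for (r in rules) {
    k <- as.character(r$decision)
    w[k] <- w[k] + r$confidence * r$support
  }
  top <- which(w == max(w)) - 1L
  list(class = as.integer(max(top)), tie = length(top) > 1L)
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Predicted class ", x$predicted, " ('", decision_labels()[x$predicted + 1L],
      "') by ", x$resolution, " (", length(x$matched_rules), " matching rules)\n",
      sep = "")
  invisible(x)
}

# vector of predictions for all rows of a decision table (or delta data frame)
classify_table <- function(ruleset, table) {
  df <- as.data.frame(table)
  vapply(seq_len(nrow(df)), function(i) {
    classify(ruleset, unlist(df[i, setdiff(names(df), .reserved_cols), drop = FALSE]))$predicted
  }, integer(1))
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive split preserving per-class proportions to within one
#' record; deterministic given `seed`. A class with a single record sends it
#' to the training half with a warning.
#'
#' @param table A `decision_table`.
#' @param ratio Training fraction in `(0, 1)`; default 0.5 (the 50:50
#'   protocol).
#' @param stratified Preserve class proportions (default `TRUE`).
#' @param seed Integer seed; default 0.
#' @return List with `train` and `test` decision tables.
#' @export
split_train_test <- function(table, ratio = 0.5, stratified = TRUE, seed = 0L) {
  stopifnot(inherits(table, "decision_table"))
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(table)
  n_train <- round(n * ratio)
  rng <- local_rng(seed)
  idx_train <- integer(0)
  if (stratified) {
    classes <- sort(unique(table$decision))
    per <- lapply(classes, function(k) which(table$decision == k))
    sizes <- vapply(per, length, integer(1))
    base <- floor(sizes * ratio)
    # distribute the remaining slots by largest fractional part (ties: class order)
    rem <- n_train - sum(base)
    frac <- sizes * ratio - base
    if (rem > 0L) {
      extra <- order(-frac, seq_along(classes))[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    for (k in seq_along(classes)) {
      idx <- per[[k]]
      if (length(idx) < 2L && base[k] == length(idx)) {
        warning("class ", classes[k], " has fewer than 2 records; kept in training",
                call. = FALSE)
      }
      take <- min(base[k], length(idx))
      idx_train <- c(idx_train, sort(rng$sample(idx, take)))
    }
  } else {
    idx_train <- sort(rng$sample(seq_len(n), n_train))
  }
  idx_train <- sort(idx_train)
  attrs <- table_attrs(table)
  train <- structure(table[idx_train, , drop = FALSE], attrs = attrs, class = class(table))
  test <- structure(table[setdiff(seq_len(n), idx_train), , drop = FALSE],
                    attrs = attrs, class = class(table))
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

# seeded RNG confined to a closure so callers' RNG state is untouched
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample = function(x, size) run(function() {
      if (length(x) == 1L) x[rep(1L, size)] else sample(x, size)
    }),
    runif = function(n) run(function() stats::runif(n)),
    rint = function(n, probs, values) run(function() {
      values[sample.int(length(values), n, replace = TRUE, prob = probs)]
    })
  )
}

#' Confusion matrix and the three efficiency cases
#'
#' Classifies every record of a labeled table, builds the 3x3 confusion
#' matrix (rows = expert class, columns = predicted class) and computes the
#' three efficiency cases: case 1 is plain 3-class accuracy; case 2 collapses
#' stable and warning against alarm (high-priority-alarm recognition); case 3
#' collapses warning and alarm against stable (any-alert recognition). All
#' three are percentages; collapsing can only merge error cells into the
#' diagonal, so case 2 and case 3 are always at least case 1.
#'
#' @param ruleset A `rule_set`.
#' @param table A nonempty labeled `decision_table`.
#' @return List of class `efficiency_report`: `confusion` (3x3 matrix),
#'   `case1`, `case2`, `case3` (percentages), `n`, `mode`.
#' @export
evaluate <- function(ruleset, table) {
  stopifnot(inherits(table, "decision_table"))
  if (!nrow(table)) stop("decision table is empty", call. = FALSE)
  pred <- classify_table(ruleset, table)
  cm <- confusion_matrix(table$decision, pred)
  c(list(confusion = cm), efficiency_cases(cm),
    list(n = nrow(table), mode = ruleset$mode)) |>
    structure(class = "efficiency_report")
}

#' @rdname evaluate
#' @param truth,predicted Integer vectors of classes in `{0,1,2}`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  cm <- table(factor(truth, levels = 0:2), factor(predicted, levels = 0:2))
  m <- matrix(as.integer(cm), 3, 3, dimnames = list(true = 0:2, predicted = 0:2))
  m
}

#' @rdname evaluate
#' @param cm A 3x3 confusion matrix (rows = true class).
#' @export
efficiency_cases <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == c(3L, 3L)), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  case1 <- sum(diag(cm)) / total
  case2 <- (sum(cm[1:2, 1:2]) + cm[3, 3]) / total           # {0,1} vs {2}
  case3 <- (cm[1, 1] + sum(cm[2:3, 2:3])) / total           # {0} vs {1,2}
  list(case1 = 100 * case1, case2 = 100 * case2, case3 = 100 * case3)
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(x$mode, "classifier on", x$n, "records\n")
  print(x$confusion)
  cat(sprintf("case 1 (3-class):     %.1f%%\n", x$case1))
  cat(sprintf("case 2 (alarm vs rest): %.1f%%\n", x$case2))
  cat(sprintf("case 3 (any alert):   %.1f%%\n", x$case3))
  invisible(x)
}

#' Nearest-neighbour sanity baseline
#'
#' Manhattan distance over delta vectors; the majority class among the `k`
#' nearest training records wins. Distance ties prefer the lower record
#' index; class ties resolve to the most severe class.
#'
#' @param train_table Nonempty labeled `decision_table`.
#' @param record A `delta_record` or named delta vector.
#' @param k Neighbourhood size (default 1).
#' @return Predicted class in `{0,1,2}`.
#' @export
nn_baseline <- function(train_table, record, k = 1L) {
  stopifnot(inherits(train_table, "decision_table"), nrow(train_table) > 0L)
  deltas <- if (inherits(record, "delta_record")) record$deltas else unlist(record)
  attrs <- table_attrs(train_table)
  m <- as.matrix(as.data.frame(train_table)[attrs])
  d <- rowSums(abs(sweep(m, 2L, deltas[attrs])))
  ord <- order(d, seq_along(d))
  nn <- ord[seq_len(min(k, length(ord)))]
  votes <- tabulate(train_table$decision[nn] + 1L, 3L)
  max(which(votes == max(votes))) - 1L
}
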