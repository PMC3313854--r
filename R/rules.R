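# Interval-condition decision rules induced by sequential covering (LEM2
# style) over the cut-discretized delta space. Plain rough-set rules (RS)
# cover each class's lower approximation with certain rules; the generalized
# variant (RS-g) covers the variable-precision beta-lower approximation and
# then shortens every rule while its confidence on the table stays >= beta.

#' Construct an interval condition
#'
#' An elementary condition `low < delta(attribute) < high` with exclusive
#' integer bounds (`-Inf` / `Inf` for one-sided conditions). The admitted
#' integer set must be nonempty.
#'
#' @param attribute Attribute name.
#' @param low,high Exclusive bounds (integers or infinite).
#' @return A list of class `rule_condition`.
#' @export
rule_condition <- function(attribute, low = -Inf, high = Inf) {
  stopifnot(is.character(attribute), length(attribute) == 1L)
  if (is.finite(low) && low != as.integer(low)) stop("low must be an integer", call. = FALSE)
  if (is.finite(high) && high != as.integer(high)) stop("high must be an integer", call. = FALSE)
  if (low >= high - 1) {
    stop("condition on '", attribute, "' admits no integer value", call. = FALSE)
  }
  structure(list(attribute = attribute, low = low, high = high),
            class = "rule_condition")
}

#' Construct a decision rule
#'
#' A conjunction of interval conditions implying a decision class, with the
#' support (matching training records) and confidence (fraction of them
#' carrying the class) measured on the inducing table.
#'
#' @param conditions List of [rule_condition()]s; at most one per attribute.
#' @param decision Class in `{0,1,2}`.
#' @param support Positive integer count.
#' @param confidence Number in `(0, 1]`.
#' @return A list of class `decision_rule`.
#' @export
decision_rule <- function(conditions, decision, support = NA_integer_,
                          confidence = NA_real_) {
  decision <- check_decision(decision)
  stopifnot(is.list(conditions))
  attrs <- vapply(conditions, function(c) c$attribute, character(1))
  if (anyDuplicated(attrs)) stop("two conditions on the same attribute", call. = FALSE)
  structure(list(conditions = conditions, decision = decision,
                 support = as.integer(support), confidence = as.numeric(confidence)),
            class = "decision_rule")
}

#' Construct a rule set
#'
#' @param rules List of [decision_rule()]s.
#' @param mode `"RS"` or `"RS-g"`.
#' @param beta Precision parameter in `(0.5, 1]` (RS-g only, `NA` for RS).
#' @return A list of class `rule_set`.
#' @export
rule_set <- function(rules, mode = c("RS", "RS-g"), beta = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "RS-g") check_beta(beta)
  structure(list(rules = rules, mode = mode, beta = beta,
                 default_class_policy = "partial match, then severity tie-break"),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(x$mode, " rule set: ", length(x$rules), " rules",
      if (x$mode == "RS-g") paste0(" (beta = ", x$beta, ")"), "\n", sep = "")
  for (r in x$rules) cat("  ", render_rule(r), "\n", sep = "")
  invisible(x)
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(render_rule(x), "\n")
  invisible(x)
}

# rows of `df` (attribute columns) matched by a rule
rule_matches <- function(rule, df) {
  keep <- rep(TRUE, nrow(df))
  for (cond in rule$conditions) {
    v <- df[[cond$attribute]]
    keep <- keep & v > cond$low & v < cond$high
  }
  keep
}

rule_stats <- function(rule, table) {
  hit <- rule_matches(rule, table)
  support <- sum(hit)
  confidence <- if (support) mean(table$decision[hit] == rule$decision) else NA_real_
  list(support = support, confidence = confidence)
}

# ---- LEM2-style covering ----------------------------------------------------

# Elementary (half-space) conditions derived from the cut set:
# for a cut (a, c), "v < c" i.e. high = c + 0.5, and "v > c" i.e. low = c - 0.5.
elementary_conditions <- function(cuts) {
  out <- list()
  for (q in seq_len(nrow(cuts))) {
    a <- cuts$attribute[q]; c <- cuts$threshold[q]
    out[[length(out) + 1L]] <- rule_condition(a, high = ceiling(c))
    out[[length(out) + 1L]] <- rule_condition(a, low = floor(c))
  }
  out
}

cond_satisfied <- function(cond, m) {
  v <- m[, cond$attribute]
  v > cond$low & v < cond$high
}

# merge a new elementary condition into the per-attribute bound list
merge_condition <- function(bounds, cond) {
  b <- bounds[[cond$attribute]]
  if (is.null(b)) b <- c(-Inf, Inf)
  b <- c(max(b[1L], cond$low), min(b[2L], cond$high))
  bounds[[cond$attribute]] <- b
  bounds
}

bounds_to_conditions <- function(bounds, attr_order) {
  out <- list()
  for (a in attr_order) {
    b <- bounds[[a]]
    if (!is.null(b) && (is.finite(b[1L]) || is.finite(b[2L]))) {
      out[[length(out) + 1L]] <- rule_condition(a, low = b[1L], high = b[2L])
    }
  }
  out
}

bounds_match <- function(bounds, m) {
  keep <- rep(TRUE, nrow(m))
  for (a in names(bounds)) {
    b <- bounds[[a]]
    keep <- keep & m[, a] > b[1L] & m[, a] < b[2L]
  }
  keep
}

# Sequential covering of goal set G (row indices) so that every grown rule's
# matched rows lie inside the region B (row indices). Deterministic:
# candidates are scored by positives covered, then fewest negatives, then
# attribute name, lower-bound conditions before upper, threshold ascending.
lem2_cover <- function(m, dec, class, B, attrs, elems) {
  G <- sort(intersect(B, which(dec == class)))
  in_B <- rep(FALSE, nrow(m)); in_B[B] <- TRUE
  rules_bounds <- list()
  elem_sat <- lapply(elems, cond_satisfied, m = m)
  ord <- order(vapply(elems, function(e) e$attribute, character(1)),
               vapply(elems, function(e) !is.finite(e$low), logical(1)),
               vapply(elems, function(e) if (is.finite(e$low)) e$low else e$high,
                      numeric(1)))

  while (length(G)) {
    bounds <- list()
    box <- rep(TRUE, nrow(m))
    repeat {
      inside <- which(box)
      if (all(in_B[inside])) break
      g_in_box <- intersect(inside, G)
      if (!length(g_in_box)) break # should not happen; guard
      best <- NULL; best_pos <- -1L; best_neg <- Inf
      for (q in ord) {
        sat <- elem_sat[[q]]
        pos <- sum(sat[g_in_box])
        if (pos == 0L) next
        # skip conditions already implied by current bounds
        b <- bounds[[elems[[q]]$attribute]]
        if (!is.null(b) && b[1L] >= elems[[q]]$low && b[2L] <= elems[[q]]$high) next
        neg <- sum(sat[inside] & !in_B[inside])
        if (pos > best_pos || (pos == best_pos && neg < best_neg)) {
          best <- q; best_pos <- pos; best_neg <- neg
        }
      }
      if (is.null(best)) break # goal rows indiscernible from outside B
      bounds <- merge_condition(bounds, elems[[best]])
      box <- box & elem_sat[[best]]
    }
    inside <- which(box)
    if (!all(in_B[inside])) {
      # uncoverable residue (contradictory support): drop it with a warning
      warning("dropping ", length(intersect(inside, G)),
              " record(s) of class ", class,
              " that cannot be covered by a certain rule", call. = FALSE)
      G <- setdiff(G, inside)
      next
    }
    # prune redundant conditions while staying inside B: first try dropping a
    # whole attribute's condition, then relaxing one side of it
    still_inside <- function(b) {
      if (length(b)) all(in_B[bounds_match(b, m)]) else all(in_B)
    }
    for (a in names(bounds)) {
      cand <- bounds[setdiff(names(bounds), a)]
      if (still_inside(cand)) {
        bounds <- cand
        next
      }
      for (side in 1:2) {
        if (is.finite(bounds[[a]][side])) {
          cand <- bounds
          cand[[a]][side] <- c(-Inf, Inf)[side]
          if (still_inside(cand)) bounds <- cand
        }
      }
    }
    rules_bounds[[length(rules_bounds) + 1L]] <- bounds
    covered <- which(bounds_match(bounds, m))
    G <- setdiff(G, covered)
  }

  # drop rules redundant for covering the class goal (first kept, later
  # dropped if the remainder still covers)
  goal <- sort(intersect(B, which(dec == class)))
  if (length(rules_bounds) > 1L) {
    covers <- lapply(rules_bounds, function(b) intersect(which(bounds_match(b, m)), goal))
    keep <- rep(TRUE, length(rules_bounds))
    for (r in rev(seq_along(rules_bounds))) {
      others <- unlist(covers[keep & seq_along(covers) != r], use.names = FALSE)
      if (all(covers[[r]] %in% others)) keep[r] <- FALSE
    }
    rules_bounds <- rules_bounds[keep]
  }
  rules_bounds
}

#' Induce rough-set decision rules
#'
#' Sequential covering per decision class over the class's lower
#' approximation in the cut-discretized space: grow a conjunction of
#' elementary interval conditions until every matched record lies in the
#' lower approximation, prune redundant conditions, remove the covered
#' records and repeat. On a consistent table every induced rule is certain
#' (confidence 1).
#'
#' @param table A deduplicated `decision_table`.
#' @param cuts A cut set from [find_cuts()] (computed from `table` by
#'   default).
#' @return A `rule_set` with `mode = "RS"`. Support and confidence of each
#'   rule are measured on `table`.
#' @export
induce_rules <- function(table, cuts = find_cuts(table)) {
  induce_internal(table, cuts, beta = 1, mode = "RS")
}

#' Induce generalized (variable-precision) rules
#'
#' Like [induce_rules()], but covering runs against the beta-lower
#' approximation (a block belongs to a class's region when at least a
#' fraction `beta` of its records carry the class), and every finished rule
#' is then shortened by greedily dropping conditions while its confidence on
#' the table stays at least `beta`. The shortened set is deduplicated, so it
#' is typically smaller than the RS set induced from the same table.
#'
#' @inheritParams induce_rules
#' @param beta Precision parameter in `(0.5, 1]`; default 0.8. `beta = 1`
#'   reproduces the classical model's classification behavior.
#' @return A `rule_set` with `mode = "RS-g"`.
#' @export
generalize_rules <- function(table, cuts = find_cuts(table), beta = 0.8) {
  check_beta(beta)
  induce_internal(table, cuts, beta = beta, mode = "RS-g")
}

induce_internal <- function(table, cuts, beta, mode) {
  stopifnot(inherits(table, "decision_table"))
  if (!nrow(table)) stop("decision table is empty", call. = FALSE)
  attrs <- table_attrs(table)
  m <- as.matrix(as.data.frame(table)[attrs])
  dec <- table$decision
  elems <- elementary_conditions(cuts)

  rules <- list()
  for (class in 0:2) {
    if (!any(dec == class)) next
    B <- beta_lower(table, attrs, class, beta = beta)
    if (!length(B)) {
      warning("empty ", if (beta < 1) "beta-" else "",
              "lower approximation for class ", class, "; no rules induced",
              call. = FALSE)
      next
    }
    for (bounds in lem2_cover(m, dec, class, B, attrs, elems)) {
      rule <- decision_rule(bounds_to_conditions(bounds, attrs), class)
      st <- rule_stats(rule, table)
      rule$support <- as.integer(st$support)
      rule$confidence <- st$confidence
      rules[[length(rules) + 1L]] <- rule
    }
  }

  if (mode == "RS-g") {
    rules <- lapply(rules, shorten_rule, table = table, beta = beta)
    rules <- rules[!duplicated(vapply(rules, render_rule, character(1)))]
  }
  rule_set(rules, mode = mode, beta = if (mode == "RS-g") beta else NA_real_)
}

# Greedily drop conditions while confidence on the table stays >= beta:
# at each step remove the condition whose removal leaves the highest
# confidence (ties: larger support, then condition order), so the rule stays
# as reliable as possible while it generalizes.
shorten_rule <- function(rule, table, beta) {
  repeat {
    best <- NULL
    best_conf <- -1
    best_sup <- -1L
    for (k in seq_along(rule$conditions)) {
      cand <- rule
      cand$conditions <- rule$conditions[-k]
      st <- rule_stats(cand, table)
      if (st$support > 0L && st$confidence >= beta &&
          (st$confidence > best_conf ||
             (st$confidence == best_conf && st$support > best_sup))) {
        best <- k
        best_conf <- st$confidence
        best_sup <- as.integer(st$support)
      }
    }
    if (is.null(best)) break
    rule$conditions <- rule$conditions[-best]
    rule$support <- best_sup
    rule$confidence <- best_conf
  }
  rule
}

# ---- rendering and serialization -------------------------------------------

#' Render a rule in the report style
#'
#' Produces the compact doctor-readable form, e.g.
#' `IfΔUPDRS13<1&-1<ΔUPDRS14<2&ΔUPDRS23RH<1&ΔUPDRS29<1=>output=1-'warning'`.
#' Conditions are joined by `&` with strict inequalities; an unconditional
#' rule renders as `Iftrue=>...`.
#'
#' @param rule A `decision_rule`.
#' @return A single string.
#' @export
render_rule <- function(rule) {
  stopifnot(inherits(rule, "decision_rule"))
  conds <- if (!length(rule$conditions)) "true" else {
    paste(vapply(rule$conditions, render_condition, character(1)), collapse = "&")
  }
  paste0("If", conds, "=>output=", rule$decision, "-'",
         decision_labels()[rule$decision + 1L], "'")
}

render_condition <- function(cond) {
  name <- attr_display_name(cond$attribute)
  if (is.finite(cond$low) && is.finite(cond$high)) {
    paste0(cond$low, "<", name, "<", cond$high)
  } else if (is.finite(cond$low)) {
    paste0(cond$low, "<", name)
  } else {
    paste0(name, "<", cond$high)
  }
}

#' Render a doctor-readable report
#'
#' @param ruleset A `rule_set`.
#' @param results Optional evaluation as returned by [evaluate()]; when
#'   given, the confusion matrix and the three efficiency cases are appended.
#' @return A single string (lines joined by newlines).
#' @export
render_report <- function(ruleset, results = NULL) {
  stopifnot(inherits(ruleset, "rule_set"))
  lines <- c(
    "Automatic assessment of PD motor-state deterioration",
    paste0("Induction mode: ", ruleset$mode,
           if (ruleset$mode == "RS-g") paste0(" (beta = ", ruleset$beta, ")")),
    paste0("Rules: ", length(ruleset$rules)),
    vapply(ruleset$rules, function(r) {
      paste0("  ", render_rule(r), "   [support ", r$support,
             ", confidence ", formatC(r$confidence, format = "f", digits = 2), "]")
    }, character(1))
  )
  if (!is.null(results)) {
    cm <- results$confusion
    lines <- c(lines, "", "Confusion matrix (rows = expert, cols = system):",
               utils::capture.output(print(cm)),
               "",
               sprintf("Case 1 (3-class recognition):      %.1f%%", results$case1),
               sprintf("Case 2 (high-priority alarm):      %.1f%%", results$case2),
               sprintf("Case 3 (any-alert recognition):    %.1f%%", results$case3))
  }
  paste(lines, collapse = "\n")
}

#' Write / read a rule set as JSON
#'
#' Schema: `{mode, beta, rules: [{conditions: [{attr, low, high}], decision,
#' support, confidence}]}` with `null` bounds for one-sided conditions.
#'
#' @param ruleset A `rule_set`.
#' @param path File path.
#' @return `read_ruleset_json()` returns a `rule_set`.
#' @export
write_ruleset_json <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "rule_set"))
  obj <- list(
    mode = ruleset$mode,
    beta = if (is.na(ruleset$beta)) NULL else ruleset$beta,
    rules = lapply(ruleset$rules, function(r) {
      list(conditions = lapply(r$conditions, function(cond) {
        list(attr = cond$attribute,
             low = if (is.finite(cond$low)) cond$low else NULL,
             high = if (is.finite(cond$high)) cond$high else NULL)
      }),
      decision = r$decision, support = r$support, confidence = r$confidence)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ruleset_json
#' @export
read_ruleset_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rules <- lapply(obj$rules, function(r) {
    conds <- lapply(r$conditions, function(cond) {
      rule_condition(cond$attr,
                     low = if (is.null(cond$low)) -Inf else cond$low,
                     high = if (is.null(cond$high)) Inf else cond$high)
    })
    decision_rule(conds, r$decision, support = r$support, confidence = r$confidence)
  })
  rule_set(rules, mode = obj$mode,
           beta = if (is.null(obj$beta)) NA_real_ else obj$beta)
}
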