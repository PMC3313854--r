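# Rough-set machinery over a decision table: indiscernibility partitions,
# lower/upper approximations, positive region and quality of classification,
# discernibility matrix, reducts and core.
#
# Delta values are treated as discrete symbols here; interval semantics enter
# only at the rule-induction layer through cuts.

#' Indiscernibility partition
#'
#' Partitions the records of a decision table into equivalence classes
#' (elementary sets): two records share a block iff their deltas agree on
#' every attribute in `attrs`.
#'
#' @param table A `decision_table`.
#' @param attrs Nonempty subset of the table's condition attributes.
#' @return List of integer vectors of record indices (the blocks), ordered by
#'   first occurrence; pairwise disjoint, jointly exhaustive, no empty block.
#' @export
indiscernibility <- function(table, attrs) {
  check_attrs(table, attrs)
  key <- do.call(paste, c(unclass(table)[attrs], sep = "\r"))
  blocks <- split(seq_len(nrow(table)), factor(key, levels = unique(key)))
  unname(blocks)
}

check_attrs <- function(table, attrs) {
  stopifnot(inherits(table, "decision_table"))
  if (!length(attrs)) stop("attribute subset must be nonempty", call. = FALSE)
  unknown <- setdiff(attrs, table_attrs(table))
  if (length(unknown)) {
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Lower and upper approximation of a decision class
#'
#' The lower approximation is the union of blocks entirely labeled with
#' `target_class`; the upper approximation the union of blocks containing at
#' least one such record. Their difference is the boundary region.
#'
#' @inheritParams indiscernibility
#' @param target_class Decision class in `{0,1,2}`.
#' @return Object of class `rough_approximation`: list with sorted integer
#'   index vectors `lower`, `upper`, `boundary` and the `target_class`.
#' @export
approximate <- function(table, attrs, target_class) {
  target_class <- check_decision(target_class)
  blocks <- indiscernibility(table, attrs)
  dec <- table$decision
  lower <- integer(0)
  upper <- integer(0)
  for (b in blocks) {
    hit <- dec[b] == target_class
    if (any(hit)) {
      upper <- c(upper, b)
      if (all(hit)) lower <- c(lower, b)
    }
  }
  structure(list(lower = sort(lower), upper = sort(upper),
                 boundary = sort(setdiff(upper, lower)),
                 target_class = target_class),
            class = "rough_approximation")
}

#' @export
print.rough_approximation <- function(x, ...) {
  cat("Rough approximation of class ", x$target_class, ": |lower| = ",
      length(x$lower), ", |upper| = ", length(x$upper), ", |boundary| = ",
      length(x$boundary), "\n", sep = "")
  invisible(x)
}

#' Positive region and quality of classification
#'
#' The positive region is the union over classes of lower approximations: the
#' records whose block is decision-pure. `quality_gamma()` is its fraction of
#' the table; gamma = 1 exactly when the table is consistent with respect to
#' `attrs`.
#'
#' @inheritParams indiscernibility
#' @return `positive_region()`: sorted integer vector of record indices;
#'   `quality_gamma()`: a number in `[0, 1]`.
#' @export
positive_region <- function(table, attrs) {
  blocks <- indiscernibility(table, attrs)
  dec <- table$decision
  pos <- lapply(blocks, function(b) {
    if (length(unique(dec[b])) == 1L) b else integer(0)
  })
  sort(unlist(pos, use.names = FALSE))
}

#' @rdname positive_region
#' @export
quality_gamma <- function(table, attrs) {
  length(positive_region(table, attrs)) / nrow(table)
}

# beta-lower approximation (variable-precision model): union of blocks in
# which at least a fraction beta of the records carry `target_class`.
# beta = 1 recovers the classical lower approximation.
beta_lower <- function(table, attrs, target_class, beta = 1) {
  check_beta(beta)
  blocks <- indiscernibility(table, attrs)
  dec <- table$decision
  keep <- lapply(blocks, function(b) {
    if (mean(dec[b] == target_class) >= beta) b else integer(0)
  })
  sort(unlist(keep, use.names = FALSE))
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0.5 || beta > 1) {
    stop("beta must lie in (0.5, 1]", call. = FALSE)
  }
  invisible(beta)
}

#' Discernibility matrix
#'
#' For every pair of records with different decisions, the set of condition
#' attributes on which they differ. Pairs with equal deltas but different
#' decisions (contradictory pairs) get an empty entry; they cannot be
#' discerned and are reported as inconsistency evidence instead of feeding
#' the reduct computation.
#'
#' @param table A `decision_table`.
#' @return Object of class `discernibility_matrix`: list with `pairs`
#'   (data frame of record indices `i`, `j`), `attrs` (list of character
#'   vectors, parallel to `pairs`; possibly empty), and `contradictory`
#'   (data frame of contradictory index pairs).
#' @export
discernibility_matrix <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  attrs <- table_attrs(table)
  n <- nrow(table)
  m <- as.matrix(as.data.frame(table)[attrs])
  dec <- table$decision
  ii <- jj <- integer(0)
  ent <- list()
  ci <- cj <- integer(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      js <- which(dec[(i + 1L):n] != dec[i]) + i
      for (j in js) {
        diff_attrs <- attrs[m[i, ] != m[j, ]]
        if (length(diff_attrs)) {
          ii <- c(ii, i); jj <- c(jj, j)
          ent[[length(ent) + 1L]] <- diff_attrs
        } else {
          ci <- c(ci, i); cj <- c(cj, j)
        }
      }
    }
  }
  structure(list(pairs = data.frame(i = ii, j = jj),
                 attrs = ent,
                 contradictory = data.frame(i = ci, j = cj)),
            class = "discernibility_matrix")
}

#' @export
print.discernibility_matrix <- function(x, ...) {
  cat("Discernibility matrix: ", nrow(x$pairs), " discernible decision-differing",
      " pairs, ", nrow(x$contradictory), " contradictory pairs\n", sep = "")
  invisible(x)
}

#' Reducts of a decision table
#'
#' A reduct is a minimal attribute subset preserving the positive region of
#' the full attribute set. `mode = "exhaustive"` enumerates all subsets
#' (allowed up to `max_exhaustive` attributes) and returns every reduct;
#' `mode = "greedy"` runs Johnson's heuristic on the discernibility matrix --
#' repeatedly pick the attribute occurring in the most uncovered nonempty
#' entries (ties broken lexicographically), then prune attributes whose
#' removal keeps the positive region -- and returns a single reduct.
#'
#' @param table A `decision_table`.
#' @param mode `"greedy"` (default) or `"exhaustive"`.
#' @param max_exhaustive Upper bound on the attribute count for exhaustive
#'   search (default 15).
#' @return For `"exhaustive"`, a list of character vectors (each sorted in
#'   table-attribute order); for `"greedy"`, a single character vector.
#' @export
find_reducts <- function(table, mode = c("greedy", "exhaustive"),
                         max_exhaustive = 15L) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "decision_table"))
  attrs <- table_attrs(table)
  m <- length(attrs)
  full_pos <- length(positive_region(table, attrs))

  if (mode == "exhaustive") {
    if (m > max_exhaustive) {
      stop("exhaustive reduct search is limited to ", max_exhaustive,
           " attributes (table has ", m, "); use mode = \"greedy\"",
           call. = FALSE)
    }
    pos_size <- integer(2^m - 1L)
    for (mask in seq_len(2^m - 1L)) {
      sub <- attrs[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]
      pos_size[mask] <- length(positive_region(table, sub))
    }
    reducts <- list()
    for (mask in seq_len(2^m - 1L)) {
      if (pos_size[mask] != full_pos) next
      bits <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
      # gamma is monotone in the attribute set, so minimality reduces to
      # every single-attribute removal breaking the positive region
      minimal <- all(vapply(bits, function(b) {
        sub_mask <- mask - bitwShiftL(1L, b - 1L)
        sub_mask == 0L || pos_size[sub_mask] != full_pos
      }, logical(1)))
      if (minimal) reducts[[length(reducts) + 1L]] <- attrs[bits]
    }
    return(reducts)
  }

  # Johnson greedy cover of the discernibility matrix
  dm <- discernibility_matrix(table)
  entries <- dm$attrs
  chosen <- character(0)
  uncovered <- seq_along(entries)
  while (length(uncovered)) {
    freq <- table(factor(unlist(entries[uncovered], use.names = FALSE),
                         levels = attrs))
    top <- attrs[freq == max(freq)]
    best <- top[order(top)][1L] # ties: lexicographic by attribute name
    chosen <- c(chosen, best)
    uncovered <- uncovered[!vapply(entries[uncovered],
                                   function(e) best %in% e, logical(1))]
  }
  if (!length(chosen)) chosen <- attrs[1L] # degenerate: single-class table
  # prune to minimality (last-added first)
  for (a in rev(chosen)) {
    cand <- setdiff(chosen, a)
    if (length(cand) &&
        length(positive_region(table, cand)) == full_pos) {
      chosen <- cand
    }
  }
  attrs[attrs %in% chosen]
}

#' Core attributes
#'
#' The core is the intersection of all reducts: the attributes that cannot be
#' removed without shrinking the positive region. Computed directly as the
#' attributes occurring as singleton entries' only discerning attribute, via
#' the exhaustive reduct set for small tables, or as single-removal tests.
#'
#' @param table A `decision_table`.
#' @return Character vector (possibly empty) of core attribute names.
#' @export
core_attributes <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  attrs <- table_attrs(table)
  full_pos <- length(positive_region(table, attrs))
  # a is in the core iff removing it shrinks the positive region
  keep <- vapply(attrs, function(a) {
    rest <- setdiff(attrs, a)
    if (!length(rest)) return(full_pos > 0L)
    length(positive_region(table, rest)) != full_pos
  }, logical(1))
  attrs[keep]
}

#' Inconsistency report
#'
#' Lists the groups of records whose delta vectors coincide while their
#' decisions conflict, plus per-class boundary-region sizes under the full
#' attribute set.
#'
#' @param table A `decision_table`.
#' @return List with `gamma`, `conflict_groups` (list of integer index
#'   vectors) and `boundary_sizes` (named vector over classes).
#' @export
inconsistency_report <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  attrs <- table_attrs(table)
  blocks <- indiscernibility(table, attrs)
  dec <- table$decision
  conflicts <- Filter(function(b) length(unique(dec[b])) > 1L, blocks)
  boundary <- vapply(0:2, function(k) {
    length(approximate(table, attrs, k)$boundary)
  }, integer(1))
  list(gamma = quality_gamma(table, attrs),
       conflict_groups = conflicts,
       boundary_sizes = stats::setNames(boundary, as.character(0:2)))
}
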