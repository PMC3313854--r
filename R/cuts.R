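# Discretization cuts for interval rules, found by Boolean reasoning.
# Candidate cuts sit at midpoints between consecutive observed values of an
# attribute. Cuts are retained greedily until every discernible
# decision-differing record pair is discerned. The greedy score of a
# candidate is balanced: the number of still-undiscerned decision-differing
# pairs it discerns minus the number of same-decision pairs it splits within
# the cells of the current discretization. The penalty term is what keeps
# cuts off attributes that are merely correlated with the decision by
# sampling accident: a spurious cut separates same-class pairs at the same
# rate as different-class ones, while a cut on a true class boundary splits
# almost no same-class pair. A final pass drops cuts that became redundant.

#' Find discretization cuts for a decision table
#'
#' @param table A nonempty `decision_table`.
#' @return Data frame of class `cut_set` with columns `attribute` and
#'   `threshold` (half-integer cut value), ordered by attribute then
#'   threshold. Constant attributes yield no cuts. The retained cuts discern
#'   every decision-differing record pair that the full integer
#'   representation discerns.
#' @export
find_cuts <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  if (!nrow(table)) stop("decision table is empty", call. = FALSE)
  attrs <- table_attrs(table)
  m <- as.matrix(as.data.frame(table)[attrs])
  dec <- table$decision
  n <- nrow(m)

  # candidate cuts: midpoints between consecutive distinct observed values
  cand_attr <- character(0)
  cand_thr <- numeric(0)
  for (a in attrs) {
    v <- sort(unique(m[, a]))
    if (length(v) > 1L) {
      mids <- (v[-1L] + v[-length(v)]) / 2
      cand_attr <- c(cand_attr, rep(a, length(mids)))
      cand_thr <- c(cand_thr, mids)
    }
  }
  empty <- data.frame(attribute = character(0), threshold = numeric(0))
  class(empty) <- c("cut_set", "data.frame")
  if (!length(cand_attr)) return(empty)

  # record pairs: decision-differing discernible pairs (contradictory ones,
  # identical on every attribute, are skipped) and same-decision pairs
  di <- dj <- si <- sj <- integer(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      differs <- rowSums(m[rest, , drop = FALSE] !=
                           matrix(m[i, ], length(rest), ncol(m), byrow = TRUE)) > 0L
      dd <- dec[rest] != dec[i]
      js <- rest[dd & differs]
      di <- c(di, rep(i, length(js))); dj <- c(dj, js)
      js <- rest[!dd]
      si <- c(si, rep(i, length(js))); sj <- c(sj, js)
    }
  }
  if (!length(di)) return(empty)

  k <- length(cand_attr)
  disc_diff <- matrix(FALSE, k, length(di))
  disc_same <- matrix(FALSE, k, length(si))
  for (q in seq_len(k)) {
    v <- m[, cand_attr[q]]
    disc_diff[q, ] <- (v[di] < cand_thr[q]) != (v[dj] < cand_thr[q])
    if (length(si)) {
      disc_same[q, ] <- (v[si] < cand_thr[q]) != (v[sj] < cand_thr[q])
    }
  }

  ord <- order(cand_attr, cand_thr) # deterministic tie-breaking order
  chosen <- integer(0)
  uncovered <- rep(TRUE, length(di))
  cell <- rep("", n) # current discretization cell of each record
  while (any(uncovered)) {
    gain <- rowSums(disc_diff[, uncovered, drop = FALSE])
    same_cell <- if (length(si)) cell[si] == cell[sj] else logical(0)
    penalty <- if (length(si)) rowSums(disc_same[, same_cell, drop = FALSE]) else 0
    score <- ifelse(gain > 0L, gain - penalty, -Inf)
    if (all(!is.finite(score))) break # cannot happen: every pair differs somewhere
    best <- ord[which.max(score[ord])]
    chosen <- c(chosen, best)
    uncovered[uncovered] <- !disc_diff[best, uncovered]
    v <- m[, cand_attr[best]]
    cell <- paste(cell, v < cand_thr[best])
  }

  # redundancy pruning, last-selected first
  for (q in rev(chosen)) {
    rest <- setdiff(chosen, q)
    if (length(rest) && all(colSums(disc_diff[rest, , drop = FALSE]) > 0L)) {
      chosen <- rest
    }
  }

  out <- data.frame(attribute = cand_attr[chosen], threshold = cand_thr[chosen],
                    stringsAsFactors = FALSE)
  out <- out[order(out$attribute, out$threshold), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cut_set", "data.frame")
  out
}

#' @export
print.cut_set <- function(x, ...) {
  cat("Cut set: ", nrow(x), " cuts on ", length(unique(x$attribute)),
      " attributes\n", sep = "")
  NextMethod()
}
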