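# Brute-force oracle: literal set-comprehension implementations of the
# rough-set definitions, kept deliberately independent of the package's code
# paths (per-record loops instead of partition reuse; reduct minimality by
# full subset enumeration).

oracle_block_of <- function(m, attrs, i) {
  which(apply(m[, attrs, drop = FALSE], 1L, function(row) {
    all(row == m[i, attrs])
  }))
}

oracle_approx <- function(m, dec, attrs, class) {
  lower <- integer(0)
  upper <- integer(0)
  for (i in seq_len(nrow(m))) {
    b <- oracle_block_of(m, attrs, i)
    if (all(dec[b] == class)) lower <- c(lower, i)
    if (any(dec[b] == class)) upper <- c(upper, i)
  }
  list(lower = sort(unique(lower)), upper = sort(unique(upper)))
}

oracle_positive_region <- function(m, dec, attrs) {
  pos <- integer(0)
  for (i in seq_len(nrow(m))) {
    b <- oracle_block_of(m, attrs, i)
    if (length(unique(dec[b])) == 1L) pos <- c(pos, i)
  }
  sort(unique(pos))
}

oracle_gamma <- function(m, dec, attrs) {
  length(oracle_positive_region(m, dec, attrs)) / nrow(m)
}

# all reducts by the definition: subsets preserving the positive region with
# no preserving proper subset
oracle_reducts <- function(m, dec, attrs) {
  full <- length(oracle_positive_region(m, dec, attrs))
  subsets <- unlist(lapply(seq_along(attrs), function(k) {
    utils::combn(attrs, k, simplify = FALSE)
  }), recursive = FALSE)
  preserving <- Filter(function(s) {
    length(oracle_positive_region(m, dec, s)) == full
  }, subsets)
  Filter(function(s) {
    !any(vapply(preserving, function(p) {
      length(p) < length(s) && all(p %in% s)
    }, logical(1)))
  }, preserving)
}

# random decision tables small enough for exhaustive checks; value ranges are
# kept narrow so that indiscernible and contradictory rows actually occur
random_small_table <- function(n_attr = sample(2:6, 1L),
                               n = sample(5:40, 1L),
                               values = if (stats::runif(1) < 0.5) 0:1 else -1:1) {
  attrs <- paste0("a", seq_len(n_attr))
  df <- as.data.frame(stats::setNames(
    lapply(attrs, function(a) sample(values, n, replace = TRUE)), attrs))
  df$decision <- sample(0:2, n, replace = TRUE)
  decision_table(df, attrs)
}

canon_sets <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1)))
}
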