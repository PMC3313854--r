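# Synthetic cohort simulator: paired UPDRS motor exams about eight months
# apart, a deterministic ground-truth deterioration labeler, and a panel of
# imperfectly agreeing experts. The generator mirrors the statistical shape
# of the clinical setting -- 0..4 integer item scores, asymmetric left/right
# progression, mostly-stable patients with a minority deteriorating -- so the
# induction and evaluation layers are testable without clinical data.

#' Simulation configuration
#'
#' Defaults emulate the study cohort: 47 patients contributing 74 exam pairs
#' (some patients have two historical exams), 4 experts per pair, exams about
#' 8 months apart. Each pair is assigned a latent progression state --
#' stable, mild or severe -- that drives per-item integer increments; left
#' and right sides progress independently (the disease is asymmetric) and a
#' small probability of improvement is allowed.
#'
#' @param n_patients Number of patients (default 47).
#' @param n_pairs Number of (historical, current) exam pairs (default 74).
#' @param n_experts Experts labeling every pair (default 4).
#' @param expert_noise Per-expert probability of deviating from the true
#'   class, in `[0, 0.5)` (default 0.15). Disagreement is ordinal: a wrong
#'   vote moves to an adjacent class, never straight from stable to alarm.
#' @param severity_profile See [default_severity_profile()].
#' @param ground_truth A labeler from [severity_labeler()] or an explicit
#'   `rule_set` applied through [classify()].
#' @param schema An [updrs_schema()].
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 47L, n_pairs = 74L, n_experts = 4L,
                              expert_noise = 0.15,
                              severity_profile = default_severity_profile(),
                              ground_truth = severity_labeler(),
                              schema = updrs_schema(), seed = 1L) {
  stopifnot(n_experts >= 1L, n_pairs >= 1L, n_patients >= 1L)
  if (expert_noise < 0 || expert_noise >= 0.5) {
    stop("expert_noise must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), n_pairs = as.integer(n_pairs),
                 n_experts = as.integer(n_experts), expert_noise = expert_noise,
                 severity_profile = severity_profile, ground_truth = ground_truth,
                 schema = schema, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Recognized keys: `n_patients`, `n_pairs`, `n_experts`, `expert_noise`,
#' `seed`, and optionally `labeler: {weights: {attr: w, ...}, warn_at,
#' alarm_at}`. Unlisted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("n_patients", "n_pairs", "n_experts", "expert_noise", "seed"))]
  if (!is.null(raw$labeler)) {
    args$ground_truth <- severity_labeler(
      weights = unlist(raw$labeler$weights),
      warn_at = raw$labeler$warn_at %||% 1,
      alarm_at = raw$labeler$alarm_at %||% 2
    )
  }
  do.call(simulation_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default severity profile
#'
#' Baseline scores are drawn per item from a mid-weighted distribution over
#' 0..4. Each exam pair carries a latent progression state with mixture
#' weights 40% stable / 40% mild / 20% severe; per-item score increments over
#' the inter-exam interval are then drawn independently per attribute (hence
#' asymmetric sides) from the state's distribution over -1..3 and clipped so
#' scores stay in 0..4. Stable patients are nearly static, severe ones
#' frequently worsen by two points on individual items.
#'
#' @return A list with `baseline_probs` (over scores 0..4), `state_probs`
#'   (stable/mild/severe) and `increment_probs` (matrix states x increments
#'   -1..3).
#' @export
default_severity_profile <- function() {
  inc <- rbind(
    stable = c(0.05, 0.90, 0.05, 0.00, 0.00),
    mild   = c(0.05, 0.62, 0.25, 0.08, 0.00),
    severe = c(0.03, 0.37, 0.30, 0.25, 0.05)
  )
  colnames(inc) <- as.character(-1:3)
  list(
    baseline_probs = c(0.20, 0.35, 0.25, 0.15, 0.05),
    state_probs = c(stable = 0.4, mild = 0.4, severe = 0.2),
    increment_probs = inc
  )
}

#' Weighted-severity ground-truth labeler
#'
#' Deterministic class assignment from a delta vector: the severity of a
#' record is the maximum over attributes of `weight x positive delta`
#' (improvements never raise severity, so a pure-improvement record is always
#' stable). Severity at or above `alarm_at` is class 2, at or above `warn_at`
#' class 1, otherwise class 0. The default weights put all mass on the axial
#' triad -- falling (d13), freezing of gait (d14) and gait (d29) -- the
#' red-flag symptoms whose worsening drives clinical alerts; a one-point
#' worsening there is a warning and a two-point worsening an alarm.
#'
#' @param weights Named nonnegative weights per attribute; unnamed attributes
#'   get weight 0.
#' @param warn_at,alarm_at Severity thresholds, `0 < warn_at <= alarm_at`.
#' @return A function of class `severity_labeler` mapping a delta vector (or
#'   `delta_record`) to a class in `{0,1,2}`.
#' @export
severity_labeler <- function(weights = c(d13 = 1, d14 = 1, d29 = 1),
                             warn_at = 1, alarm_at = 2) {
  stopifnot(all(weights >= 0), warn_at > 0, alarm_at >= warn_at)
  f <- function(record) {
    deltas <- if (inherits(record, "delta_record")) record$deltas else unlist(record)
    w <- weights[intersect(names(weights), names(deltas))]
    sev <- if (length(w)) max(0, w * pmax(deltas[names(w)], 0)) else 0
    if (sev >= alarm_at) 2L else if (sev >= warn_at) 1L else 0L
  }
  attr(f, "weights") <- weights
  attr(f, "warn_at") <- warn_at
  attr(f, "alarm_at") <- alarm_at
  class(f) <- c("severity_labeler", "function")
  f
}

apply_labeler <- function(labeler, record) {
  if (inherits(labeler, "rule_set")) {
    classify(labeler, record)$predicted
  } else {
    labeler(record)
  }
}

#' Simulate paired UPDRS examinations
#'
#' @param config A [simulation_config()].
#' @return List of `n_pairs` elements, each a list with `historical` and
#'   `current` [updrs_exam()]s roughly eight months apart.
#' @export
simulate_exam_pairs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rng <- local_rng(config$seed)
  prof <- config$severity_profile
  attrs <- config$schema$attributes
  n_attr <- length(attrs)
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  # every patient contributes one pair; the surplus pairs reuse patients
  # (a second historical exam), mirroring the cohort bookkeeping
  pair_patient <- patients[c(seq_len(config$n_patients),
                             seq_len(max(0L, config$n_pairs - config$n_patients)))]
  pair_patient <- pair_patient[seq_len(config$n_pairs)]
  states <- names(prof$state_probs)
  incs <- as.integer(colnames(prof$increment_probs))

  lapply(seq_len(config$n_pairs), function(p) {
    base <- rng$rint(n_attr, prof$baseline_probs, 0:4)
    state <- rng$rint(1L, prof$state_probs, seq_along(states))
    inc <- rng$rint(n_attr, prof$increment_probs[state, ], incs)
    cur <- pmin(4L, pmax(0L, base + inc))
    day0 <- as.Date("2010-01-01") + rng$rint(1L, rep(1, 365), 0:364)
    gap <- 240L + rng$rint(1L, rep(1, 61), -30:30) # ~8 months +/- one
    h <- updrs_exam(pair_patient[p], day0,
                    stats::setNames(as.integer(base), attrs), config$schema)
    cu <- updrs_exam(pair_patient[p], day0 + gap,
                     stats::setNames(as.integer(cur), attrs), config$schema)
    list(historical = h, current = cu)
  })
}

#' Label exam pairs with a panel of noisy experts
#'
#' Each expert reports the ground-truth class with probability
#' `1 - expert_noise` and otherwise an adjacent class (stable and alarm
#' confusions always pass through warning; a warning flips to stable or alarm
#' with equal probability). Votes are flattened into one record per
#' (pair, expert) and the table is deduplicated.
#'
#' @param pairs Exam pairs from [simulate_exam_pairs()], or a list of
#'   `delta_record`s.
#' @param labeler Ground-truth labeler ([severity_labeler()] or a
#'   `rule_set`).
#' @param n_experts Number of experts.
#' @param expert_noise Disagreement probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param dedup Deduplicate the flattened table (default `TRUE`).
#' @return A `decision_table` with `expert_id` and `patient_id` provenance.
#' @export
label_with_experts <- function(pairs, labeler, n_experts = 4L,
                               expert_noise = 0.15, seed = 1L, dedup = TRUE) {
  if (expert_noise < 0 || expert_noise >= 0.5) {
    stop("expert_noise must lie in [0, 0.5)", call. = FALSE)
  }
  records <- lapply(pairs, function(p) {
    if (inherits(p, "delta_record")) p else compute_delta(p$historical, p$current)
  })
  truth <- vapply(records, function(r) apply_labeler(labeler, r), integer(1))
  rng <- local_rng(seed)
  n <- length(records)
  votes <- expand.grid(pair = seq_len(n), expert = seq_len(n_experts))
  wrong <- rng$runif(nrow(votes)) < expert_noise
  flip <- rng$runif(nrow(votes)) # direction for class-1 errors
  vote <- truth[votes$pair]
  vote[wrong & vote == 0L] <- 1L
  vote[wrong & vote == 2L] <- 1L
  one_wrong <- wrong & truth[votes$pair] == 1L
  vote[one_wrong] <- ifelse(flip[one_wrong] < 0.5, 0L, 2L)
  tab <- build_decision_table(
    records,
    data.frame(pair = votes$pair,
               expert_id = sprintf("E%d", votes$expert),
               decision = vote)
  )
  if (dedup) deduplicate(tab) else tab
}

#' Cohort-scale bookkeeping fixture
#'
#' A deterministic 296-row decision table: 74 exam pairs, 4 unanimous
#' experts. Four of the pairs are fully stable re-examinations with an
#' unchanged score vector (a realistic feature of short-interval follow-up),
#' and all remaining delta vectors are pairwise distinct, so each expert's
#' 74-row table contains exactly 3 repeated entries: 12 duplicates in total,
#' and [deduplicate()] leaves exactly 284 records.
#'
#' @param seed Integer seed (default 1).
#' @return A `decision_table` with 296 rows (before deduplication).
#' @export
make_cohort_fixture <- function(seed = 1L) {
  config <- simulation_config(expert_noise = 0, seed = seed)
  pairs <- simulate_exam_pairs(config)
  # four identical-score follow-ups: the all-zero delta vector, four times
  for (p in 1:4) {
    pairs[[p]]$current <- updrs_exam(pairs[[p]]$current$patient_id,
                                     pairs[[p]]$current$exam_date,
                                     pairs[[p]]$historical$scores,
                                     config$schema)
  }
  # make the remaining 70 delta vectors pairwise distinct and nonzero by a
  # deterministic one-point bump on the first adjustable light attribute
  attrs <- config$schema$attributes
  bump_attrs <- setdiff(attrs, c("d13", "d14", "d29"))
  repeat {
    deltas <- vapply(pairs, function(p) {
      paste(p$current$scores - p$historical$scores, collapse = ",")
    }, character(1))
    zero_key <- paste(rep(0L, length(attrs)), collapse = ",")
    clash <- which(duplicated(deltas) | (deltas == zero_key))
    clash <- setdiff(clash, 1:4)
    if (!length(clash)) break
    p <- clash[1L]
    sc <- pairs[[p]]$current$scores
    a <- bump_attrs[which(sc[bump_attrs] < 4L)][1L]
    if (is.na(a)) a <- bump_attrs[1L] # all saturated: lower instead
    sc[a] <- if (sc[a] < 4L) sc[a] + 1L else sc[a] - 1L
    pairs[[p]]$current <- updrs_exam(pairs[[p]]$current$patient_id,
                                     pairs[[p]]$current$exam_date, sc, config$schema)
  }
  label_with_experts(pairs, config$ground_truth, n_experts = 4L,
                     expert_noise = 0, seed = seed, dedup = FALSE)
}
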