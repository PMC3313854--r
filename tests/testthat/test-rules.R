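test_that("a one-attribute consistent table induces the two threshold rules", {
  tab <- toy_table(d29 = c(0, 0, 1, 2), decision = c(0, 0, 1, 1))
  rs <- induce_rules(tab)
  rendered <- sort(vapply(rs$rules, render_rule, character(1)))
  expect_identical(rendered,
                   sort(c("If\u0394UPDRS29<1=>output=0-'stable'",
                          "If0<\u0394UPDRS29=>output=1-'warning'")))
  expect_true(all(vapply(rs$rules, function(r) r$confidence, numeric(1)) == 1))
})

test_that("a single-class table yields one unconditional rule", {
  tab <- toy_table(d13 = c(0, 1, 2), decision = c(0, 0, 0))
  rs <- induce_rules(tab)
  expect_length(rs$rules, 1L)
  expect_identical(render_rule(rs$rules[[1]]), "Iftrue=>output=0-'stable'")
})

test_that("stored support and confidence equal a from-scratch recount", {
  tab <- deduplicate(make_cohort_fixture(seed = 1))
  for (rs in list(induce_rules(tab), generalize_rules(tab, beta = 0.8))) {
    for (r in rs$rules) {
      df <- as.data.frame(tab)
      hit <- rep(TRUE, nrow(df))
      for (cond in r$conditions) {
        hit <- hit & df[[cond$attribute]] > cond$low & df[[cond$attribute]] < cond$high
      }
      expect_identical(r$support, sum(hit))
      expect_equal(r$confidence, mean(df$decision[hit] == r$decision))
      expect_gte(r$support, 1L)
    }
  }
})

test_that("RS rules are certain and cover the positive region of their class", {
  set.seed(23)
  for (k in 1:8) {
    tab <- deduplicate(random_small_table(n_attr = 3, n = 30))
    rs <- suppressWarnings(induce_rules(tab))
    attrs <- table_attrs(tab)
    df <- as.data.frame(tab)
    expect_true(all(vapply(rs$rules, function(r) r$confidence, numeric(1)) == 1))
    for (cls in 0:2) {
      low <- approximate(tab, attrs, cls)$lower
      if (!length(low)) next
      covered <- rep(FALSE, nrow(df))
      for (r in rs$rules) {
        if (r$decision != cls) next
        hit <- rep(TRUE, nrow(df))
        for (cond in r$conditions) {
          hit <- hit & df[[cond$attribute]] > cond$low & df[[cond$attribute]] < cond$high
        }
        covered <- covered | hit
      }
      expect_true(all(covered[low]))
    }
  }
})

test_that("beta = 1 reproduces the classical model's training classifications", {
  tab <- deduplicate(make_cohort_fixture(seed = 2))
  rs <- induce_rules(tab)
  rsg <- generalize_rules(tab, beta = 1)
  df <- as.data.frame(tab)[table_attrs(tab)]
  for (i in seq_len(nrow(df))) {
    rec <- stats::setNames(as.integer(unlist(df[i, ])), names(df))
    expect_identical(classify(rsg, rec)$predicted, classify(rs, rec)$predicted)
  }
})

test_that("a condition whose removal keeps confidence above beta is dropped", {
  # four (A=1,B=0) warnings, one (A=1,B=1) stable, two (A=0,B=0) stable:
  # RS needs both 0<A and B<1 to stay certain; at beta = 0.8 dropping B<1
  # keeps confidence 0.8 (dropping 0<A would fall to 4/6), so B<1 goes
  tab <- toy_table(A = c(1, 1, 1, 1, 1, 0, 0), B = c(0, 0, 0, 0, 1, 0, 0),
                   decision = c(1, 1, 1, 1, 0, 0, 0))
  rs <- induce_rules(tab)
  warn_rs <- Filter(function(r) r$decision == 1L, rs$rules)
  expect_identical(length(warn_rs[[1]]$conditions), 2L)

  rsg <- generalize_rules(tab, beta = 0.8)
  warn_g <- Filter(function(r) r$decision == 1L, rsg$rules)
  expect_identical(length(warn_g[[1]]$conditions), 1L)
  expect_identical(warn_g[[1]]$conditions[[1]]$attribute, "A")
  expect_equal(warn_g[[1]]$confidence, 0.8)
  expect_identical(warn_g[[1]]$support, 5L)
})

test_that("lowering beta never shrinks the beta-positive region", {
  set.seed(29)
  for (k in 1:10) {
    tab <- random_small_table()
    attrs <- table_attrs(tab)
    for (cls in 0:2) {
      b_hi <- updrsalert:::beta_lower(tab, attrs, cls, beta = 0.9)
      b_lo <- updrsalert:::beta_lower(tab, attrs, cls, beta = 0.6)
      expect_true(all(b_hi %in% b_lo))
    }
  }
})

test_that("RS-g is usually no larger than RS on noisy tables", {
  smaller <- 0L
  for (r in 1:10) {
    cfg <- simulation_config(n_patients = 40, n_pairs = 40, expert_noise = 0.15,
                             seed = 300 + r)
    pairs <- simulate_exam_pairs(cfg)
    tab <- label_with_experts(pairs, severity_labeler(), 4, 0.15, seed = 300 + r)
    cuts <- find_cuts(tab)
    n_rs <- length(induce_rules(tab, cuts)$rules)
    n_rsg <- length(generalize_rules(tab, cuts, beta = 0.8)$rules)
    smaller <- smaller + (n_rsg <= n_rs)
  }
  expect_gte(smaller, 6L)
})

test_that("beta outside (0.5, 1] is rejected", {
  tab <- toy_table(a = c(0, 1), decision = c(0, 1))
  expect_error(generalize_rules(tab, beta = 0.5), "beta")
  expect_error(generalize_rules(tab, beta = 1.2), "beta")
})

test_that("rendering matches the report style for every condition shape", {
  expect_identical(render_rule(printed_rule()), printed_rule_string())
  unc <- decision_rule(list(), 0L, support = 3L, confidence = 1)
  expect_identical(render_rule(unc), "Iftrue=>output=0-'stable'")
  two_sided <- decision_rule(list(rule_condition("d23LH", low = -1, high = 2)), 2L)
  expect_identical(render_rule(two_sided),
                   "If-1<\u0394UPDRS23LH<2=>output=2-'alarm'")
})

test_that("rendering is injective over induced rule sets", {
  tab <- deduplicate(make_cohort_fixture(seed = 3))
  rs <- induce_rules(tab)
  rendered <- vapply(rs$rules, render_rule, character(1))
  expect_identical(anyDuplicated(rendered), 0L)
})

test_that("rule-set JSON round trip preserves structure and rendering", {
  tab <- deduplicate(make_cohort_fixture(seed = 1))
  for (rs in list(induce_rules(tab), generalize_rules(tab, beta = 0.8))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_ruleset_json(rs, path)
    back <- read_ruleset_json(path)
    expect_identical(back$mode, rs$mode)
    expect_identical(vapply(back$rules, render_rule, character(1)),
                     vapply(rs$rules, render_rule, character(1)))
    expect_identical(vapply(back$rules, function(r) r$support, integer(1)),
                     vapply(rs$rules, function(r) r$support, integer(1)))
  }
})

test_that("induction is deterministic: same table, same rule set", {
  tab <- deduplicate(make_cohort_fixture(seed = 4))
  r1 <- induce_rules(tab)
  r2 <- induce_rules(tab)
  expect_identical(vapply(r1$rules, render_rule, character(1)),
                   vapply(r2$rules, render_rule, character(1)))
})

test_that("invalid conditions are rejected", {
  expect_error(rule_condition("d13", low = 1, high = 2), "no integer")
  expect_error(decision_rule(list(rule_condition("d13", high = 1),
                                  rule_condition("d13", low = 0)), 1L),
               "same attribute")
})
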