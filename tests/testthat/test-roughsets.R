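test_that("indiscernibility groups records that agree on the chosen attributes", {
  tab <- toy_table(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1), decision = c(0, 0, 1, 1))
  expect_identical(indiscernibility(tab, c("a", "b")),
                   list(1L, 2L, 3L, 4L)) # all rows distinct -> singletons
  expect_identical(indiscernibility(tab, "a"), list(c(1L, 2L), c(3L, 4L)))
  expect_error(indiscernibility(tab, "z"), "unknown attribute")
  expect_error(indiscernibility(tab, character(0)), "nonempty")
})

test_that("partitions refine as attributes are added", {
  set.seed(5)
  for (k in 1:15) {
    tab <- random_small_table()
    attrs <- table_attrs(tab)
    sub <- sample(attrs, sample(seq_along(attrs), 1))
    fine <- indiscernibility(tab, attrs)
    coarse <- indiscernibility(tab, sub)
    for (b in fine) {
      expect_true(any(vapply(coarse, function(cb) all(b %in% cb), logical(1))))
    }
  }
})

test_that("approximations sandwich the class and detect contradictions", {
  # consistent table: lower = upper = class set
  tab <- toy_table(a = c(0, 0, 1, 2), decision = c(0, 0, 1, 2))
  ap <- approximate(tab, "a", 0)
  expect_identical(ap$lower, c(1L, 2L))
  expect_identical(ap$upper, c(1L, 2L))
  expect_length(ap$boundary, 0L)

  # three identical rows with decisions 0,0,1: class 0 has empty lower,
  # full upper
  tab2 <- toy_table(a = c(1, 1, 1), decision = c(0, 0, 1))
  ap2 <- approximate(tab2, "a", 0)
  expect_length(ap2$lower, 0L)
  expect_identical(ap2$upper, 1:3)

  set.seed(8)
  for (k in 1:15) {
    tab <- random_small_table()
    attrs <- table_attrs(tab)
    for (cls in 0:2) {
      ap <- approximate(tab, attrs, cls)
      cls_set <- which(tab$decision == cls)
      expect_true(all(ap$lower %in% cls_set))
      expect_true(all(cls_set %in% ap$upper))
      expect_true(all(ap$lower %in% ap$upper))
    }
  }
})

test_that("gamma measures consistency and grows with attributes", {
  tab <- toy_table(a = c(0, 0, 1, 2), decision = c(0, 0, 1, 2))
  expect_identical(quality_gamma(tab, "a"), 1)
  tab2 <- toy_table(a = c(1, 1, 1), decision = c(0, 0, 1))
  expect_identical(quality_gamma(tab2, "a"), 0)

  set.seed(13)
  for (k in 1:15) {
    tab <- random_small_table()
    attrs <- table_attrs(tab)
    sub <- sample(attrs, sample(seq_along(attrs), 1))
    expect_lte(quality_gamma(tab, sub), quality_gamma(tab, attrs))
    # lower approximations of distinct classes are disjoint and union to the
    # positive region
    lows <- lapply(0:2, function(cls) approximate(tab, attrs, cls)$lower)
    expect_identical(sort(unlist(lows)), positive_region(tab, attrs))
    expect_identical(anyDuplicated(unlist(lows)), 0L)
    # gamma = 1 iff no contradictory pair
    contradictory <- nrow(discernibility_matrix(tab)$contradictory) > 0L
    expect_identical(quality_gamma(tab, attrs) == 1, !contradictory)
  }
})

test_that("discernibility matrix lists differing attributes per decision-differing pair", {
  one_class <- toy_table(a = c(0, 1, 2), decision = c(1, 1, 1))
  expect_identical(nrow(discernibility_matrix(one_class)$pairs), 0L)

  tab <- toy_table(d13 = c(0, 0), d29 = c(0, 2), decision = c(0, 2))
  dm <- discernibility_matrix(tab)
  expect_identical(dm$attrs[[1]], "d29")

  contr <- toy_table(a = c(1, 1), decision = c(0, 1))
  dmc <- discernibility_matrix(contr)
  expect_identical(nrow(dmc$pairs), 0L)
  expect_identical(nrow(dmc$contradictory), 1L)
})

test_that("no reduct keeps a duplicated attribute twice", {
  set.seed(21)
  for (k in 1:5) {
    tab <- random_small_table(n_attr = 3, n = 20)
    df <- as.data.frame(tab)
    df$a4 <- df$a1 # a4 duplicates a1 column-wise
    tab2 <- decision_table(df, c("a1", "a2", "a3", "a4"))
    reducts <- find_reducts(tab2, mode = "exhaustive")
    for (r in reducts) expect_false(all(c("a1", "a4") %in% r))
  }
})

test_that("single-attribute tables have that attribute as reduct", {
  tab <- toy_table(a = c(0, 1, 1), decision = c(0, 1, 1))
  expect_identical(find_reducts(tab, mode = "exhaustive"), list("a"))
  expect_identical(find_reducts(tab, mode = "greedy"), "a")
})

test_that("greedy reducts are genuine reducts (oracle check) and preserve gamma", {
  set.seed(33)
  for (k in 1:25) {
    tab <- random_small_table()
    attrs <- table_attrs(tab)
    m <- as.matrix(as.data.frame(tab)[attrs])
    g <- find_reducts(tab, mode = "greedy")
    expect_identical(quality_gamma(tab, g), quality_gamma(tab, attrs))
    all_reducts <- canon_sets(oracle_reducts(m, tab$decision, attrs))
    expect_true(paste(sort(g), collapse = ",") %in% all_reducts)
    # removing any attribute from the greedy reduct drops the positive region
    if (length(g) > 1L) {
      for (a in g) {
        expect_lt(quality_gamma(tab, setdiff(g, a)), quality_gamma(tab, attrs))
      }
    }
  }
})

test_that("exhaustive mode refuses oversized tables with guidance", {
  tab <- deduplicate(make_cohort_fixture(seed = 1))
  expect_error(find_reducts(tab, mode = "exhaustive"), "greedy")
})

test_that("core is the intersection of all reducts", {
  set.seed(55)
  for (k in 1:10) {
    tab <- random_small_table(n_attr = sample(2:5, 1))
    reducts <- find_reducts(tab, mode = "exhaustive")
    expected <- Reduce(intersect, reducts)
    expect_setequal(core_attributes(tab), expected)
  }
})

test_that("inconsistency report exposes conflict groups and boundaries", {
  tab <- toy_table(a = c(1, 1, 0), decision = c(0, 1, 0))
  rep <- inconsistency_report(tab)
  expect_identical(rep$gamma, 1 / 3)
  expect_identical(rep$conflict_groups, list(c(1L, 2L)))
  expect_identical(rep$boundary_sizes, c(`0` = 2L, `1` = 2L, `2` = 0L))
})
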