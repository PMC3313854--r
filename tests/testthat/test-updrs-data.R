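test_that("compute_delta subtracts per attribute and is antisymmetric", {
  e1 <- make_exam(date = "2010-01-01")
  expect_true(all(compute_delta(e1, e1)$deltas == 0L))

  e2 <- make_exam(date = "2010-09-01", d23RH = 3)
  d <- compute_delta(e1, e2)
  expect_identical(d$deltas[["d23RH"]], 2L)
  expect_true(all(d$deltas[setdiff(names(d$deltas), "d23RH")] == 0L))

  set.seed(7)
  sch <- test_schema()
  for (k in 1:20) {
    s1 <- stats::setNames(sample(0:4, 21, replace = TRUE), sch$attributes)
    s2 <- stats::setNames(sample(0:4, 21, replace = TRUE), sch$attributes)
    # same-dated exams so both orders satisfy the date precondition
    a <- updrs_exam("p", "2011-01-01", s1, sch)
    b <- updrs_exam("p", "2011-01-01", s2, sch)
    expect_identical(compute_delta(a, b)$deltas, -compute_delta(b, a)$deltas)
  }
})

test_that("compute_delta validates schema agreement and date order", {
  sub <- updrs_schema(data.frame(item = c(13, 14), laterality = "none"))
  e_small <- updrs_exam("p", "2010-01-01", c(d13 = 1, d14 = 1), sub)
  expect_error(compute_delta(e_small, make_exam()), "schema mismatch")
  expect_error(compute_delta(make_exam(date = "2012-01-01"),
                             make_exam(date = "2010-01-01")),
               "dated after")
})

test_that("expert votes flatten to one object per (pair, expert)", {
  e1 <- make_exam()
  recs <- lapply(1:74, function(p) {
    cur <- make_exam(date = "2010-09-01", d29 = (p %% 3) + 1)
    d <- compute_delta(e1, cur)
    d$deltas[["d23RH"]] <- as.integer(p %% 5 - 2) # make vectors distinct-ish
    d
  })
  votes <- expand.grid(pair = 1:74, expert_id = paste0("E", 1:4))
  votes$decision <- (votes$pair + as.integer(factor(votes$expert_id))) %% 3
  tab <- build_decision_table(recs, votes)
  expect_identical(nrow(tab), 296L)
  expect_error(build_decision_table(recs, rbind(votes, votes[1, ])),
               "duplicated")
  bad <- votes
  bad$decision[5] <- 7
  expect_error(build_decision_table(recs, bad), "decision")
})

test_that("deduplicate removes within-expert repeats, keeps conflicts, is idempotent", {
  tab <- toy_table(d13 = c(0, 0, 0, 1, 1), decision = c(0, 0, 1, 2, 2))
  dd <- deduplicate(tab)
  expect_identical(nrow(dd), 3L) # exact repeats collapse, conflict 0-vs-1 kept
  expect_identical(dd$decision, c(0L, 1L, 2L))
  expect_identical(as.data.frame(deduplicate(dd)), as.data.frame(dd))

  # distinct rows are untouched
  tab2 <- toy_table(d13 = 0:2, decision = c(0, 1, 2))
  expect_identical(nrow(deduplicate(tab2)), 3L)

  # with expert provenance, the same (deltas, decision) from different
  # experts stays: repeats are removed within each expert's table only
  df <- data.frame(d13 = c(0, 0, 0, 0), decision = c(0, 0, 0, 0),
                   expert_id = c("E1", "E1", "E2", "E3"))
  expect_identical(nrow(deduplicate(decision_table(df, "d13"))), 3L)
})

test_that("deduplicate preserves the set of distinct rows", {
  set.seed(42)
  for (k in 1:10) {
    tab <- random_small_table()
    dd <- deduplicate(tab)
    key <- function(t) unique(paste(do.call(paste, as.data.frame(t)[table_attrs(t)]),
                                    t$decision))
    expect_setequal(key(dd), key(tab))
  }
})

test_that("vote histograms count every vote", {
  expect_identical(vote_histogram(c(0, 0, 0, 0))$counts,
                   c(`0` = 4L, `1` = 0L, `2` = 0L))
  expect_identical(vote_histogram(c(0, 1, 1, 2))$counts,
                   c(`0` = 1L, `1` = 2L, `2` = 1L))
  expect_identical(vote_histogram(c(2, 2, 2, 2))$counts,
                   c(`0` = 0L, `1` = 0L, `2` = 4L))
  expect_error(vote_histogram(integer(0)), "empty")
  expect_error(vote_histogram(c(0, 3)), "decision")
  set.seed(11)
  for (k in 1:10) {
    v <- sample(0:2, sample(1:9, 1), replace = TRUE)
    expect_identical(sum(vote_histogram(v)$counts), length(v))
  }
})

test_that("exam and decision-table CSV round trips are lossless", {
  sch <- test_schema()
  exams <- list(make_exam("a", "2010-01-01", base = 2),
                make_exam("b", "2010-03-04", d13 = 4, d29 = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_exams_csv(exams, path)
  back <- read_exams_csv(path, sch)
  expect_identical(back[[2]]$scores, exams[[2]]$scores)
  expect_identical(back[[1]]$exam_date, exams[[1]]$exam_date)

  set.seed(3)
  for (k in 1:5) {
    tab <- random_small_table()
    tp <- withr::local_tempfile(fileext = ".csv")
    write_table_csv(tab, tp)
    back <- read_table_csv(tp)
    expect_identical(as.data.frame(back), as.data.frame(tab))
  }
})

test_that("malformed CSVs are rejected with row/column context", {
  sch <- updrs_schema(data.frame(item = c(13, 14), laterality = "none"))
  p <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("patient_id,exam_date,d13,d14", "p1,2010-01-01,5,0"), p)
  expect_error(read_exams_csv(p, sch), "row 1, column 'd13'")

  writeLines(c("patient_id,exam_date,d13", "p1,2010-01-01,1"), p)
  expect_error(read_exams_csv(p, sch), "missing column.*d14")

  writeLines(c("d13,d14,decision", "0,1,3"), p)
  expect_error(read_table_csv(p), "row 1, column 'decision'")

  writeLines(c("d13,d14,decision", "0,1.5,1"), p)
  expect_error(read_table_csv(p), "row 1, column 'd14'")

  writeLines(c("d13,d14", "0,1"), p)
  expect_error(read_table_csv(p), "decision")
})
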