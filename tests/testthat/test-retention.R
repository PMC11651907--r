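# retained contacts, binomial null models and the retention index

pop4 <- c("A", "B", "C", "D")

test_that("retained contacts are per-node intersections of step pairs", {
  s <- make_series(list(c("A","B", "A","C"), c("A","B", "C","D")), pop4)
  rc <- retained_contacts(s, 1)
  expect_equal(as.integer(rc$r[pop4]), c(1L, 1L, 0L, 0L))
  expect_equal(nrow(rc$pairs), 1)
  expect_true(all(rc$r <= pmin(step_degrees(s, 1), step_degrees(s, 2))))

  # identical snapshots: every contact retained
  s2 <- make_series(list(c("A","B", "C","D"), c("A","B", "C","D")), pop4)
  rc2 <- retained_contacts(s2, 1)
  expect_equal(as.integer(rc2$r), rep(1L, 4))
  expect_equal(nrow(rc2$pairs), 2)

  # disjoint snapshots: nothing retained
  s3 <- make_series(list(c("A","B"), c("C","D")), pop4)
  expect_equal(sum(retained_contacts(s3, 1)$r), 0)

  expect_error(retained_contacts(s, 2), "consecutive")
})

test_that("static null mean is the population mean degree", {
  expect_equal(static_null_mean(c(2, 1, 1, 0)), 1.0)
  expect_equal(static_null_mean(rep(0, 5)), 0)
  expect_equal(static_null_mean(rep(9, 10)), 9)  # complete graph on N = 10
})

test_that("dynamic null mean matches brute-force enumeration", {
  # single edge A-B in both steps among N = 4: full enumeration gives 1/12
  deg <- c(1, 1, 0, 0)
  expect_equal(dynamic_null_mean(deg, deg), 1 / 12)
  expect_equal(oracle_dyna_mean(deg, deg), 1 / 12)

  # random degree pairs: vectorized sum equals the double loop
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(4:12, 1)
    e1 <- rand_edges(N, sample(1:6, 1))
    e2 <- rand_edges(N, sample(1:6, 1))
    d1 <- degrees_from_edges(e1, N)
    d2 <- degrees_from_edges(e2, N)
    expect_equal(dynamic_null_mean(d1, d2), oracle_dyna_mean(d1, d2))
  }

  # empty second snapshot: nothing can be retained
  expect_equal(dynamic_null_mean(c(2, 1, 1, 0), c(0, 0, 0, 0)), 0)

  # joint reading uses per-node degree pairs
  expect_equal(dynamic_null_mean(c(1, 1, 0, 0), c(1, 1, 0, 0), joint = TRUE),
               (1 / 3 + 1 / 3) / 4)
})

test_that("null retained-contact distribution is consistent and degenerates", {
  set.seed(12)
  for (rep in 1:15) {
    N <- sample(4:12, 1)
    d1 <- degrees_from_edges(rand_edges(N, sample(1:8, 1)), N)
    d2 <- degrees_from_edges(rand_edges(N, sample(1:8, 1)), N)
    pmf <- null_retained_distribution(d1, d2)
    expect_equal(sum(pmf), 1)
    # mean of the distribution equals the analytic mean exactly
    expect_equal(sum(pmf * (seq_along(pmf) - 1)), dynamic_null_mean(d1, d2))
    # p = 1 with static degree coupling collapses to the degree distribution
    expect_identical(null_retained_distribution(d1, d2, model = "static"),
                     tabulate(d1 + 1, nbins = max(d1) + 1) / N)
  }
  # empty snapshots: point mass at zero
  expect_equal(null_retained_distribution(rep(0, 4), rep(0, 4)), 1)
})

test_that("retention index matches the hand-computed worked example", {
  s <- make_series(list(c("A","B", "A","C"), c("A","B", "C","D")), pop4)
  ri <- retention_index(s, 1)
  expect_equal(ri$r_bar_temp, 0.5)
  expect_equal(ri$r_bar_stat, 1.0)
  expect_equal(ri$r_bar_dyna, 0.25)
  expect_equal(ri$index, 1 / 3)

  # identical snapshots: index exactly 1
  s2 <- make_series(list(c("A","B", "C","D"), c("A","B", "C","D")), pop4)
  expect_equal(retention_index(s2, 1)$index, 1)

  # empty earlier snapshot: degenerate denominator, flagged undefined
  s3 <- make_series(list(NULL, c("A","B")), pop4)
  ri3 <- retention_index(s3, 1)
  expect_false(ri3$defined)
  expect_true(is.na(ri3$index))
})

test_that("retained-type breakdown counts pair label agreement", {
  at <- data.frame(node = c("A", "B", "C", "D", "E"),
                   dept = c("ICU", "ICU", "ICU", "ER", "unknown"))
  pairs <- data.frame(i = c("A", "A", "B", "C"), j = c("B", "C", "C", "D"))
  b <- retained_type_breakdown(pairs, at, "dept")
  expect_equal(b[["same-dept"]], 0.75)
  expect_equal(b[["different-dept"]], 0.25)
  expect_equal(sum(b), 1)

  # unknown labels are reported, not guessed
  b2 <- retained_type_breakdown(data.frame(i = "A", j = "E"), at, "dept")
  expect_equal(names(b2), "unknown")

  expect_equal(length(retained_type_breakdown(pairs[0, ], at, "dept")), 0)
  expect_error(retained_type_breakdown(pairs, at, "cabin"), "not in")
})

test_that("series-level summary: static median 1, IQR width 0, breakdowns", {
  s <- make_series(rep(list(c("A","B", "A","C")), 5), pop4)
  rs <- summarize_retention(s)
  expect_equal(rs$median_index, 1)
  expect_equal(diff(rs$iqr_index), 0)
  expect_equal(rs$n_defined, 4)

  # all step pairs degenerate -> explicit error
  s_empty <- make_series(list(NULL, NULL, NULL), pop4)
  expect_error(summarize_retention(s_empty), "defined step pairs")
  expect_error(summarize_retention(make_series(list(c("A","B")), pop4)),
               "at least two")

  # per-step type breakdown rides along when attributes are present
  s$node_attributes <- data.frame(node = pop4,
                                  dept = c("ICU", "ICU", "ER", "ER"))
  rs2 <- summarize_retention(s, attribute = "dept")
  expect_equal(rs2$type_breakdown[["1"]][["same-dept"]], 0.5)
  expect_equal(rs2$type_breakdown[["1"]][["different-dept"]], 0.5)
})
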