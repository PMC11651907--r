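# per-step top-80% groups, persistence curve and classification

test_that("top group is the smallest prefix reaching 80% of weight", {
  # spoke weights {10,5,3,1,1} against a shared hub: sorted node weights are
  # {20,10,5,3,1,1}; two nodes reach 75% of the total, three reach 87.5%
  pop <- c("v1", "v2", "v3", "v4", "v5", "x")
  ct <- data.frame(step = 1,
                   i = c("v1", "v2", "v3", "v4", "v5"),
                   j = c("x", "x", "x", "x", "x"),
                   seconds = c(10, 5, 3, 1, 1))
  s <- snapshot_series(ct, 1, pop, step_length = 100,
                       duration_threshold = 1)
  w <- step_weights(s, 1, "duration")
  expect_equal(as.numeric(w[c("x", "v1", "v2")]), c(20, 10, 5))
  tg <- top_group(s, 1, weight = "duration")
  expect_equal(tg, c("x", "v1", "v2"))

  # all-equal weights: ties broken by id, group size = ceil(0.8 N)
  s3 <- make_series(list(c("A","B", "C","D", "E","F", "G","H", "I","J")),
                    LETTERS[1:10])
  expect_equal(top_group(s3, 1), LETTERS[1:8])

  # single contact pair: the pair is the group
  s4 <- make_series(list(c("A","B")), LETTERS[1:4])
  expect_setequal(top_group(s4, 1), c("A", "B"))

  # empty snapshot: empty group
  s5 <- make_series(list(NULL, c("A","B")), LETTERS[1:2])
  expect_equal(top_group(s5, 1), character(0))
})

test_that("trajectory counts steps of top-group membership", {
  # static series: counts are 0 or S only
  s <- make_series(rep(list(c("A","B", "A","C", "D","E")), 4), LETTERS[1:5])
  tr <- top_group_trajectory(s)
  expect_true(all(tr$counts %in% c(0L, tr$S)))
  expect_equal(tr$S, 4)

  # a node in the group in 2 of 4 steps
  s2 <- make_series(list(c("A","B"), c("A","B"), c("C","D"), c("C","D")),
                    LETTERS[1:4])
  expect_equal(as.integer(top_group_trajectory(s2)$counts[c("A", "C")]),
               c(2L, 2L))

  # empty steps count toward S unless skipped
  s3 <- make_series(list(c("A","B"), NULL, c("A","B"), NULL), LETTERS[1:2])
  expect_equal(top_group_trajectory(s3)$S, 4)
  expect_equal(top_group_trajectory(s3, skip_empty_steps = TRUE)$S, 2)
})

test_that("persistence curve matches cumulative counting", {
  tr <- structure(list(counts = c(a = 4L, b = 2L, c = 1L, d = 0L), S = 4L,
                       weight = "contacts", threshold = 0.8,
                       p80_per_step = rep(0.5, 4)),
                  class = "top_trajectory")
  pc <- persistence_curve(tr)
  expect_equal(pc$rho, c(0.25, 0.5, 0.75, 0.75, 1.0))
  expect_equal(attr(pc, "S"), 4)

  # degenerate count patterns
  tr$counts[] <- 0L
  expect_equal(persistence_curve(tr)$rho[1], 1)
  tr$counts[] <- 4L
  expect_equal(persistence_curve(tr)$rho, c(0, 0, 0, 0, 1))
})

test_that("rho_s is non-decreasing with rho_S = 1 on random trajectories", {
  set.seed(31)
  for (rep in 1:20) {
    S <- sample(1:12, 1)
    N <- sample(2:30, 1)
    tr <- structure(list(counts = stats::setNames(sample(0:S, N, TRUE),
                                                  sprintf("n%02d", 1:N)),
                         S = S, weight = "contacts", threshold = 0.8,
                         p80_per_step = numeric(S)),
                    class = "top_trajectory")
    rho <- persistence_curve(tr)$rho
    expect_true(all(diff(rho) >= 0))
    expect_equal(rho[length(rho)], 1)
  }
})

test_that("classification thresholds: at least half vs under a quarter", {
  tr <- structure(list(counts = c(a = 4L, b = 2L, c = 1L, d = 0L), S = 4L,
                       weight = "contacts", threshold = 0.8,
                       p80_per_step = rep(0.5, 4)),
                  class = "top_trajectory")
  cl <- classify_contributors(tr)
  expect_setequal(cl$superspreaders, c("a", "b"))
  expect_setequal(cl$sse_drivers, "d")
  expect_setequal(cl$neither, "c")  # c sits exactly at S/4

  tr$counts[] <- 0L
  expect_setequal(classify_contributors(tr)$sse_drivers,
                  names(tr$counts))

  tr$S <- 3L
  expect_warning(classify_contributors(tr), "S < 4")
})

test_that("dynamic reference curve is p80^s", {
  expect_equal(unname(dynamic_reference_curve(1, 5)), rep(1, 6))
  expect_equal(dynamic_reference_curve(0.8, 3)[["1"]], 0.8)
  expect_equal(dynamic_reference_curve(0.5, 3)[["3"]], 0.125)
  expect_error(dynamic_reference_curve(0, 3), "p80")
})

test_that("membership persistence separates static from dynamic dynamics", {
  # with the contacts weighting, top-group membership is a function of the
  # per-node degrees; in a degree-preserving dynamic series with
  # deterministic ties it therefore never changes
  d <- generate_fully_dynamic(N = 120, T_steps = 8, deg_poisson(5), seed = 78)
  expect_true(all(top_group_trajectory(d)$counts %in% c(0L, 8L)))

  # the homogeneous dynamic reference re-draws membership each step
  # (all-equal degrees + random tie-breaking): the fraction identified for
  # at least s steps decays towards p80^S, far below the static p80
  set.seed(77)
  for (rep in 1:3) {
    d <- generate_fully_dynamic(N = 200, T_steps = 8, deg_constant(4))
    tr <- top_group_trajectory(d, random_ties = TRUE)
    pc <- persistence_curve(tr)
    at_least <- 1 - c(0, pc$rho[-nrow(pc)])   # fraction with counts >= s
    expect_true(all(diff(at_least) <= 1e-12))
    p80 <- mean(tr$p80_per_step)              # = ceil(0.8 N)/N each step
    always <- at_least[tr$S + 1]
    expect_lt(always, p80)                    # below the static reference
    expect_lt(abs(always - p80^tr$S), 0.08)   # near-independent membership
  }
})
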