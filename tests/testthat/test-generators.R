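# synthetic temporal network generators

test_that("degree sequences are graphical, capped and even-summed", {
  set.seed(5)
  for (law in list(deg_constant(4), deg_poisson(6), deg_nbinom(5, 0.5))) {
    for (rep in 1:5) {
      d <- sample_degrees(law, 40)
      expect_equal(length(d), 40)
      expect_true(all(d <= 39))
      expect_equal(sum(d) %% 2, 0)
      expect_true(igraph::is_graphical(d))
    }
  }
})

test_that("generators are seed-reproducible and structurally valid", {
  a <- generate_partial_retention(60, 6, q = 0.4, seed = 123)
  b <- generate_partial_retention(60, 6, q = 0.4, seed = 123)
  expect_identical(a$contacts, b$contacts)

  for (s in list(a, generate_static(60, 4, seed = 1),
                 generate_fully_dynamic(60, 4, seed = 2))) {
    expect_false(any(s$contacts$i == s$contacts$j))
    expect_false(anyDuplicated(paste(s$contacts$step, s$contacts$i,
                                     s$contacts$j)) > 0)
  }
})

test_that("static generator repeats one graph; dynamic preserves degrees", {
  s <- generate_static(80, 6, deg_poisson(4), seed = 9)
  first <- s$contacts[s$contacts$step == 1, c("i", "j")]
  for (t in 2:6)
    expect_equal(s$contacts[s$contacts$step == t, c("i", "j")],
                 first, ignore_attr = TRUE)
  tr <- top_group_trajectory(s)
  expect_true(all(tr$counts %in% c(0L, 6L)))

  d <- generate_fully_dynamic(80, 6, deg_poisson(4), seed = 10)
  deg1 <- step_degrees(d, 1)
  for (t in 2:6) expect_equal(step_degrees(d, t), deg1)
})

test_that("partial retention hits its limits and its retained fraction", {
  # q = 1 reduces to the static generator's behaviour
  s1 <- generate_partial_retention(60, 5, q = 1, seed = 11)
  expect_equal(summarize_retention(s1)$median_index, 1)

  # q = 0: no systematic retention beyond chance
  s0 <- generate_partial_retention(300, 12, q = 0, deg_poisson(5), seed = 12)
  expect_lt(abs(summarize_retention(s0)$median_index), 0.08)

  # expected retained edge fraction per step pair = q + (1-q) * chance,
  # with chance estimated from the q = 0 runs (N = 200)
  frac_retained <- function(series) {
    per <- vapply(seq_len(series$n_steps - 1), function(t) {
      e1 <- series$contacts[series$contacts$step == t, ]
      e2 <- series$contacts[series$contacts$step == t + 1, ]
      mean(paste(e1$i, e1$j) %in% paste(e2$i, e2$j))
    }, numeric(1))
    mean(per)
  }
  chance <- mean(vapply(1:3, function(k)
    frac_retained(generate_partial_retention(200, 20, 0, deg_poisson(5),
                                             seed = 40 + k)), numeric(1)))
  for (q in c(0.3, 0.7)) {
    obs <- mean(vapply(1:3, function(k)
      frac_retained(generate_partial_retention(200, 20, q, deg_poisson(5),
                                               seed = 50 + 10 * q + k)),
      numeric(1)))
    expect_lt(abs(obs - (q + (1 - q) * chance)), 0.03)
  }
})

test_that("achieved p80: ties for constant degrees, less under dispersion", {
  # constant degrees: everything ties, group size = ceil(0.8 N)
  expect_equal(achieved_p80(deg_constant(4), N = 100, replicates = 2,
                            seed = 3), ceiling(0.8 * 100) / 100)
  # concentration orders with heterogeneity: constant > Poisson > overdispersed
  p_const <- achieved_p80(deg_constant(5), N = 400, replicates = 3, seed = 3)
  p_pois <- achieved_p80(deg_poisson(5), N = 400, replicates = 3, seed = 4)
  p_od <- achieved_p80(deg_nbinom(5, 0.3), N = 400, replicates = 3, seed = 5)
  expect_lt(p_pois, p_const)
  expect_lt(p_od, p_pois)
  expect_lt(p_od, 0.55)
})

test_that("p80 calibration reaches an attainable target and rejects others", {
  law <- calibrate_p80(mu = 5, p80_target = 0.5, N = 400, replicates = 2,
                       tol = 0.03, seed = 6)
  expect_s3_class(law, "degree_law")
  expect_lt(abs(attr(law, "achieved_p80") - 0.5), 0.031)
  expect_error(calibrate_p80(mu = 5, p80_target = 0.99, N = 200,
                             replicates = 2, seed = 7), "unattainable")
})

test_that("group assignment partitions the population near-evenly", {
  g <- assign_groups(sprintf("n%03d", 1:10), 3, seed = 2)
  expect_setequal(g$node, sprintf("n%03d", 1:10))
  expect_equal(sort(as.integer(table(g$group))), c(3L, 3L, 4L))
})

test_that("multiday generator fills valid episodes with day structure", {
  x <- generate_multiday(N = 25, days = 3, pairs_per_day = 6, rho = 0.5,
                         seed = 8)
  expect_s3_class(x, "contact_records")
  s <- build_snapshots(x, step_length = 86400, duration_threshold = 40)
  led <- unique_contact_ledger(s, 86400)
  expect_equal(led$daily_unique, rep(6L, 3))
  expect_error(generate_multiday(5, 2, pairs_per_day = 20, rho = 0),
               "exceeds")
})
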