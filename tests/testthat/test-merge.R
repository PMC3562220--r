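test_that("group_by_mz applies ppm gap chaining", {
  # 2.5 ppm gap at 5 ppm tolerance -> one group
  g <- group_by_mz(c(200.0000, 200.0005), 5)
  expect_equal(length(g), 1)
  # 15 ppm gap -> two groups
  g2 <- group_by_mz(c(200.0000, 200.0030), 5)
  expect_equal(length(g2), 2)
  expect_equal(group_by_mz(numeric(), 5), list())
  # input order does not matter
  set.seed(6)
  mz <- runif(40, 85, 850)
  perm <- sample(40)
  expect_equal(canon_groups(group_by_mz(mz, 10)),
               canon_groups(lapply(group_by_mz(mz[perm], 10),
                                   function(g) perm[g])))
})

test_that("grouping equals brute-force transitive closure (oracle)", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    # mix of spread-out and clustered masses to exercise chaining
    mz <- c(runif(n, 85, 850),
            300 + cumsum(runif(5, 0, 3e-3)))
    tol <- sample(c(2, 5, 10, 50), 1)
    got <- canon_groups(group_by_mz(mz, tol))
    want <- canon_groups(bf_closure_groups(mz, function(a, b)
      abs(a - b) <= tol * 1e-6 * min(a, b)))
    expect_equal(got, want)
  }
  # RT sub-grouping against the same oracle with absolute tolerance
  for (i in 1:20) {
    rt <- runif(sample(2:40, 1), 0, 300)
    got <- canon_groups(subgroup_by_rt(rt, 10))
    want <- canon_groups(bf_closure_groups(rt, function(a, b)
      abs(a - b) <= 10))
    expect_equal(got, want)
  }
})

test_that("subgroup_by_rt handles the documented cases", {
  expect_equal(length(subgroup_by_rt(c(50, 55), 10)), 1)
  expect_equal(length(subgroup_by_rt(c(50, 300), 10)), 2)
  expect_equal(subgroup_by_rt(7, 10), list(1L))
})

test_that("paired_t matches stats::t.test and handles degenerates", {
  x <- c(10, 20, 30); y <- c(12, 19, 33)
  got <- paired_t(x, y)
  want <- stats::t.test(x, y, paired = TRUE)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$p, want$p.value)
  expect_equal(got$df, unname(want$parameter))

  expect_equal(paired_t(x, x)[c("t", "p")], list(t = 0, p = 1))
  z <- paired_t(c(1, 2, 3), c(2, 3, 4))   # constant nonzero differences
  expect_equal(z$t, -Inf)
  expect_equal(z$p, 0)
  expect_match(z$note, "zero-variance")
  u <- paired_t(c(1, NA), c(2, 3))
  expect_true(is.na(u$t))
  expect_match(u$note, "unavailable")
})

test_that("select_representative prefers minimum median, then intensity", {
  expect_equal(select_representative(c(12, 30.5), c(1, 1), c(1, 2),
                                     c(1, 2)), 1)
  expect_equal(select_representative(30, 5, 1, 1), 1)
  # tie on median -> higher mean intensity
  expect_equal(select_representative(c(10, 10), c(1, 9), c(1, 2),
                                     c(1, 2)), 2)
  # full tie -> lower table index
  expect_equal(select_representative(c(10, 10), c(3, 3), c(2, 1),
                                     c(1, 1)), 2)
  expect_warning(k <- select_representative(c(NA, NA), c(1, 5),
                                            c(1, 2), c(1, 2)),
                 "no evaluable")
  expect_equal(k, 2)
})

make_pair <- function(mz1, rt1, mz2, rt2, sd1 = 0.05, sd2 = 0.3,
                      n_samples = 4, seed = 10) {
  set.seed(seed)
  profiles <- as.vector(vapply(seq_len(n_samples), function(s)
    sprintf("S%d_r%d", s, 1:2), character(2)))
  base1 <- rlnorm(length(mz1), log(1e5), 0.5)
  base2 <- rlnorm(length(mz2), log(1e5), 0.5)
  mk <- function(mz, rt, base, sd, label) {
    intens <- vapply(seq_along(profiles), function(j)
      base * exp(rnorm(length(mz), 0, sd)), numeric(length(mz)))
    intens <- matrix(intens, nrow = length(mz),
                     dimnames = list(NULL, profiles))
    feature_table(mz, rt, intens, profiles, label)
  }
  list(t1 = mk(mz1, rt1, base1, sd1, "P1"),
       t2 = mk(mz2, rt2, base2, sd2, "P2"),
       design = replicate_design(profiles,
                                 rep(sprintf("S%d", seq_len(n_samples)),
                                     each = 2)))
}

test_that("self-merge is idempotent on feature count", {
  set.seed(8)
  ft <- random_table(30, n_samples = 4)
  d <- tiny_design(ft)
  res <- merge_results(list(ft, ft), d)
  expect_equal(n_features(res$table), n_features(ft))
  expect_equal(res$report$n_redundant_collapsed, n_features(ft))
})

test_that("disjoint tables are additive; shared pair keeps lower-PID member", {
  px <- make_pair(mz1 = c(200.0000, 400.0), rt1 = c(50, 100),
                  mz2 = c(300.0, 500.0), rt2 = c(60, 200))
  res <- merge_results(list(px$t1, px$t2), px$design)
  expect_equal(n_features(res$table), 4)
  expect_equal(res$report$n_unique_passthrough, 4)

  # one shared coordinate within 5 ppm / 10 s: member with lower noise wins
  py <- make_pair(mz1 = 200.0000, rt1 = 50, mz2 = 200.0005, rt2 = 52,
                  sd1 = 0.03, sd2 = 0.4)
  q1 <- evaluate_features(py$t1, py$design)
  q2 <- evaluate_features(py$t2, py$design)
  expect_lt(q1$median, q2$median)
  res2 <- merge_results(list(py$t1, py$t2), py$design)
  expect_equal(n_features(res2$table), 1)
  expect_equal(res2$table$mz, 200.0000)        # the P1 member, verbatim
  expect_equal(res2$report$collapses$representative_table, 1)
})

test_that("merge is invariant to row order within tables", {
  set.seed(9)
  px <- make_pair(mz1 = runif(15, 100, 700), rt1 = runif(15, 0, 500),
                  mz2 = runif(15, 100, 700), rt2 = runif(15, 0, 500))
  res <- merge_results(list(px$t1, px$t2), px$design)
  perm <- sample(15)
  t1p <- subset_features(px$t1, perm)
  res_p <- merge_results(list(t1p, px$t2), px$design)
  expect_equal(res_p$table$mz, res$table$mz)
  expect_equal(res_p$table$intensities, res$table$intensities)
})

test_that("t-test split keeps significantly different pairs distinct", {
  # same coordinates, systematically different intensities
  profiles <- sprintf("S%d_r%d", rep(1:4, each = 2), 1:2)
  set.seed(12)
  base <- rlnorm(8, log(1e5), 0.1)
  m1 <- matrix(base * exp(rnorm(8, 0, 0.01)), 1,
               dimnames = list(NULL, profiles))
  m2 <- m1 * 3   # large paired shift
  d <- replicate_design(profiles, rep(sprintf("S%d", 1:4), each = 2))
  t1 <- feature_table(250.0, 100, m1, profiles, "P1")
  t2 <- feature_table(250.0002, 101, m2, profiles, "P2")
  res <- merge_results(list(t1, t2), d, merge_config(t_test_alpha = 0.05))
  expect_equal(n_features(res$table), 2)
  expect_equal(res$report$n_t_split, 1)
  # default config still collapses and reports the test
  res2 <- merge_results(list(t1, t2), d)
  expect_equal(n_features(res2$table), 1)
  expect_lt(res2$report$collapses$p, 0.05)
})

test_that("merge validates inputs and folds more than two tables", {
  ft <- tiny_table(5)
  other <- random_table(5, n_samples = 3)
  expect_error(merge_results(list(ft, other), tiny_design(ft)),
               "different profile columns")
  # three disjoint tables fold to the sum of counts
  pz <- make_pair(mz1 = c(100, 200), rt1 = c(10, 20),
                  mz2 = c(300, 400), rt2 = c(30, 40))
  t3 <- feature_table(c(500, 600), c(50, 60),
                      pz$t1$intensities, pz$t1$profile_ids, "P3")
  expect_warning(res <- merge_results(list(pz$t1, pz$t2, t3), pz$design),
                 "folding pairwise")
  expect_equal(n_features(res$table), 6)
})

test_that("merge report satisfies its accounting invariant", {
  set.seed(13)
  for (i in 1:10) {
    px <- make_pair(mz1 = runif(12, 100, 500), rt1 = runif(12, 0, 300),
                    mz2 = runif(12, 100, 500), rt2 = runif(12, 0, 300),
                    seed = i)
    r <- merge_results(list(px$t1, px$t2), px$design)$report
    expect_equal(r$n_output,
                 r$n_unique_passthrough + r$n_redundant_collapsed +
                   2 * r$n_t_split)
    expect_lte(r$n_output, r$n_pooled)
  }
})
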