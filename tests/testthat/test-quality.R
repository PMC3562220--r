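test_that("pid matches its definition and properties", {
  expect_equal(pid(100, 300), 100)   # |d| = 200, mean = 200
  expect_equal(pid(5, 5), 0)
  expect_equal(pid(0, 7), 200)       # metric maximum
  expect_true(is.na(pid(0, 0)))      # undefined
  expect_error(pid(-1, 2), "nonnegative")
  # symmetry, scale invariance, bounds on random pairs
  set.seed(1)
  a <- runif(200, 0, 1e6); b <- runif(200, 0, 1e6); k <- runif(200, 0.1, 9)
  expect_equal(pid(a, b), pid(b, a))
  expect_equal(pid(k * a, k * b), pid(a, b))
  expect_true(all(pid(a, b) >= 0 & pid(a, b) <= 200))
})

test_that("cv matches its definition", {
  expect_equal(cv(c(2, 4, 6)), 50)   # sample sd 2, mean 4
  expect_equal(cv(c(3, 3, 3)), 0)
  expect_error(cv(7), "at least 2")
  expect_true(is.na(cv(c(0, 0))))
  set.seed(2)
  x <- rlnorm(50); k <- 3.7
  expect_equal(cv(k * x), cv(x))                 # scale-invariant
  expect_false(isTRUE(all.equal(cv(x + 10), cv(x))))  # translation-sensitive
})

test_that("evaluate_features computes PID per sample for duplicates", {
  # identical replicates within every sample -> all medians 0
  profiles <- c("S1_r1", "S1_r2", "S2_r1", "S2_r2")
  d <- replicate_design(profiles, c("S1", "S1", "S2", "S2"))
  m <- matrix(c(10, 10, 40, 40,
                7, 7, 9, 9), 2, byrow = TRUE,
              dimnames = list(NULL, profiles))
  ft <- table_from_matrix(m)
  q <- evaluate_features(ft, d)
  expect_equal(attr(q, "metric_kind"), "PID")
  expect_equal(q$median, c(0, 0))

  # one evaluable sample pair (100, 300), other sample missing
  m2 <- matrix(c(100, 300, NA, 5), 1,
               dimnames = list(NULL, profiles))
  q2 <- evaluate_features(table_from_matrix(m2), d)
  expect_equal(q2$median, 100)
  expect_equal(q2$n_samples_used, 1)

  # feature with no evaluable sample -> NA summary
  m3 <- matrix(c(NA, 300, NA, 5), 1,
               dimnames = list(NULL, profiles))
  q3 <- evaluate_features(table_from_matrix(m3), d)
  expect_true(is.na(q3$median))
})

test_that("evaluate_features switches to CV for triplicates", {
  profiles <- sprintf("S1_r%d", 1:3)
  d <- replicate_design(profiles, rep("S1", 3))
  ft <- table_from_matrix(matrix(c(2, 4, 6), 1,
                                 dimnames = list(NULL, profiles)))
  q <- evaluate_features(ft, d)
  expect_equal(attr(q, "metric_kind"), "CV")
  expect_equal(q$median, 50)
})

test_that("evaluate_features rejects non-uniform replicate counts", {
  profiles <- c("S1_r1", "S1_r2", "S2_r1", "S2_r2", "S2_r3")
  d <- replicate_design(profiles, c("S1", "S1", "S2", "S2", "S2"))
  ft <- table_from_matrix(matrix(1:5, 1,
                                 dimnames = list(NULL, profiles)))
  expect_error(evaluate_features(ft, d), "S1=2.*S2=3")
})

test_that("six-number summary is ordered and uses type-7 quartiles", {
  set.seed(3)
  ft <- random_table(30, n_samples = 6)
  d <- tiny_design(ft)
  q <- evaluate_features(ft, d)
  ok <- !is.na(q$median)
  expect_true(all(q$min[ok] <= q$q1[ok] & q$q1[ok] <= q$median[ok] &
                    q$median[ok] <= q$q3[ok] & q$q3[ok] <= q$max[ok]))
  per <- attr(q, "per_sample")
  i <- which(ok)[1]
  expect_equal(q$q1[i], unname(quantile(per[i, ], 0.25, na.rm = TRUE)))
})

test_that("evaluate_samples reproduces textbook Pearson means", {
  profiles <- c("S1_r1", "S1_r2")
  d <- replicate_design(profiles, c("S1", "S1"))
  # byte-identical replicates
  m <- matrix(rep(c(5, 9, 2), 2), 3,
              dimnames = list(NULL, profiles))
  expect_equal(
    evaluate_samples(table_from_matrix(m), d)$mean_pairwise_correlation, 1)
  # scaled replicate: Pearson scale-invariant
  m2 <- cbind(c(5, 9, 2), c(10, 18, 4))
  colnames(m2) <- profiles
  expect_equal(
    evaluate_samples(table_from_matrix(m2), d)$mean_pairwise_correlation, 1)
  # reversed ranks -> -1
  m3 <- cbind(c(1, 2, 3), c(3, 2, 1))
  colnames(m3) <- profiles
  expect_equal(
    evaluate_samples(table_from_matrix(m3), d)$mean_pairwise_correlation, -1)
})

test_that("evaluate_samples equals mean of cor() over pairs (oracle)", {
  set.seed(4)
  for (rep_i in 1:5) {
    ft <- random_table(40, n_samples = 3, reps = 3)
    d <- tiny_design(ft)
    q <- evaluate_samples(ft, d)
    for (s in unique(d$sample_id)) {
      cols <- which(d$sample_id == s)
      cm <- cor(ft$intensities[, cols])
      expect_equal(q$mean_pairwise_correlation[q$sample_id == s],
                   mean(cm[upper.tri(cm)]))
    }
  }
})

test_that("evaluate_samples handles degenerate inputs", {
  profiles <- c("S1_r1", "S1_r2")
  d <- replicate_design(profiles, c("S1", "S1"))
  # fewer than 3 complete features -> unavailable with reason
  m <- matrix(c(1, 2, NA, 4, 5, 6), 3, 2,
              dimnames = list(NULL, profiles))
  q <- evaluate_samples(table_from_matrix(m), d)
  expect_true(is.na(q$mean_pairwise_correlation))
  expect_match(attr(q, "reason"), "complete")
  # zero-variance replicate vector: pair excluded and counted
  m2 <- matrix(c(7, 7, 7, 1, 2, 3), 3, 2,
               dimnames = list(NULL, profiles))
  q2 <- evaluate_samples(table_from_matrix(m2), d)
  expect_equal(q2$n_pairs_undefined, 1)
  expect_true(is.na(q2$mean_pairwise_correlation))
})

test_that("filter_samples drops only samples below threshold", {
  set.seed(5)
  profiles <- c("G_r1", "G_r2", "B_r1", "B_r2")
  d <- replicate_design(profiles, c("G", "G", "B", "B"))
  good <- rlnorm(20, log(1e5), 0.5)
  bad1 <- rlnorm(20, log(1e5), 0.5)
  m <- cbind(good, good * exp(rnorm(20, 0, 0.01)),
             bad1, sample(bad1))   # shuffled partner: low correlation
  colnames(m) <- profiles
  ft <- table_from_matrix(m)
  q <- evaluate_samples(ft, d)
  expect_true(q$mean_pairwise_correlation[q$sample_id == "G"] > 0.95)
  res <- suppressMessages(filter_samples(ft, d, q, 0.7))
  expect_equal(res$dropped, "B")
  expect_equal(res$table$profile_ids, c("G_r1", "G_r2"))
  # disabled filter is the identity
  res2 <- filter_samples(ft, d, q, NA)
  expect_identical(res2$table, ft)
  # all samples at r = 1 -> unchanged
  m3 <- cbind(good, good, bad1, bad1); colnames(m3) <- profiles
  ft3 <- table_from_matrix(m3)
  res3 <- filter_samples(ft3, d, evaluate_samples(ft3, d), 0.7)
  expect_identical(res3$table, ft3)
})

test_that("filter_features uses a strict median threshold", {
  profiles <- c("S1_r1", "S1_r2")
  d <- replicate_design(profiles, c("S1", "S1"))
  # duplicate pairs whose PIDs approximate 0, 29.9, 30, 45
  pair_for_pid <- function(p) c(100, 100 * (200 + p) / (200 - p))
  m <- t(vapply(c(0, 29.9, 30, 45), pair_for_pid, numeric(2)))
  colnames(m) <- profiles
  ft <- table_from_matrix(m)
  q <- evaluate_features(ft, d)
  expect_equal(q$median, c(0, 29.9, 30, 45), tolerance = 1e-12)
  # strict-inequality semantics checked on exact medians (the engineered
  # PID of 30 lands one ulp off the boundary)
  q$median <- c(0, 29.9, 30, 45)
  expect_equal(n_features(filter_features(ft, q, 30)), 2)
  # disabled and above-max thresholds are identities
  expect_equal(n_features(filter_features(ft, q, NA)), 4)
  expect_equal(n_features(filter_features(ft, q, 200 + 1e-9)), 4)
  expect_warning(out <- filter_features(ft, q, 0), "no feature")
  expect_equal(n_features(out), 0)
})
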