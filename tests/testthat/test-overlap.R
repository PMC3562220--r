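frame <- function(mz, time = rep(0, length(mz))) data.frame(mz, time)

test_that("find_overlapping_mzs matches the documented cases", {
  cfg <- match_config(5, 10)
  r <- find_overlapping_mzs(frame(100.0000, 50), frame(100.0004, 55), cfg)
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$ppm_error, 4, tolerance = 1e-3)
  expect_equal(r$pairs$rt_diff, 5)

  # time threshold disabled: distant RTs still match on m/z alone
  r2 <- find_overlapping_mzs(frame(100.0, 50), frame(100.0, 500),
                             match_config(5, NA))
  expect_equal(nrow(r2$pairs), 1)
  # ... and enabled: they do not
  r3 <- find_overlapping_mzs(frame(100.0, 50), frame(100.0, 500), cfg)
  expect_equal(nrow(r3$pairs), 0)
  expect_equal(r3$unique1, 1L)

  # disjoint ranges
  r4 <- find_overlapping_mzs(frame(c(100, 110)), frame(c(200, 210)),
                             match_config(5, NA))
  expect_equal(nrow(r4$pairs), 0)
  expect_equal(r4$unique1, 1:2)
  expect_equal(r4$unique2, 1:2)
})

test_that("matching equals brute force and is symmetric (oracle)", {
  set.seed(14)
  for (i in 1:40) {
    n1 <- sample(0:50, 1); n2 <- sample(1:50, 1)
    l1 <- frame(runif(n1, 100, 200), runif(n1, 0, 100))
    # append near-collided copies of some L1 masses to force matches
    n_j <- min(n1, 10)
    mz2 <- c(runif(n2, 100, 200),
             if (n_j) l1$mz[seq_len(n_j)] * (1 + runif(n_j, -8e-6, 8e-6)))
    l2 <- frame(mz2, runif(length(mz2), 0, 100))
    ppm <- sample(c(3, 5, 10), 1)
    tt <- sample(c(NA, 20, 50), 1)
    got <- find_overlapping_mzs(l1, l2, match_config(ppm, tt))
    want <- bf_match_pairs(l1, l2, ppm, tt)
    expect_equal(pair_matrix(got$pairs[, c("index1", "index2")]),
                 pair_matrix(want))
    # symmetry: swapped lists give the transposed pair set
    got_sw <- find_overlapping_mzs(l2, l1, match_config(ppm, tt))
    expect_equal(pair_matrix(got_sw$pairs[, c("index2", "index1")]),
                 pair_matrix(want))
    # matched and unique partition each list
    expect_equal(sort(c(unique(got$pairs$index1), got$unique1)),
                 seq_len(nrow(l1)))
    expect_equal(sort(c(unique(got$pairs$index2), got$unique2)),
                 seq_len(nrow(l2)))
  }
})

test_that("find_unique_mzs is the complement of the match", {
  cfg <- match_config(5, NA)
  l <- frame(c(100, 200, 300))
  u <- find_unique_mzs(l, frame(numeric(0)), cfg)
  expect_equal(u$unique1$index, 1:3)
  u2 <- find_unique_mzs(l, l, cfg)
  expect_equal(nrow(u2$unique1), 0)
  expect_equal(nrow(u2$unique2), 0)
  # one shared of three each
  u3 <- find_unique_mzs(frame(c(100, 200, 300)),
                        frame(c(100, 400, 500)), cfg)
  expect_equal(u3$unique1$mz, c(200, 300))
  expect_equal(u3$unique2$mz, c(400, 500))
})

test_that("venn_counts covers two- and three-set cases", {
  cfg <- match_config(5, NA)
  A <- frame(c(100, 200, 300))
  vc <- venn_counts(list(A = A, B = A), cfg)
  expect_equal(unname(vc$counts[c("A", "B", "A&B")]), c(0, 0, 3))

  vc2 <- venn_counts(list(A = A, B = frame(c(400, 500))), cfg)
  expect_equal(unname(vc2$counts[c("A", "B", "A&B")]), c(3, 2, 0))

  # three lists sharing exactly one feature
  B <- frame(c(100, 600)); C <- frame(c(100, 700, 800))
  vc3 <- venn_counts(list(A = A, B = B, C = C), cfg)
  expect_equal(unname(vc3$counts["A&B&C"]), 1)
  expect_equal(unname(vc3$counts["A"]), 2)
  # each dataset's regions sum to its size
  expect_equal(unname(rowSums(vc3$per_dataset)), unname(vc3$sizes))

  expect_error(venn_counts(list(A, A, A, A), cfg), "unsupported")
})

test_that("venn region sums hold on random instances (property)", {
  set.seed(15)
  cfg <- match_config(10, NA)
  for (i in 1:10) {
    ds <- lapply(1:3, function(k) frame(runif(sample(5:30, 1), 100, 300)))
    names(ds) <- c("A", "B", "C")
    vc <- venn_counts(ds, cfg)
    expect_equal(unname(rowSums(vc$per_dataset)), unname(vc$sizes))
  }
})

test_that("check_mz_in_replicates applies min_samps and min_reps", {
  n_samp <- 10
  profiles <- sprintf("S%02d_r%d", rep(1:n_samp, each = 2), 1:2)
  d <- replicate_design(profiles, rep(sprintf("S%02d", 1:n_samp), each = 2))
  m <- matrix(NA_real_, 1, 20, dimnames = list(NULL, profiles))
  m[1, 1:2] <- c(1e5, 2e5)   # present in both replicates of sample 1 only
  ft <- feature_table(150.0, 60, m, profiles)
  got <- check_mz_in_replicates(ft, d, rare_feature_config(1, 100))
  expect_equal(attr(got, "indices"), 1L)
  got2 <- check_mz_in_replicates(ft, d, rare_feature_config(2, 100))
  expect_equal(length(attr(got2, "indices")), 0)

  # 1 of 3 replicates in 5 samples, min_reps 66 -> need ceil(1.98) = 2
  profiles3 <- sprintf("S%d_r%d", rep(1:5, each = 3), 1:3)
  d3 <- replicate_design(profiles3, rep(sprintf("S%d", 1:5), each = 3))
  m3 <- matrix(NA_real_, 1, 15, dimnames = list(NULL, profiles3))
  m3[1, seq(1, 15, by = 3)] <- 1e5
  ft3 <- feature_table(150.0, 60, m3, profiles3)
  got3 <- check_mz_in_replicates(ft3, d3, rare_feature_config(5, 66))
  expect_equal(length(attr(got3, "indices")), 0)
  got4 <- check_mz_in_replicates(ft3, d3, rare_feature_config(5, 33))
  expect_equal(attr(got4, "indices"), 1L)
})
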