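# Shared fixtures and independent brute-force oracles.

# A tiny deterministic table: n features, one duplicate pair per sample.
tiny_table <- function(n = 4, n_samples = 2, seed = 42, label = "tiny") {
  set.seed(seed)
  profiles <- as.vector(vapply(seq_len(n_samples), function(s)
    sprintf("S%d_r%d", s, 1:2), character(2)))
  intens <- matrix(rlnorm(n * length(profiles), log(1e5), 0.3),
                   nrow = n, dimnames = list(NULL, profiles))
  feature_table(mz = sort(runif(n, 100, 800)),
                rt = runif(n, 60, 500),
                intensities = intens, profile_ids = profiles,
                setting_label = label)
}

tiny_design <- function(ft) {
  replicate_design(ft$profile_ids,
                   sub("_r[0-9]+$", "", ft$profile_ids))
}

# Random feature table for property tests (no NA unless asked).
random_table <- function(n, n_samples = 2, reps = 2, missing_prob = 0,
                         label = "rnd") {
  profiles <- as.vector(vapply(seq_len(n_samples), function(s)
    sprintf("S%d_r%d", s, seq_len(reps)), character(reps)))
  intens <- matrix(rlnorm(n * length(profiles), log(1e5), 0.5),
                   nrow = n, dimnames = list(NULL, profiles))
  if (missing_prob > 0)
    intens[runif(length(intens)) < missing_prob] <- NA
  feature_table(mz = runif(n, 85, 850), rt = runif(n, 0, 600),
                intensities = intens, profile_ids = profiles,
                setting_label = label)
}

# Oracle: transitive closure of the pairwise "within tolerance" relation,
# by repeated sweep over an explicit adjacency matrix (no sorting).
bf_closure_groups <- function(x, within_pair) {
  n <- length(x)
  if (!n) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- within_pair(x[i], x[j])
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[max(i, j)]] <- comp[min(i, j)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(seq_len(n), comp))
}

# Canonical form of a grouping for set comparison.
canon_groups <- function(groups) {
  g <- lapply(groups, sort)
  g[order(vapply(g, min, 0))]
}

# Canonical integer matrix form for comparing pair sets (handles the
# empty case, where as.matrix() on a data.frame degrades to logical).
pair_matrix <- function(x) {
  m <- matrix(as.integer(as.matrix(x)), ncol = 2)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Oracle: exhaustive pairwise match search.
bf_match_pairs <- function(l1, l2, ppm, time_thresh = NA) {
  out <- list()
  for (i in seq_len(nrow(l1))) for (j in seq_len(nrow(l2))) {
    dppm <- abs(l1$mz[i] - l2$mz[j]) / min(l1$mz[i], l2$mz[j]) * 1e6
    drt <- abs(l1$time[i] - l2$time[j])
    if (dppm <= ppm && (is.na(time_thresh) || drt <= time_thresh))
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(matrix(integer(), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Oracle: exhaustive annotation window search.
bf_annotate <- function(mz, db, adducts, ppm) {
  out <- list()
  for (q in mz) for (a in adducts) for (k in seq_len(nrow(db))) {
    theo <- adduct_mz(db$monoisotopic_mass[k], a)
    if (abs(q - theo) / q * 1e6 <= ppm)
      out[[length(out) + 1L]] <- data.frame(query_mz = q, adduct = a,
                                            id = db$id[k])
  }
  if (!length(out))
    return(data.frame(query_mz = numeric(), adduct = character(),
                      id = character()))
  d <- do.call(rbind, out)
  d[order(d$query_mz, d$adduct, d$id), , drop = FALSE]
}

demo_db <- function() {
  read_compound_db(system.file("extdata", "demo_compound_db.tsv",
                               package = "mzmerge"))
}

# Build a feature table directly from an intensity matrix.
table_from_matrix <- function(intens, mz = NULL, rt = NULL,
                              label = "mat") {
  n <- nrow(intens)
  if (is.null(mz)) mz <- seq(100, by = 10, length.out = n)
  if (is.null(rt)) rt <- seq(50, by = 30, length.out = n)
  feature_table(mz, rt, intens, colnames(intens), label)
}
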