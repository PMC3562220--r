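#' Configuration for the synthetic two-setting extraction generator
#'
#' The generator emulates the situation the merge-and-select workflow is
#' built for: one ground-truth set of compounds extracted under two
#' parameter settings. Shared compounds appear in both tables with slightly
#' jittered coordinates and correlated intensities but different replicate
#' reproducibility per setting; setting-unique compounds appear in one
#' table only, with m/z separations far above the merge tolerance so
#' ground-truth identity is unambiguous.
#'
#' Replicate noise is multiplicative log-normal (LC/MS intensities are
#' heavy-tailed and replicate error scales with intensity). For each shared
#' compound one member is drawn from the low-noise band and one from the
#' high-noise band (assigned to a random setting), so "which member is more
#' reproducible" is a well-defined ground truth; the default bands
#' (log-sd 0.05-0.15 vs 0.25-0.35) put per-sample PIDs in the 0-60% range
#' typical of real duplicate injections.
#'
#' @param n_shared compounds present in both settings (default 30).
#' @param n_unique_per_setting compounds present in only one setting each
#'   (default 10).
#' @param n_samples biological samples (default 10).
#' @param replicates_per_sample analytical replicates per sample, 2 or 3.
#' @param mz_range,rt_range coordinate ranges (m/z dimensionless, RT in
#'   seconds).
#' @param noise_sd_low,noise_sd_high log-scale replicate-noise bands
#'   (length-2 ranges) for the low- and high-noise member of each shared
#'   compound. Set them equal to generate a single homogeneous noise level.
#' @param jitter_ppm_sd m/z jitter between settings, ppm standard
#'   deviation; must stay well inside `mz_tolerance_ppm`.
#' @param jitter_rt_sd RT jitter between settings in seconds.
#' @param missing_prob independent per-cell missingness probability.
#' @param mz_tolerance_ppm,rt_tolerance_s the merge tolerances the fixture
#'   is built for: ground-truth m/z separations exceed
#'   `3 * mz_tolerance_ppm`.
#' @param seed integer random seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_shared = 30, n_unique_per_setting = 10,
                         n_samples = 10, replicates_per_sample = 2,
                         mz_range = c(85, 850), rt_range = c(60, 600),
                         noise_sd_low = c(0.05, 0.15),
                         noise_sd_high = c(0.25, 0.35),
                         jitter_ppm_sd = 1, jitter_rt_sd = 2,
                         missing_prob = 0.05,
                         mz_tolerance_ppm = 5, rt_tolerance_s = 10,
                         seed = 1) {
  stopifnot(n_shared >= 0, n_unique_per_setting >= 0,
            n_shared + n_unique_per_setting > 0,
            n_samples >= 1, replicates_per_sample %in% 2:3,
            missing_prob >= 0, missing_prob < 1,
            mz_tolerance_ppm > 0, rt_tolerance_s > 0)
  if (jitter_ppm_sd > mz_tolerance_ppm / 3)
    stop("generation error: jitter_ppm_sd (", jitter_ppm_sd,
         ") must be well below the merge tolerance (",
         mz_tolerance_ppm, " ppm); keep it <= tolerance/3")
  if (jitter_rt_sd > rt_tolerance_s / 3)
    stop("generation error: jitter_rt_sd (", jitter_rt_sd,
         ") must be well below rt_tolerance_s (", rt_tolerance_s, ")")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic two-setting extraction with ground truth
#'
#' Produces two feature tables sharing profile columns, the replicate
#' design, and a ground-truth table mapping every feature row to its
#' compound — including which member of each shared compound carries the
#' lower true replicate noise (the member the merge should select).
#'
#' Intensity model: compound base abundance log-normal
#' (`meanlog = log(1e5)`, `sdlog = 1.2`); a per-(compound, sample)
#' biological effect (`sdlog = 0.5`) shared by both settings, so shared
#' features are correlated across settings; independent per-cell replicate
#' noise at the member's log-sd; independent missingness.
#'
#' @param config a [synth_config()].
#' @return List with `table1`, `table2` ([feature_table()]s), `design`
#'   ([replicate_design()]) and `truth` (data.frame: `compound`,
#'   `membership` in both/setting1/setting2, `true_mz`, `true_rt`,
#'   `row1`, `row2` (NA when absent), `noise_sd1`, `noise_sd2`,
#'   `lower_noise_setting`).
#' @export
generate_extraction_pair <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_u <- config$n_unique_per_setting
  n_total <- config$n_shared + 2 * n_u
  membership <- rep(c("both", "setting1", "setting2"),
                    c(config$n_shared, n_u, n_u))

  # ground-truth m/z: rejection-sample until separations > 3x tolerance
  min_gap <- 3 * config$mz_tolerance_ppm * 1e-6 * config$mz_range[2]
  mz_true <- NULL
  for (try in 1:200) {
    cand <- sort(stats::runif(n_total, config$mz_range[1],
                              config$mz_range[2]))
    if (n_total < 2 || min(diff(cand)) > min_gap) {
      mz_true <- sample(cand)  # decouple compound id from mass order
      break
    }
  }
  if (is.null(mz_true))
    stop("generation error: could not place ", n_total,
         " compounds with m/z separations > 3x tolerance in range [",
         config$mz_range[1], ", ", config$mz_range[2], "]")
  rt_true <- stats::runif(n_total, config$rt_range[1], config$rt_range[2])

  r <- config$replicates_per_sample
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  profile_ids <- as.vector(t(outer(sample_ids, seq_len(r),
                                   function(s, k) sprintf("%s_r%d", s, k))))
  design <- replicate_design(profile_ids,
                             rep(sample_ids, each = r))

  base <- stats::rlnorm(n_total, meanlog = log(1e5), sdlog = 1.2)
  bio <- matrix(stats::rlnorm(n_total * config$n_samples, 0, 0.5),
                n_total, config$n_samples)

  # per-member replicate noise: shared compounds get one low- and one
  # high-noise member in random setting order
  sd1 <- sd2 <- rep(NA_real_, n_total)
  for (c_i in seq_len(n_total)) {
    if (membership[c_i] == "both") {
      lo <- stats::runif(1, config$noise_sd_low[1], config$noise_sd_low[2])
      hi <- stats::runif(1, config$noise_sd_high[1],
                         config$noise_sd_high[2])
      if (stats::runif(1) < 0.5) {
        sd1[c_i] <- lo; sd2[c_i] <- hi
      } else {
        sd1[c_i] <- hi; sd2[c_i] <- lo
      }
    } else {
      s <- stats::runif(1, config$noise_sd_low[1],
                        config$noise_sd_high[2])
      if (membership[c_i] == "setting1") sd1[c_i] <- s else sd2[c_i] <- s
    }
  }

  make_table <- function(setting) {
    in_table <- membership %in% c("both", paste0("setting", setting))
    comp <- which(in_table)
    sds <- if (setting == 1) sd1 else sd2
    n_f <- length(comp)
    intens <- matrix(NA_real_, n_f, length(profile_ids))
    for (fi in seq_len(n_f)) {
      c_i <- comp[fi]
      mu <- base[c_i] * bio[c_i, rep(seq_len(config$n_samples), each = r)]
      vals <- mu * exp(stats::rnorm(length(profile_ids), 0, sds[c_i]))
      vals[stats::runif(length(vals)) < config$missing_prob] <- NA
      intens[fi, ] <- vals
    }
    # jitter truncated so two jittered copies of the same compound always
    # stay within the merge tolerance of each other (< tol/2 each side):
    # ground-truth identity is exact by construction
    mz_jit <- trunc_norm(n_f, config$jitter_ppm_sd,
                         0.45 * config$mz_tolerance_ppm)
    rt_jit <- trunc_norm(n_f, config$jitter_rt_sd,
                         0.45 * config$rt_tolerance_s)
    mz_obs <- mz_true[comp] * (1 + mz_jit * 1e-6)
    rt_obs <- pmax(0, rt_true[comp] + rt_jit)
    ord <- order(mz_obs)
    list(table = feature_table(mz_obs[ord], rt_obs[ord],
                               intens[ord, , drop = FALSE], profile_ids,
                               paste0("synthetic-setting", setting)),
         rows = stats::setNames(seq_along(ord), comp[ord]))
  }
  t1 <- make_table(1)
  t2 <- make_table(2)

  row_of <- function(rows, c_i) {
    k <- match(as.character(c_i), names(rows))
    if (is.na(k)) NA_integer_ else unname(rows[k])
  }
  truth <- data.frame(
    compound = sprintf("C%03d", seq_len(n_total)),
    membership = membership,
    true_mz = mz_true, true_rt = rt_true,
    row1 = vapply(seq_len(n_total), function(i) row_of(t1$rows, i), 0L),
    row2 = vapply(seq_len(n_total), function(i) row_of(t2$rows, i), 0L),
    noise_sd1 = sd1, noise_sd2 = sd2,
    lower_noise_setting = ifelse(
      membership == "both", ifelse(sd1 < sd2, 1L, 2L),
      ifelse(membership == "setting1", 1L, 2L)),
    stringsAsFactors = FALSE)

  list(table1 = t1$table, table2 = t2$table, design = design,
       truth = truth, config = config)
}

# Normal draws clipped to [-bound, bound]; with the default sd the bound
# sits beyond 2 sd so the clipping is rare.
trunc_norm <- function(n, sd, bound) {
  pmin(pmax(stats::rnorm(n, 0, sd), -bound), bound)
}

#' Write a generated fixture to disk
#'
#' Standard feature-table files for both settings, the replicate design and
#' the ground-truth TSV.
#'
#' @param fixture result of [generate_extraction_pair()].
#' @param dir output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_synthetic_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table1 = file.path(dir, "setting1_features.tsv"),
    table2 = file.path(dir, "setting2_features.tsv"),
    design = file.path(dir, "replicate_design.tsv"),
    truth = file.path(dir, "ground_truth.tsv"))
  write_feature_table(fixture$table1, paths["table1"])
  write_feature_table(fixture$table2, paths["table2"])
  write_replicate_design(fixture$design, paths["design"])
  utils::write.table(fixture$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
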