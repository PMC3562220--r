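---
title: "Merging and quality-scoring LC/MS feature tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging and quality-scoring LC/MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzmerge)
```

## The problem

Peak-detection software for untargeted LC/MS metabolomics (apLCMS, XCMS and
relatives) exposes stringency parameters — how many scans must support a
peak, in what fraction of scans a signal must be present — and any single
choice trades sensitivity against reliability. Strict settings miss low
abundance metabolites; lenient settings admit noise. `mzmerge` operates
*after* extraction: the same raw data are extracted at two (or more)
parameter settings, and the resulting feature tables are merged into one
optimized table that unites the settings' unique features and keeps, for
every feature found by both, the copy that quantifies more reproducibly
across analytical replicates.

Everything downstream of the extractor is covered: replicate-based quality
metrics and filters, the merge itself, cross-dataset feature matching and
Venn summaries, a scoring function for choosing the best setting pair, and
offline adduct-based annotation of m/z values against a local compound
database.

## Reproducibility metrics

Two analytical replicates of biological sample $s$ give, for each feature,
the **percent intensity difference**

$$\mathrm{PID} = 100\,\frac{|I_1 - I_2|}{(I_1 + I_2)/2} \in [0, 200],$$

and designs with $r \ge 3$ replicates use the **coefficient of variation**
$\mathrm{CV} = 100\,\hat\sigma/\bar I$ (sample standard deviation). Both are
computed within each biological sample, skipping samples with any missing
replicate value, and condensed per feature to the six-number summary (min,
Q1, median, mean, Q3, max; type-7 linearly interpolated quartiles, the
`summary()` convention, fixed so results are reproducible). The median is
the working statistic: feature filtering keeps features with median metric
strictly below a threshold (30% by default, matching the usual
"median PID < 30%" reporting convention), and merging selects
representatives by minimum median metric.

Sample-level quality is the mean pairwise Pearson correlation of replicate
intensity vectors over *complete* features (no missing value in any profile
of the table); at least three complete features are required, and
zero-variance replicate vectors make a pair's correlation undefined — the
pair is excluded from the mean and counted in a diagnostics column rather
than poisoning the result. Correlation is computed on raw intensities by
default; a `log2_intensities` switch exists because heavy-tailed intensity
distributions can make raw-scale correlations optimistic, but no transform
is ever applied silently. The conventional quality cut drops samples with
mean $r < 0.7$. (The threshold is often quoted against "$R^2$" in the
field; it is applied here to $r$ itself and is fully configurable.)

## The merge

Four steps, given tables $P_1$ and $P_2$ sharing profile columns:

1. **Pool** all features of both tables into one list.
2. **Group by m/z**: sort the pooled m/z values and start a new group
   whenever the gap to the previous value exceeds the tolerance (5 ppm
   default), with the ppm gap referenced to the lower of the two adjacent
   values. This sorted single-linkage chaining is exactly the transitive
   closure of the pairwise "within tolerance" relation — deterministic,
   order-independent, $O(n \log n)$ — with the documented caveat that a
   chain of close features can span more than the tolerance end to end.
3. **Sub-group by retention time** inside each m/z group with the same
   chaining rule and an absolute tolerance in seconds (10 s default; pick
   it for your chromatography, e.g. by matching replicate extractions with
   `find_overlapping_mzs()`).
4. **Resolve redundancy**: singleton sub-groups pass through unchanged.
   For multi-member sub-groups the member with the minimum median PID/CV
   (computed per input table, before merging) becomes the representative,
   its coordinates and intensities copied verbatim. Ties go to higher mean
   intensity, then lower table index, then lower row index. For two-member
   sub-groups a paired t-test over the profiles observed in both members is
   reported (two-sided, $n-1$ df, no multiple-testing correction — the
   statistic is informational by design). With the default configuration
   the test never blocks a collapse; setting `t_test_alpha` makes pairs
   with $p < \alpha$ count as genuinely different features, keeping both.
   Degenerate tests get sentinels, not errors: all-zero differences give
   $t = 0, p = 1$; constant nonzero differences give $t = \pm\infty, p = 0$
   with a note; fewer than two complete pairs marks the test unavailable.

Design points that were genuinely open:

* Whether representative quality is computed before or after merging is not
  fixed by the method's description; qualities are computed per input table
  before merging, so the choice reflects each extraction's own replicate
  behaviour.
* The consequence of the paired t-test is likewise unstated; reporting
  always and acting only under an explicit `t_test_alpha` preserves the
  default merge-by-tolerance behaviour while making the test actionable.
* More than two tables fold pairwise in input order, with a warning — the
  algorithm is defined for the two-setting case.

## Choosing a setting pair

Each candidate setting (and each unordered pair, evaluated on its merged
table) is scored with

$$S = N - w \cdot \mathrm{medianPID},$$

where $N$ is the feature count, medianPID the median over features of the
per-feature median metric (in percent), and $w$ balances quantity against
quality: $w = 30$ favours feature count, $w = 100$ reliability. For merged
pairs, medianPID is recomputed on the merged table. "Median over features"
is one reading of an ambiguous convention ("averaged over all features");
`optimize_pair(..., summary_fun = "mean")` provides the other. The bundled
`sensitivity_settings()` table carries a published benchmark of ten
candidates; ranking it selects the same optimum under both weights.

## Matching, Venn counts, rare features

`find_overlapping_mzs()` reports *all* pairs within the m/z (and
optionally RT) thresholds, many-to-many included. The ppm denominator is
the smaller of the two m/z values, making matching symmetric in the two
lists (the asymmetric "reference = list 1" convention would let a pair
match in one direction only). `find_unique_mzs()` is the per-list
complement, and both are verified against exhaustive pairwise search.

For Venn summaries each feature is assigned to the region of all datasets
in which it has at least one match, so regions count features, not matches,
and each dataset's regions sum to its feature count. Because dataset A's
tally of the "A∩B" region and B's tally need not agree under many-to-many
matching, `venn_counts()` returns both the per-dataset tally matrix and a
consolidated count per region, the maximum of the contributing tallies
(identical lists then give $|A|$ in the intersection, not $2|A|$).

`check_mz_in_replicates()` finds rare features — present in few biological
samples but consistently within them, the signature of individual-specific
exposures. A feature qualifies in a sample when observed in at least
`ceiling(min_reps/100 * r)` of its `r` replicates, and is kept when it
qualifies in at least `min_samps` samples.

## Annotation

`batch_annotate()` matches query m/z values against a local compound table
via adduct arithmetic: a compound of neutral monoisotopic mass $M$ is
observed at $(M + \delta)/z$ per adduct (proton 1.00727646677 u, water
18.0105646863 u; one constants table). The ppm window is referenced to the
query m/z. The implementation is a sorted binary search proven equal to
exhaustive search in the tests. Live database queries are deliberately out
of scope — they are irreproducible and terms-of-service-fragile — so the
database is a documented TSV; a ~58-compound demo database with masses
computed from molecular formulas and exact atomic masses ships in
`inst/extdata/`. External identifiers (KEGG, HMDB, PubChem, ChEBI, CAS,
LipidMAPS) pass through as opaque strings and become hyperlinks in the HTML
report. Expect random m/z values to annotate occasionally even against a
sparse database — an annotation is a mass match, not an identification.

## The synthetic-data generator

`generate_extraction_pair()` builds the world the merge exists for: a
ground-truth compound set extracted under two settings. Defaults state that
world once:

* 30 shared + 10 per-setting-unique compounds, m/z uniform in [85, 850]
  with separations forced above 3x the merge tolerance (identity is never
  ambiguous), RT uniform in [60, 600] s;
* 10 biological samples, duplicate injections (the common QC design);
* compound base abundances log-normal (`sdlog` 1.2) with per-sample
  biological effects (`sdlog` 0.5) shared across settings, so shared
  features are correlated between tables;
* multiplicative log-normal replicate noise; each shared compound gets one
  low-noise member (log-sd ~ U(0.05, 0.15)) and one high-noise member
  (~ U(0.25, 0.35)) in a random setting — different extraction settings
  genuinely differ in integration reproducibility, which is what
  representative selection is for. These bands put per-sample PIDs in the
  0–60% range seen in real duplicate data;
* 5% independent per-cell missingness; coordinate jitter between settings
  of 1 ppm / 2 s standard deviation, truncated at 0.45x the respective
  tolerance so two copies of one compound always fall within tolerance —
  the generator's identity contract is exact by construction, not just
  probable.

What the generator does *not* emulate: retention-time drift and warping,
correlated (adduct/isotope) features, intensity-dependent missingness,
chemical noise, batch effects. A green synthetic test therefore establishes
algorithmic correctness on well-posed inputs, not robustness to
chromatographic pathology — that is what the quality filters are for on
real data.

## Numerical and I/O conventions

* Extractors commonly write 0 for "not detected"; by default a stored 0 is
  read as missing, with `zero_as_missing = FALSE` to treat zeros as
  observed (the raw data cannot settle which is meant, so it is a flag).
  The "no missing values" completeness rules above are meaningless without
  this convention.
* Tables are delimited text (tab or comma, auto-detected) with columns
  `mz`, `time` (seconds), then one intensity column per profile. m/z is
  written with 7 decimals (sub-ppm everywhere in range), intensities with
  6 significant digits; a write/read round trip is the identity to that
  precision.
* PID of a (0, 0) pair and CV of a zero-mean vector are undefined and
  excluded, never coerced to a number.
* The pipeline (`run_pipeline()`) is deterministic: fixed inputs and
  configuration give byte-identical primary outputs; timestamps are
  confined to the run log.

## A worked example

```{r example, eval = FALSE}
fx <- generate_extraction_pair(synth_config(seed = 7))
res <- merge_results(list(fx$table1, fx$table2), fx$design)
res$report
#> merge_report: inputs 40 + 40 -> 50 features
#>   sub-groups: 50 (20 unique, 30 collapsed, 0 kept distinct by t-test)

ranked <- rank_settings(sensitivity_settings(), w = c(30, 100))
subset(ranked, is_argmax)
#>            label n_features median_pid   w  score is_argmax
#> 1  3,0.3 u 3,0.8       2384      35.69  30 1313.3      TRUE
#> 11 3,0.3 u 3,0.8       2384      35.69 100 -1185.0      TRUE
```

## Known limitations

* Single-linkage chains can join features spanning more than one tolerance
  between extremes; with well-separated analytes this does not occur, but
  dense regions (isotope shoulders, co-eluting isomers) can over-merge.
* The merge assumes the input tables come from the *same* runs (identical
  profile columns); it performs no retention-time alignment across runs.
* Folding more than two settings is order-dependent in principle (the
  two-setting algorithm applied repeatedly).
* Annotation is mass-based only; isotope patterns and MS/MS evidence are
  out of scope.
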