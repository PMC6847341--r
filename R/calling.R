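# Per-position orchestration over an mpileup file: estimate rates for the
# treated and control groups, run the between- and within-group tests,
# apply the published filters and call candidate m7G positions.

#' Treated/control sample design
#'
#' Maps 1-based sample column indices of a multi-sample mpileup file to
#' conditions. Each index is its own replicate.
#'
#' @param treated,control integer vectors of sample indices (1-based, in
#'   mpileup column order).
#' @return an object of class `m7g_design`.
#' @examples
#' sample_design(treated = 1:3, control = 4:6)
#' @export
sample_design <- function(treated, control) {
  treated <- as.integer(treated); control <- as.integer(control)
  if (length(treated) < 1L || length(control) < 1L)
    stop("need at least one treated and one control sample")
  if (anyDuplicated(c(treated, control)))
    stop("sample indices must be unique across conditions")
  if (any(c(treated, control) < 1L))
    stop("sample indices are 1-based and must be >= 1")
  structure(list(treated = treated, control = control), class = "m7g_design")
}

#' Calling thresholds
#'
#' Filter and calling cut-offs with the published defaults: combined
#' sequencing depth strictly greater than 1500 across all samples (500 in
#' single-replicate rRNA-style analyses), mean control-replicate mutation
#' frequency below 1%, within-replicate heterogeneity p-value at least
#' 1e-5, and candidate calling at a mutation-rate difference of at least
#' 0.5% with a between-condition p-value below 1e-50.
#'
#' @param min_depth_combined combined treated+control depth must exceed
#'   this (strict) to pass; default 1500.
#' @param min_depth_single depth cut-off used instead when both conditions
#'   have a single replicate; default 500.
#' @param max_control_rate mean per-replicate control frequency must be
#'   below this; default 0.01.
#' @param within_p_floor positions with a within-replicate p-value below
#'   this (either condition) are flagged inconsistent; default 1e-5.
#' @param min_delta minimum mutation-rate difference for calling; default
#'   0.005.
#' @param max_between_p between-condition p-value must be below this for
#'   calling; default 1e-50.
#' @param g_only restrict candidate calls to reference-base G positions
#'   (m7G occurs on G); default `TRUE`. The full results table always
#'   reports every base, since other NaBH4-sensitive modifications (m1A,
#'   dihydrouridine, ac4C) also leave signals.
#' @return an object of class `m7g_thresholds`.
#' @export
calling_thresholds <- function(min_depth_combined = 1500L,
                               min_depth_single = 500L,
                               max_control_rate = 0.01,
                               within_p_floor = 1e-5,
                               min_delta = 0.005,
                               max_between_p = 1e-50,
                               g_only = TRUE) {
  stopifnot(min_depth_combined >= 0, min_depth_single >= 0, min_delta >= 0)
  stop_if_not_scalar_prob(max_control_rate, "max_control_rate")
  stop_if_not_scalar_prob(within_p_floor, "within_p_floor")
  stop_if_not_scalar_prob(max_between_p, "max_between_p")
  structure(list(min_depth_combined = as.integer(min_depth_combined),
                 min_depth_single = as.integer(min_depth_single),
                 max_control_rate = max_control_rate,
                 within_p_floor = within_p_floor,
                 min_delta = min_delta,
                 max_between_p = max_between_p,
                 g_only = isTRUE(g_only)),
            class = "m7g_thresholds")
}

# observation sets per sample for one parsed site
site_obs_sets <- function(site, idx) {
  lapply(site$samples[idx], function(s)
    obs_set_from_strings(s$base_string, s$quality_string,
                         site$reference_base))
}

#' Analyze one pileup position
#'
#' Runs the estimator and both likelihood-ratio tests on a parsed site and
#' returns the per-position statistics row. When a condition has zero
#' observations the position is marked untestable (no p-values).
#'
#' @param site one element of `parse_mpileup()$sites`.
#' @param design an [sample_design()].
#' @return a one-row data frame: `reference_name`, `position`,
#'   `reference_base`, `depth_treated`, `depth_control` (summed reported
#'   mpileup depths), `f_treated`, `f_control`, `delta`, `p_between`,
#'   `neg10log10_p`, `p_within_treated`, `p_within_control`,
#'   `control_rate_mean` (unweighted mean of per-replicate control
#'   estimates) and `untestable`.
#' @export
analyze_position <- function(site, design) {
  if (max(c(design$treated, design$control)) > length(site$samples))
    stop("design refers to sample indices beyond the file's sample count")
  tr_sets <- site_obs_sets(site, design$treated)
  ct_sets <- site_obs_sets(site, design$control)
  depth_t <- sum(vapply(site$samples[design$treated], `[[`, 0L, "reported_depth"))
  depth_c <- sum(vapply(site$samples[design$control], `[[`, 0L, "reported_depth"))

  bt <- lrt_between(tr_sets, ct_sets)
  wt <- if (length(tr_sets) >= 2L) lrt_within(tr_sets) else untestable_result()
  wc <- if (length(ct_sets) >= 2L) lrt_within(ct_sets) else untestable_result()

  ct_f <- vapply(ct_sets, function(g)
    if (n_obs(g) > 0) estimate_rate_em(g)$f_hat else NA_real_, 0)
  ctrl_mean <- if (all(is.na(ct_f))) NA_real_ else mean(ct_f, na.rm = TRUE)

  delta <- if (isTRUE(bt$untestable)) NA_real_ else
    mutation_rate_difference(bt$f_treated, bt$f_control)
  data.frame(
    reference_name = site$reference_name,
    position = site$position,
    reference_base = site$reference_base,
    depth_treated = depth_t,
    depth_control = depth_c,
    f_treated = bt$f_treated,
    f_control = bt$f_control,
    delta = delta,
    p_between = bt$p_value,
    neg10log10_p = bt$neg10log10_p,
    p_within_treated = wt$p_value,
    p_within_control = wc$p_value,
    control_rate_mean = ctrl_mean,
    untestable = isTRUE(bt$untestable),
    stringsAsFactors = FALSE)
}

#' Analyze all positions of an mpileup input
#'
#' Parses (if needed) and analyzes every position, then applies the
#' filters. The output is deterministic: the same input and design give a
#' byte-identical table.
#'
#' @param input an `m7g_pileup` object, a path to an mpileup file, or
#'   mpileup lines.
#' @param design an [sample_design()].
#' @param thresholds a [calling_thresholds()] (used by the filter columns).
#' @return a data frame with one row per position: the columns of
#'   [analyze_position()] plus `filter_flags`, `passed` and `called` (see
#'   [apply_filters()] and [call_candidates()]).
#' @examples
#' cfg <- sim_config(reference_length = 50, mean_depth = 150, seed = 7,
#'                   n_treated = 2, n_control = 2)
#' sim <- simulate_pileup(cfg)
#' res <- analyze_pileup(sim$lines, sample_design(1:2, 3:4),
#'                       calling_thresholds(min_depth_combined = 100))
#' head(res[, c("position", "delta", "p_between", "passed")])
#' @export
analyze_pileup <- function(input, design, thresholds = calling_thresholds()) {
  pu <- if (inherits(input, "m7g_pileup")) input else parse_mpileup(input)
  if (length(pu$sites) && max(c(design$treated, design$control)) > pu$n_samples)
    stop("design refers to sample indices beyond the file's sample count")
  rows <- lapply(pu$sites, analyze_position, design = design)
  res <- if (length(rows)) do.call(rbind, rows) else
    analyze_position_empty_frame()
  res <- apply_filters(res, thresholds,
                       single_replicate = length(design$treated) == 1L &&
                         length(design$control) == 1L)
  res$called <- called_flag(res, thresholds)
  res
}

analyze_position_empty_frame <- function() {
  data.frame(reference_name = character(), position = integer(),
             reference_base = character(), depth_treated = integer(),
             depth_control = integer(), f_treated = numeric(),
             f_control = numeric(), delta = numeric(), p_between = numeric(),
             neg10log10_p = numeric(), p_within_treated = numeric(),
             p_within_control = numeric(), control_rate_mean = numeric(),
             untestable = logical(), stringsAsFactors = FALSE)
}

#' Apply the position filters
#'
#' Sets independent filter flags on a results table:
#' * `low_depth` — combined treated+control depth not strictly greater
#'   than the threshold (1500 by default; the single-replicate threshold,
#'   500 by default, is used when `single_replicate = TRUE`);
#' * `high_control_rate` — mean per-replicate control frequency at or
#'   above 1%;
#' * `replicate_inconsistent` — within-replicate heterogeneity p-value
#'   below 1e-5 in either condition;
#' * `untestable` — a condition had no observations.
#'
#' Flags are set independently, so filtering is order-independent; a
#' position passes iff its flag set is empty.
#'
#' @param results data frame from [analyze_position()] rows.
#' @param thresholds a [calling_thresholds()].
#' @param single_replicate use the single-replicate depth cut-off and skip
#'   replicate-consistency flags (no within-group test exists).
#' @return `results` with added columns `flag_low_depth`,
#'   `flag_high_control_rate`, `flag_replicate_inconsistent`,
#'   `flag_untestable`, `filter_flags` (comma-separated, `""` if none) and
#'   `passed`.
#' @export
apply_filters <- function(results, thresholds = calling_thresholds(),
                          single_replicate = FALSE) {
  min_depth <- if (single_replicate) thresholds$min_depth_single
               else thresholds$min_depth_combined
  combined <- results$depth_treated + results$depth_control
  results$flag_low_depth <- combined <= min_depth
  results$flag_high_control_rate <-
    !is.na(results$control_rate_mean) &
    results$control_rate_mean >= thresholds$max_control_rate
  wt <- results$p_within_treated
  wc <- results$p_within_control
  results$flag_replicate_inconsistent <-
    (!is.na(wt) & wt < thresholds$within_p_floor) |
    (!is.na(wc) & wc < thresholds$within_p_floor)
  results$flag_untestable <- results$untestable

  flagmat <- cbind(low_depth = results$flag_low_depth,
                   high_control_rate = results$flag_high_control_rate,
                   replicate_inconsistent = results$flag_replicate_inconsistent,
                   untestable = results$flag_untestable)
  results$filter_flags <- apply(flagmat, 1L, function(r)
    paste(colnames(flagmat)[r], collapse = ","))
  results$passed <- !rowSums(flagmat)
  results
}

called_flag <- function(results, thresholds) {
  ok <- results$passed &
    !is.na(results$delta) & results$delta >= thresholds$min_delta &
    !is.na(results$p_between) & results$p_between < thresholds$max_between_p
  if (thresholds$g_only)
    ok <- ok & toupper(results$reference_base) == "G"
  ok
}

#' Call candidate modified positions
#'
#' Returns the positions passing every filter with a mutation-rate
#' difference of at least `min_delta` and a between-condition p-value
#' below `max_between_p`; restricted to reference-base G by default.
#'
#' @param results filtered results table (from [analyze_pileup()] or
#'   [apply_filters()]).
#' @param thresholds a [calling_thresholds()].
#' @return the subset of rows that are called.
#' @export
call_candidates <- function(results, thresholds = calling_thresholds()) {
  results[called_flag(results, thresholds), , drop = FALSE]
}

# ---- table I/O ------------------------------------------------------------

#' Write / read a results table
#'
#' Tab-separated export with a header, one row per analyzed position,
#' 1-based positions. Numeric columns are written with full precision so
#' the export/import round-trip is lossless.
#'
#' @param results results data frame.
#' @param path output TSV path.
#' @return `write_results_tsv()` returns `path` invisibly;
#'   `read_results_tsv()` returns the data frame.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, TRUE) & !vapply(out, is.integer, TRUE)
  for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = NA)
}

#' Export called sites as BED6
#'
#' Converts called positions to BED6 (0-based half-open; the only place
#' the package leaves 1-based coordinates). Score is the capped
#' `-10*log10(p)` rounded and truncated at 1000 per the BED convention.
#'
#' @param called data frame of called rows (see [call_candidates()]).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
export_called_bed <- function(called, path) {
  bed <- data.frame(chrom = called$reference_name,
                    start = called$position - 1L,
                    end = called$position,
                    name = paste0("m7G_", called$reference_name, "_",
                                  called$position),
                    score = pmin(1000L, as.integer(round(called$neg10log10_p))),
                    strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
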