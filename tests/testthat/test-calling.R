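# build a 2-sample pileup line with given mutated counts and quality 'I'
two_sample_line <- function(k_t, n_t, k_c, n_c, pos = 10L, base = "G") {
  mk <- function(k, n) {
    bases <- paste0(strrep(".", n - k), strrep("A", k))
    paste(n, bases, strrep("I", n), sep = "\t")
  }
  paste("ref", pos, base, mk(k_t, n_t), mk(k_c, n_c), sep = "\t")
}

test_that("analyze_position fills the statistics row from the pileup", {
  design <- sample_design(treated = 1, control = 2)
  site <- parse_mpileup(two_sample_line(10, 100, 0, 100))$sites[[1]]
  row <- analyze_position(site, design)
  expect_equal(row$depth_treated, 100L)
  expect_equal(row$depth_control, 100L)
  expect_equal(row$delta, row$f_treated - row$f_control)
  expect_gt(row$delta, 0.08)
  # near-zero error: p agrees with the closed-form two-binomial LRT
  p_oracle <- pchisq(binom_lrt2(10, 100, 0, 100), df = 1, lower.tail = FALSE)
  expect_equal(row$p_between, p_oracle, tolerance = 1e-2)
  expect_lt(row$p_between, 1e-3)
  expect_false(row$untestable)
  # no replicates: within-group p-values undefined
  expect_true(is.na(row$p_within_treated))

  same <- parse_mpileup(two_sample_line(5, 80, 5, 80))$sites[[1]]
  row2 <- analyze_position(same, design)
  expect_equal(row2$delta, 0, tolerance = 1e-9)
  expect_equal(row2$p_between, 1)

  zd <- parse_mpileup("ref\t1\tG\t5\t..,..\tIIIII\t0\t*\t*")$sites[[1]]
  row3 <- analyze_position(zd, design)
  expect_true(row3$untestable)
  expect_true(is.na(row3$p_between))
})

test_that("filters implement the published cut-offs with strict depth", {
  base_row <- function(depth_t, depth_c, ctrl_mean = 0.001,
                       pw_t = 0.5, pw_c = 0.5) {
    data.frame(reference_name = "ref", position = 1L, reference_base = "G",
               depth_treated = depth_t, depth_control = depth_c,
               f_treated = 0.05, f_control = 0.001, delta = 0.049,
               p_between = 1e-60, neg10log10_p = 600,
               p_within_treated = pw_t, p_within_control = pw_c,
               control_rate_mean = ctrl_mean, untestable = FALSE,
               stringsAsFactors = FALSE)
  }
  th <- calling_thresholds()
  # combined depth must be strictly greater than 1500
  expect_true(apply_filters(base_row(700, 799), th)$flag_low_depth)
  expect_true(apply_filters(base_row(750, 750), th)$flag_low_depth)
  expect_false(apply_filters(base_row(751, 750), th)$flag_low_depth)
  # mean control replicate frequency must stay below 1%
  expect_true(apply_filters(base_row(1000, 1000, ctrl_mean = 0.012),
                            th)$flag_high_control_rate)
  expect_false(apply_filters(base_row(1000, 1000, ctrl_mean = 0.009),
                             th)$flag_high_control_rate)
  # replicate heterogeneity below 1e-5 in either condition flags the site
  expect_true(apply_filters(base_row(1000, 1000, pw_c = 1e-6),
                            th)$flag_replicate_inconsistent)
  expect_false(apply_filters(base_row(1000, 1000, pw_c = 1e-4),
                             th)$flag_replicate_inconsistent)
  # flags compose into filter_flags / passed independently
  r <- apply_filters(base_row(700, 700, ctrl_mean = 0.02), th)
  expect_equal(r$filter_flags, "low_depth,high_control_rate")
  expect_false(r$passed)
  ok <- apply_filters(base_row(1000, 1000), th)
  expect_identical(ok$filter_flags, "")
  expect_true(ok$passed)
  # single-replicate mode uses the 500 cut-off
  expect_true(apply_filters(base_row(250, 250), th,
                            single_replicate = TRUE)$flag_low_depth)
  expect_false(apply_filters(base_row(300, 300), th,
                             single_replicate = TRUE)$flag_low_depth)
})

test_that("candidate calling applies delta and p cut-offs on passed G sites", {
  th <- calling_thresholds()
  row <- function(delta, p, base = "G") {
    r <- data.frame(reference_name = "ref", position = 1L,
                    reference_base = base, depth_treated = 3000L,
                    depth_control = 3000L, f_treated = delta + 0.001,
                    f_control = 0.001, delta = delta, p_between = p,
                    neg10log10_p = -10 * log10(p), p_within_treated = 0.5,
                    p_within_control = 0.5, control_rate_mean = 0.001,
                    untestable = FALSE, stringsAsFactors = FALSE)
    apply_filters(r, th)
  }
  expect_equal(nrow(call_candidates(row(0.006, 1e-60), th)), 1L)
  expect_equal(nrow(call_candidates(row(0.006, 1e-10), th)), 0L)
  expect_equal(nrow(call_candidates(row(0.004, 1e-200), th)), 0L)
  # G restriction is on by default and can be lifted
  expect_equal(nrow(call_candidates(row(0.02, 1e-60, base = "A"), th)), 0L)
  th_all <- calling_thresholds(g_only = FALSE)
  expect_equal(nrow(call_candidates(row(0.02, 1e-60, base = "A"), th_all)), 1L)
})

test_that("analysis output is deterministic and round-trips through TSV", {
  cfg <- sim_config(reference_length = 40L, mean_depth = 150L,
                    n_treated = 2L, n_control = 2L, n_modified = 1L,
                    detection = 0.3, seed = 77)
  sim <- simulate_pileup(cfg)
  design <- sample_design(1:2, 3:4)
  th <- calling_thresholds(min_depth_combined = 100L)
  r1 <- analyze_pileup(sim$lines, design, th)
  r2 <- analyze_pileup(sim$lines, design, th)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_results_tsv(r1, f1); write_results_tsv(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_results_tsv(f1)
  expect_equal(back$delta, r1$delta)             # lossless numerics
  expect_equal(back$p_between, r1$p_between)
  unlink(c(f1, f2))
})

test_that("BED export converts to 0-based half-open coordinates", {
  called <- data.frame(reference_name = "SSU", position = 527L,
                       neg10log10_p = 1234.5)
  f <- tempfile(fileext = ".bed")
  export_called_bed(called, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2, 526L)
  expect_equal(bed$V3, 527L)
  expect_equal(bed$V5, 1000L)  # capped BED score
  unlink(f)
})

test_that("designs are validated", {
  expect_error(sample_design(integer(), 1), "at least one")
  expect_error(sample_design(c(1, 2), c(2, 3)), "unique")
  expect_error(sample_design(0, 1), "1-based")
  site <- parse_mpileup("ref\t1\tG\t1\t.\tI")$sites[[1]]
  expect_error(analyze_position(site, sample_design(1, 5)), "beyond")
})
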