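test_that("mpileup lines map to sites with verbatim columns", {
  p <- parse_mpileup("SSU\t527\tG\t5\t..AA,\tIIIII")
  expect_equal(length(p$sites), 1L)
  s <- p$sites[[1]]
  expect_equal(s$reference_name, "SSU")
  expect_equal(s$position, 527L)
  expect_equal(s$reference_base, "G")
  expect_equal(s$samples[[1]]$reported_depth, 5L)
  expect_equal(s$samples[[1]]$base_string, "..AA,")

  # zero-depth column convention in a 2-sample file
  p2 <- parse_mpileup("ref\t1\tG\t3\t..,\tIII\t0\t*\t*")
  expect_equal(p2$n_samples, 2L)
  expect_equal(p2$sites[[1]]$samples[[2]]$reported_depth, 0L)
  expect_equal(nrow(tokenize_bases(p2$sites[[1]]$samples[[2]]$base_string,
                                   p2$sites[[1]]$samples[[2]]$quality_string,
                                   "G")), 0L)
})

test_that("malformed input is rejected with the offending line number", {
  expect_error(parse_mpileup(c("ref\t1\tG\t1\t.\tI",
                               "ref\t2\tG\t1\t.")), "line 2")
  expect_error(parse_mpileup("ref\t0\tG\t1\t.\tI"), "position")
  expect_warning(parse_mpileup(c("ref\t5\tG\t1\t.\tI",
                                 "ref\t3\tG\t1\t.\tI")), "non-monotone")
})

test_that("pileup grammar resolves matches, mismatches, indels and skips", {
  tk <- tokenize_bases("..A", "III", "G")
  expect_equal(as.character(tk$kind),
               c("reference_match", "reference_match", "substitution"))
  expect_equal(tk$observed_base[3], "A")
  expect_equal(tk$error_prob, rep(1e-4, 3))

  # read start consumed; '+' upgrades its preceding anchor to insertion
  tk2 <- tokenize_bases("^].+2AG,", "II", "G")
  expect_equal(as.character(tk2$kind), c("insertion", "reference_match"))
  expect_equal(tk2$observed_base[1], "AG")
  expect_equal(tk2$strand, c("forward", "reverse"))

  # '*' is a deletion observation; '>' occupies a quality slot only
  tk3 <- tokenize_bases(".*>,", "IIII", "G")
  expect_equal(as.character(tk3$kind),
               c("reference_match", "deletion", "reference_match"))

  # '-' upgrades its anchor to deletion kind; '$' produces no observation
  tk4 <- tokenize_bases(".-1T.$", "II", "G")
  expect_equal(as.character(tk4$kind), c("deletion", "reference_match"))

  # N calls are reported as substitutions with base N
  tk5 <- tokenize_bases(".N", "II", "G")
  expect_equal(tk5$observed_base, c("G", "N"))
})

test_that("grammar violations are parse errors", {
  expect_error(tokenize_bases("+2AG.", "I", "G"), "dangling indel")
  expect_error(tokenize_bases("..", "I", "G"), "shorter")
  expect_error(tokenize_bases(".", "II", "G"), "longer")
  expect_error(tokenize_bases(".x", "II", "G"), "unknown pileup character")
  expect_error(tokenize_bases("^", "", "G"), "dangling")
})

test_that("parsing is strand-symmetric and bounded by reported depth", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    tok <- sample(c(".", "A", "C", "T", "*"), n, replace = TRUE,
                  prob = c(0.7, 0.1, 0.1, 0.05, 0.05))
    q <- paste(sample(strsplit("IJF5+!", "")[[1]], n, TRUE), collapse = "")
    up <- paste(tok, collapse = "")
    down <- chartr(".ACT", ",act", up)
    tu <- tokenize_bases(up, q, "G")
    td <- tokenize_bases(down, q, "G")
    expect_equal(table(tu$kind), table(td$kind))
    expect_lte(nrow(tu), n)
    expect_equal(nrow(tu), n)  # no '><' present: equality
  }
  # with skips, strictly fewer observations than the depth slot count
  tk <- tokenize_bases(".>><,", "IIIII", "G")
  expect_equal(nrow(tk), 2L)
})

test_that("parser agrees with samtools mpileup on a constructed alignment", {
  fx <- samtools_fixture()
  on.exit(unlink(fx$dir, recursive = TRUE))
  got <- parse_observed_counts(fx$pileup)
  want <- cigar_walk_expected(fx$sam, fx$ref)
  want <- want[want$n_obs > 0, ]
  merged <- merge(got, want, by = "position", suffixes = c("_parser", "_sam"))
  expect_equal(nrow(merged), nrow(got))
  expect_equal(merged$n_obs_parser, merged$n_obs_sam)
  expect_equal(merged$n_mut_parser, merged$n_mut_sam)
})
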