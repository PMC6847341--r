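write_fastq <- function(recs, path) {
  writeLines(unlist(lapply(recs, function(r)
    c(paste0("@", r$id), r$seq, "+", r$qual))), path)
}

test_that("barcode extraction trims 9 bases and discards N barcodes", {
  fq <- tempfile(fileext = ".fastq"); out <- tempfile(fileext = ".fastq")
  tab <- tempfile(fileext = ".tsv")
  write_fastq(list(
    list(id = "read1", seq = "ACGTACGTTGCATGCA", qual = strrep("I", 16)),
    list(id = "read2", seq = "ACGNACGTTGCATGCA", qual = strrep("I", 16)),
    list(id = "read3", seq = "TTTTTTTTTGGGG", qual = strrep("F", 13))), fq)
  st <- extract_barcodes(fq, out, tab)
  expect_equal(st$n_in, 3L)
  expect_equal(st$n_out, 2L)
  expect_equal(st$n_discarded_n, 1L)
  expect_equal(st$barcodes$barcode, c("ACGTACG", "TTTTTTT"))
  fqo <- readLines(out)
  expect_equal(fqo[1], "@read1:BC:ACGTACG")
  expect_equal(fqo[2], "GCATGCA")      # 9 bases trimmed from 16
  expect_equal(nchar(fqo[4]), 7L)      # qualities trimmed in step
  sidecar <- read.table(tab, header = TRUE, sep = "\t",
                        colClasses = "character")
  expect_equal(sidecar$read_id, c("read1", "read3"))
  unlink(c(fq, out, tab))
})

test_that("short reads are discarded with a warning and empty input is fine", {
  fq <- tempfile(fileext = ".fastq"); out <- tempfile(fileext = ".fastq")
  write_fastq(list(list(id = "tiny", seq = "ACGTAC", qual = "IIIIII"),
                   list(id = "ok", seq = "ACGTACGTTGCA", qual = strrep("I", 12))),
              fq)
  expect_warning(st <- extract_barcodes(fq, out), "shorter")
  expect_equal(st$n_discarded_short, 1L)
  expect_equal(st$n_out, 1L)

  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  st0 <- extract_barcodes(empty, out)
  expect_equal(st0$n_in, 0L)
  expect_equal(st0$n_out, 0L)
  unlink(c(fq, out, empty))
})

sam_lines <- function(recs) {
  c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000", "@SQ\tSN:chr2\tLN:1000",
    vapply(recs, function(r)
      paste(r$id, r$flag, r$ref, r$pos, 60, "8M", "*", 0, 0,
            "ACGTACGT", "IIIIIIII", sep = "\t"), ""))
}

test_that("duplicate collapsing keeps one read per position/strand/barcode", {
  sam <- tempfile(fileext = ".sam"); out <- tempfile(fileext = ".sam")
  recs <- list(
    list(id = "c:BC:AAAAAAA", flag = 0, ref = "chr1", pos = 100),
    list(id = "a:BC:AAAAAAA", flag = 0, ref = "chr1", pos = 100),
    list(id = "b:BC:AAAAAAA", flag = 0, ref = "chr1", pos = 100),
    list(id = "d:BC:CCCCCCC", flag = 0, ref = "chr1", pos = 100),
    list(id = "e:BC:AAAAAAA", flag = 16, ref = "chr1", pos = 100),
    list(id = "f:BC:AAAAAAA", flag = 0, ref = "chr2", pos = 100),
    list(id = "g:BC:AAAAAAA", flag = 4, ref = "*", pos = 0),
    list(id = "nobc", flag = 0, ref = "chr1", pos = 200))
  writeLines(sam_lines(recs), sam)
  st <- collapse_duplicates(sam, out)
  expect_equal(st$n_in, 8L)
  expect_equal(st$n_unmapped, 1L)
  expect_equal(st$n_no_barcode, 1L)
  expect_equal(st$n_duplicates, 2L)
  kept <- grep("^@", readLines(out), value = TRUE, invert = TRUE)
  ids <- vapply(strsplit(kept, "\t"), `[[`, "", 1)
  # smallest read id wins within the triplicated group
  expect_true("a:BC:AAAAAAA" %in% ids)
  expect_false(any(c("b:BC:AAAAAAA", "c:BC:AAAAAAA") %in% ids))
  expect_setequal(ids, c("a:BC:AAAAAAA", "d:BC:CCCCCCC", "e:BC:AAAAAAA",
                         "f:BC:AAAAAAA", "nobc"))
  unlink(c(sam, out))
})

test_that("collapsing is idempotent and order-independent", {
  set.seed(53)
  recs <- lapply(1:40, function(i)
    list(id = sprintf("r%02d:BC:%s", i,
                      paste(sample(c("A", "C"), 7, TRUE), collapse = "")),
         flag = sample(c(0, 16), 1), ref = sample(c("chr1", "chr2"), 1),
         pos = sample(c(10, 20, 30), 1)))
  sam <- tempfile(); out1 <- tempfile(); out2 <- tempfile(); out3 <- tempfile()
  writeLines(sam_lines(recs), sam)
  collapse_duplicates(sam, out1)
  collapse_duplicates(out1, out2)              # idempotence
  expect_identical(readLines(out1), readLines(out2))

  shuf <- tempfile()
  lines <- sam_lines(recs)
  hdr <- grep("^@", lines, value = TRUE)
  body <- setdiff(lines, hdr)
  writeLines(c(hdr, sample(body)), shuf)
  collapse_duplicates(shuf, out3)              # order independence
  expect_identical(readLines(out1), readLines(out3))

  # retained count equals the number of distinct groups
  key <- vapply(recs, function(r)
    paste(r$ref, r$pos, bitwAnd(r$flag, 16), sub("^.*:BC:", "", r$id)), "")
  mapped <- vapply(recs, function(r) r$flag != 4, TRUE)
  st <- collapse_duplicates(sam, out1)
  expect_equal(st$n_out, length(unique(key[mapped])))
  unlink(c(sam, out1, out2, out3, shuf))
})

test_that("barcodes can come from a sidecar table", {
  sam <- tempfile(); out <- tempfile()
  recs <- list(list(id = "x1", flag = 0, ref = "chr1", pos = 50),
               list(id = "x2", flag = 0, ref = "chr1", pos = 50),
               list(id = "x3", flag = 0, ref = "chr1", pos = 50))
  writeLines(sam_lines(recs), sam)
  tab <- data.frame(read_id = c("x1", "x2", "x3"),
                    barcode = c("AAAAAAA", "AAAAAAA", "TTTTTTT"))
  st <- collapse_duplicates(sam, out, barcode_table = tab)
  expect_equal(st$n_out, 2L)
  unlink(c(sam, out))
})
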