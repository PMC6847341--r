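# Constructed 5-read alignment fixture and an independent CIGAR walker.
# samtools (on PATH) turns the SAM into a pileup; the walker computes the
# expected per-position observation counts directly from the alignment
# records, so parser-vs-samtools agreement is checked against an
# independent path that never touches pileup strings.

samtools_fixture <- function(dir = tempfile("samfix")) {
  dir.create(dir)
  ref_seq <- "ACGTGGCTAGACGTGGCTAG"
  writeLines(c(">ref", ref_seq), file.path(dir, "ref.fa"))
  sub5 <- sub("^(GT)G", "\\1A", substr(ref_seq, 3, 12))  # G->A at pos 5
  reads <- c(
    paste("r1", 0, "ref", 1, 60, "10M", "*", 0, 0,
          substr(ref_seq, 1, 10), strrep("I", 10), sep = "\t"),
    paste("r2", 16, "ref", 3, 60, "10M", "*", 0, 0,
          sub5, strrep("I", 10), sep = "\t"),
    paste("r3", 0, "ref", 2, 60, "4M1I5M", "*", 0, 0,
          paste0(substr(ref_seq, 2, 5), "T", substr(ref_seq, 6, 10)),
          strrep("I", 10), sep = "\t"),
    paste("r4", 0, "ref", 4, 60, "3M2D5M", "*", 0, 0,
          paste0(substr(ref_seq, 4, 6), substr(ref_seq, 9, 13)),
          strrep("I", 8), sep = "\t"),
    paste("r5", 16, "ref", 6, 60, "8M", "*", 0, 0,
          substr(ref_seq, 6, 13), strrep("I", 8), sep = "\t"))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:ref\tLN:%d", nchar(ref_seq)), reads),
             file.path(dir, "aln.sam"))
  system2("samtools", c("view", "-b", "-o", file.path(dir, "aln.unsorted.bam"),
                        file.path(dir, "aln.sam")))
  system2("samtools", c("sort", "-o", file.path(dir, "aln.bam"),
                        file.path(dir, "aln.unsorted.bam")))
  system2("samtools",
          c("mpileup", "-B", "-Q", "0", "-f", file.path(dir, "ref.fa"),
            file.path(dir, "aln.bam")),
          stdout = file.path(dir, "aln.pileup"), stderr = FALSE)
  list(dir = dir, ref = ref_seq, sam = file.path(dir, "aln.sam"),
       pileup = file.path(dir, "aln.pileup"))
}

# expected (n_obs, n_mutated) per reference position from the SAM records,
# using mpileup conventions: deletions span as one observation per deleted
# position; an indel right after an aligned base upgrades that base's
# observation to the mutated class
cigar_walk_expected <- function(sam_path, ref_seq) {
  recs <- grep("^@", readLines(sam_path), value = TRUE, invert = TRUE)
  n_obs <- integer(nchar(ref_seq))
  n_mut <- integer(nchar(ref_seq))
  for (r in recs) {
    f <- strsplit(r, "\t")[[1]]
    pos <- as.integer(f[4]); cig <- f[6]; seq <- f[10]
    ops <- regmatches(cig, gregexpr("\\d+[MIDNSH]", cig))[[1]]
    rp <- pos; sp <- 1L
    last_aligned <- NA_integer_
    for (op in ops) {
      len <- as.integer(sub("[MIDNSH]", "", op))
      type <- sub("\\d+", "", op)
      if (type == "M") {
        for (j in 0:(len - 1L)) {
          n_obs[rp + j] <- n_obs[rp + j] + 1L
          if (substr(seq, sp + j, sp + j) !=
              substr(ref_seq, rp + j, rp + j))
            n_mut[rp + j] <- n_mut[rp + j] + 1L
        }
        last_aligned <- rp + len - 1L
        rp <- rp + len; sp <- sp + len
      } else if (type == "I") {
        n_mut[last_aligned] <- n_mut[last_aligned] + 1L  # anchor upgrade
        sp <- sp + len
      } else if (type == "D") {
        n_mut[last_aligned] <- n_mut[last_aligned] + 1L  # anchor upgrade
        for (j in 0:(len - 1L)) {
          n_obs[rp + j] <- n_obs[rp + j] + 1L             # '*' placeholders
          n_mut[rp + j] <- n_mut[rp + j] + 1L
        }
        rp <- rp + len
      } else if (type == "S") {
        sp <- sp + len
      } else if (type == "N") {
        rp <- rp + len
      }
    }
  }
  data.frame(position = seq_along(n_obs), n_obs = n_obs, n_mut = n_mut)
}

# (n_obs, n_mutated) per position from parsing an mpileup file, where an
# anchor upgraded by an indel counts once in the mutated class
parse_observed_counts <- function(pileup_path) {
  pu <- parse_mpileup(pileup_path)
  do.call(rbind, lapply(pu$sites, function(s) {
    tk <- tokenize_bases(s$samples[[1]]$base_string,
                         s$samples[[1]]$quality_string, s$reference_base)
    data.frame(position = s$position, n_obs = nrow(tk),
               n_mut = sum(tk$kind != "reference_match"))
  }))
}
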