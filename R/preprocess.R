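# Read pre-processing for barcoded MaP-seq libraries: extract the 7-nt
# barcode from the 5' end of each read (with two further bases trimmed,
# nine in total) and collapse PCR duplicates among aligned reads sharing
# (reference, leftmost position, strand, barcode). Small-RNA libraries are
# analysed without either step.

#' Extract read barcodes from a FASTQ file
#'
#' Moves the first `barcode_length` bases of each read into the read name
#' (as a `:BC:<barcode>` suffix) and a sidecar table, trimming `trim`
#' bases in total from sequence and qualities. Reads with one or more `N`
#' in the barcode are discarded; reads shorter than `trim` are discarded
#' and counted separately.
#'
#' @param fastq_in input FASTQ path (gzip-transparent).
#' @param fastq_out output FASTQ path for the trimmed reads.
#' @param barcode_table_out optional path for the two-column sidecar TSV
#'   (`read_id`, `barcode`).
#' @param barcode_length barcode length (default 7).
#' @param trim total number of bases removed from the read start (default
#'   9: the 7-base barcode plus 2 spacer bases).
#' @return (invisibly) a list with `n_in`, `n_out`, `n_discarded_n`
#'   (N-containing barcodes), `n_discarded_short`, and `barcodes`, the
#'   sidecar data frame for the retained reads.
#' @export
extract_barcodes <- function(fastq_in, fastq_out, barcode_table_out = NULL,
                             barcode_length = 7L, trim = 9L) {
  stopifnot(trim >= barcode_length)
  empty <- function() {
    writeLines(character(), fastq_out)
    tab <- data.frame(read_id = character(), barcode = character(),
                      stringsAsFactors = FALSE)
    if (!is.null(barcode_table_out))
      write.table(tab, barcode_table_out, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    invisible(list(n_in = 0L, n_out = 0L, n_discarded_n = 0L,
                   n_discarded_short = 0L, barcodes = tab))
  }
  if (file.size(fastq_in) == 0) return(empty())
  reads <- Biostrings::readDNAStringSet(fastq_in, format = "fastq",
                                        with.qualities = TRUE)
  if (length(reads) == 0L) return(empty())
  quals <- S4Vectors::mcols(reads)$qualities
  widths <- Biostrings::width(reads)

  long_enough <- widths >= trim
  n_short <- sum(!long_enough)
  if (n_short > 0L)
    warning(sprintf("%d read(s) shorter than %d bases discarded",
                    n_short, trim))
  reads <- reads[long_enough]
  quals <- quals[long_enough]

  barcodes <- as.character(Biostrings::subseq(reads, 1L, barcode_length))
  keep <- !grepl("N", barcodes, fixed = TRUE)
  n_n <- sum(!keep)
  reads <- reads[keep]
  quals <- quals[keep]
  barcodes <- barcodes[keep]

  ids <- sub(" .*$", "", names(reads))
  out <- Biostrings::subseq(reads, trim + 1L)
  qual_out <- Biostrings::subseq(quals, trim + 1L)
  names(out) <- paste0(ids, ":BC:", barcodes)
  Biostrings::writeXStringSet(out, fastq_out, format = "fastq",
                              qualities = qual_out)
  tab <- data.frame(read_id = ids, barcode = barcodes,
                    stringsAsFactors = FALSE)
  if (!is.null(barcode_table_out))
    write.table(tab, barcode_table_out, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(n_in = n_short + n_n + length(out), n_out = length(out),
                 n_discarded_n = n_n, n_discarded_short = n_short,
                 barcodes = tab))
}

#' Collapse PCR duplicates by barcode and mapping position
#'
#' Retains exactly one alignment record per (reference, leftmost mapped
#' position, strand, barcode) group — the one with the lexicographically
#' smallest read id, so the result is independent of input order.
#' Unmapped records are dropped; records without a retrievable barcode are
#' retained ungrouped and counted separately. Collapsing is idempotent.
#'
#' @param sam_in input SAM path (text; header lines are passed through).
#' @param sam_out output SAM path.
#' @param barcode_table optional data frame (`read_id`, `barcode`) or path
#'   to the sidecar TSV from [extract_barcodes()]. When absent, barcodes
#'   are taken from the `:BC:<barcode>` read-name suffix.
#' @return (invisibly) a list with `n_in`, `n_out`, `n_duplicates`,
#'   `n_unmapped` and `n_no_barcode`.
#' @export
collapse_duplicates <- function(sam_in, sam_out, barcode_table = NULL) {
  lines <- readLines(sam_in)
  is_header <- startsWith(lines, "@")
  header <- lines[is_header]
  recs <- lines[!is_header]
  if (length(recs) == 0L) {
    writeLines(header, sam_out)
    return(invisible(list(n_in = 0L, n_out = 0L, n_duplicates = 0L,
                          n_unmapped = 0L, n_no_barcode = 0L)))
  }
  fields <- strsplit(recs, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L))
    stop("malformed SAM record (fewer than 11 fields)")
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  strand <- ifelse(bitwAnd(flag, 16L) == 0L, "+", "-")

  if (is.character(barcode_table))
    barcode_table <- read.table(barcode_table, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  bc <- if (!is.null(barcode_table)) {
    barcode_table$barcode[match(qname, barcode_table$read_id)]
  } else {
    ifelse(grepl(":BC:", qname, fixed = TRUE),
           sub("^.*:BC:", "", qname), NA_character_)
  }

  n_unmapped <- sum(!mapped)
  idx <- which(mapped)
  has_bc <- !is.na(bc[idx])
  grouped <- idx[has_bc]
  ungrouped <- idx[!has_bc]

  keep <- ungrouped
  if (length(grouped)) {
    key <- paste(rname[grouped], pos[grouped], strand[grouped], bc[grouped],
                 sep = "\r")
    ord <- grouped[order(key, qname[grouped])]
    okey <- paste(rname[ord], pos[ord], strand[ord], bc[ord], sep = "\r")
    keep <- c(keep, ord[!duplicated(okey)])
  }
  # deterministic output order regardless of input order
  keep <- keep[order(rname[keep], pos[keep], strand[keep], qname[keep])]
  writeLines(c(header, recs[keep]), sam_out)
  invisible(list(n_in = length(recs), n_out = length(keep),
                 n_duplicates = length(grouped) -
                   (length(keep) - length(ungrouped)),
                 n_unmapped = n_unmapped, n_no_barcode = length(ungrouped)))
}
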