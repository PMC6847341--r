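# Parsing of samtools-mpileup text: one line per reference position, three
# leading fields (reference, 1-based position, reference base) followed by a
# (depth, base string, quality string) triplet per sample. Coordinates stay
# 1-based mpileup-native throughout the package.

#' Parse multi-sample samtools-mpileup text
#'
#' Reads default-format `samtools mpileup` output (tab-separated, Phred+33
#' qualities, one `(depth, bases, qualities)` triplet per sample) into a
#' list of per-position sites. Base and quality strings are retained
#' verbatim; the pileup grammar is resolved lazily by [tokenize_bases()].
#'
#' @param input path to an mpileup file, or a character vector of mpileup
#'   lines.
#' @param n_samples expected number of samples; inferred from the first
#'   line when `NULL`. A line whose field count disagrees is a parse error.
#' @return an object of class `m7g_pileup`: a list with elements `sites`
#'   (list of sites, each with `reference_name`, `position`,
#'   `reference_base` and `samples`, a list of `(reported_depth,
#'   base_string, quality_string)`) and `n_samples`.
#' @details Zero-depth sample columns may be encoded as `0 * *` (or with
#'   empty strings); they yield zero observations. Non-monotone positions
#'   within one reference give a warning, not an error, since mpileup
#'   output over concatenated references restarts coordinates.
#' @examples
#' p <- parse_mpileup("SSU\t527\tG\t5\t..AA,\tIIIII")
#' p$sites[[1]]$position
#' @export
parse_mpileup <- function(input, n_samples = NULL) {
  lines <- if (length(input) == 1L && !grepl("\t", input) && file.exists(input))
    readLines(input) else input
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(structure(list(sites = list(), n_samples = n_samples %||% 0L),
                     class = "m7g_pileup"))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (is.null(n_samples)) {
    if ((nf[1L] - 3L) %% 3L != 0L || nf[1L] < 6L)
      stop(sprintf("line 1: expected 3 + 3*n_samples fields, got %d", nf[1L]))
    n_samples <- (nf[1L] - 3L) %/% 3L
  }
  want <- 3L + 3L * n_samples
  bad <- which(nf != want)
  if (length(bad))
    stop(sprintf("line %d: expected %d tab-separated fields, got %d",
                 bad[1L], want, nf[bad[1L]]))

  sites <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos) || pos < 1L)
      stop(sprintf("line %d: position '%s' is not a positive integer", i, f[2L]))
    samples <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      o <- 3L + 3L * (s - 1L)
      depth <- suppressWarnings(as.integer(f[o + 1L]))
      if (is.na(depth) || depth < 0L)
        stop(sprintf("line %d: sample %d depth '%s' is not a non-negative integer",
                     i, s, f[o + 1L]))
      bs <- f[o + 2L]
      qs <- f[o + 3L]
      if (depth == 0L) { bs <- ""; qs <- "" }  # "0 * *" convention
      samples[[s]] <- list(reported_depth = depth,
                           base_string = bs, quality_string = qs)
    }
    sites[[i]] <- list(reference_name = f[1L], position = pos,
                       reference_base = f[3L], samples = samples)
  }

  # warn (once) about non-monotone positions within a reference
  refs <- vapply(sites, `[[`, "", "reference_name")
  poss <- vapply(sites, `[[`, 0L, "position")
  for (r in unique(refs)) {
    p <- poss[refs == r]
    if (length(p) > 1L && any(diff(p) <= 0L)) {
      warning(sprintf("non-monotone positions within reference '%s'", r))
      break
    }
  }
  structure(list(sites = sites, n_samples = n_samples), class = "m7g_pileup")
}

#' @export
print.m7g_pileup <- function(x, ...) {
  cat(sprintf("<m7g_pileup> %d position(s), %d sample(s)\n",
              length(x$sites), x$n_samples))
  invisible(x)
}

#' Resolve a pileup base string into per-read observations
#'
#' Applies the full mpileup base-string grammar: `.`/`,` reference matches
#' (forward/reverse), letters mismatches, `^X` read starts (mapping quality
#' consumed, no observation), `$` read ends, `*` deletion placeholders
#' (consuming one quality character), `+n[seq]`/`-n[seq]` indels that
#' upgrade their anchoring (preceding) observation to insertion/deletion
#' kind, and `>`/`<` reference skips (quality slot consumed, no
#' observation). Indels carry no quality of their own, so an upgraded
#' observation keeps its anchor's error probability.
#'
#' @param base_string raw mpileup bases for one sample at one position.
#' @param quality_string matching Phred+33 quality characters.
#' @param reference_base the site's reference base.
#' @return a data frame with one row per observation: `kind` (factor:
#'   `reference_match`, `substitution`, `insertion`, `deletion`),
#'   `observed_base` (nucleotide, inserted sequence, or `-` gap symbol;
#'   `N` calls are reported as substitutions with base `N` and dropped
#'   before modelling), `strand` (`forward`/`reverse`) and `error_prob`
#'   (from [phred_to_error()]).
#' @examples
#' tokenize_bases("..A", "III", "G")
#' tokenize_bases("^].+2AG,", "II", "G")  # '.' anchor upgraded to insertion
#' @export
tokenize_bases <- function(base_string, quality_string, reference_base) {
  tk <- .tokenize_bases_cpp(base_string, quality_string, reference_base, TRUE)
  kind <- c("reference_match", "substitution", "insertion", "deletion",
            "substitution")[tk$kind + 1L]
  base <- tk$base
  base[tk$kind == 4L] <- "N"
  data.frame(
    kind = factor(kind, levels = c("reference_match", "substitution",
                                   "insertion", "deletion")),
    observed_base = base,
    strand = ifelse(tk$reverse == 1L, "reverse", "forward"),
    error_prob = phred_to_error_q(tk$qual),
    stringsAsFactors = FALSE)
}

# Fast path for the pipeline: tokenize and aggregate one sample column into
# an observation set without materialising per-read bases. N calls are
# discarded here (uninformative under the two-class model).
obs_set_from_strings <- function(base_string, quality_string, reference_base) {
  tk <- .tokenize_bases_cpp(base_string, quality_string, reference_base, FALSE)
  keep <- tk$kind != 4L
  kind <- tk$kind[keep]
  qual <- tk$qual[keep]
  if (length(kind) == 0L) return(empty_obs_set())
  # model classes: 0 match, 1 substitution, 2 indel (ins and del pooled)
  cls <- ifelse(kind == 0L, 0L, ifelse(kind == 1L, 1L, 2L))
  qual[qual > 93L] <- 93L
  key <- cls * 94L + qual
  cnt <- tabulate(key + 1L, nbins = 3L * 94L)
  nz <- which(cnt > 0L) - 1L
  obs_set_new(class = c("match", "sub", "indel")[nz %/% 94L + 1L],
              error_prob = phred_to_error_q(nz %% 94L),
              n = cnt[nz + 1L])
}
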