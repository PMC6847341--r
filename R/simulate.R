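# Synthetic multi-sample mpileup generator with planted m7G positions and a
# ground-truth ledger. The generative model factorizes the signal at a
# modified G into modification stoichiometry theta (fraction of molecules
# carrying m7G) and detection level r (per-fully-modified-molecule mutation
# yield of abasic-site read-through), so a treated read is mutated with
# probability theta * r. Mutated templates become a random non-reference
# base, or an indel with probability indel_fraction (split evenly between
# insertions and deletions). Every base call then passes a symmetric
# sequencing-error channel at rate 10^(-phred/10); control samples receive
# error only. RT-stop attrition is not simulated.

#' Simulation configuration
#'
#' Builds and validates a reproducible simulation configuration. The
#' reference sequence and any automatically planted modified positions are
#' drawn at configuration time from `seed`, so the configuration fully
#' determines the simulated output.
#'
#' @param reference_length length of the generated reference (ignored when
#'   `reference` is given).
#' @param gc_fraction GC content of the generated reference.
#' @param reference optional explicit reference sequence (single string).
#' @param reference_name name used in the pileup and FASTA output.
#' @param n_treated,n_control numbers of treated / control samples.
#' @param mean_depth Poisson mean per-sample read depth.
#' @param modified optional data frame with columns `position`, `theta`
#'   (modification stoichiometry in `[0,1]`) and `detection` (per-modified
#'   -molecule mutation yield in `[0,1]`). Every position must be a G in
#'   the reference.
#' @param n_modified alternatively, plant this many modifications on
#'   randomly chosen G positions.
#' @param theta,detection stoichiometry and detection level(s) for
#'   auto-planted sites; recycled to `n_modified`.
#' @param phred constant Phred quality assigned to every base call; the
#'   sequencing-error rate is `10^(-phred/10)` (use `Inf` for error-free
#'   reads, written as quality `~`).
#' @param indel_fraction fraction of mutated templates that present as an
#'   indel rather than a substitution.
#' @param decorate_rate rate at which read-start (`^~`) and read-end (`$`)
#'   markers are added to tokens, to exercise the full pileup grammar.
#' @param seed integer seed; the same configuration yields byte-identical
#'   output.
#' @return an object of class `m7g_sim_config`.
#' @examples
#' cfg <- sim_config(reference_length = 100, n_modified = 2,
#'                   detection = 0.1, mean_depth = 500, seed = 42)
#' cfg$modified
#' @export
sim_config <- function(reference_length = 1000L, gc_fraction = 0.5,
                       reference = NULL, reference_name = "simref",
                       n_treated = 3L, n_control = 3L, mean_depth = 2000L,
                       modified = NULL, n_modified = 0L, theta = 1,
                       detection = 0.1, phred = 30, indel_fraction = 0.2,
                       decorate_rate = 0, seed = 1L) {
  stop_if_not_scalar_prob(gc_fraction, "gc_fraction")
  stop_if_not_scalar_prob(indel_fraction, "indel_fraction")
  stop_if_not_scalar_prob(decorate_rate, "decorate_rate")
  stopifnot(n_treated >= 1L, n_control >= 1L, mean_depth > 0, phred >= 0)
  ref <- with_seed(seed, {
    if (is.null(reference)) {
      p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
      paste(sample(names(p), reference_length, replace = TRUE, prob = p),
            collapse = "")
    } else toupper(reference)
  })
  bases <- strsplit(ref, "")[[1L]]
  if (is.null(modified) && n_modified > 0L) {
    g_pos <- which(bases == "G")
    if (length(g_pos) < n_modified)
      stop("reference has fewer G positions than n_modified")
    pos <- with_seed(seed + 1L, sort(sample(g_pos, n_modified)))
    modified <- data.frame(position = pos,
                           theta = rep_len(theta, n_modified),
                           detection = rep_len(detection, n_modified))
  }
  if (is.null(modified))
    modified <- data.frame(position = integer(), theta = numeric(),
                           detection = numeric())
  if (nrow(modified)) {
    if (any(modified$theta < 0 | modified$theta > 1) ||
        any(modified$detection < 0 | modified$detection > 1))
      stop("'theta' and 'detection' must lie in [0, 1]")
    not_g <- modified$position[bases[modified$position] != "G"]
    if (length(not_g))
      stop(sprintf("modified position(s) %s are not G in the reference",
                   paste(not_g, collapse = ", ")))
  }
  structure(list(reference = ref, reference_name = reference_name,
                 n_treated = as.integer(n_treated),
                 n_control = as.integer(n_control),
                 mean_depth = mean_depth, modified = modified,
                 phred = phred, indel_fraction = indel_fraction,
                 decorate_rate = decorate_rate, seed = as.integer(seed)),
            class = "m7g_sim_config")
}

# one sample column at one position -> list(depth, bases, quals,
# n_mut_template, n_nonref)
sim_sample_column <- function(ref_base, treated, theta_r, cfg, eps, qchar) {
  n <- rpois(1L, cfg$mean_depth)
  if (n == 0L)
    return(list(depth = 0L, bases = "*", quals = "*",
                n_mut_template = 0L, n_nonref = 0L))
  others <- setdiff(c("A", "C", "G", "T"), ref_base)

  n_mut <- if (treated && theta_r > 0) rbinom(1L, n, theta_r) else 0L
  n_ind <- if (n_mut > 0L) rbinom(1L, n_mut, cfg$indel_fraction) else 0L
  n_ins <- if (n_ind > 0L) rbinom(1L, n_ind, 0.5) else 0L
  n_del <- n_ind - n_ins
  n_subt <- n_mut - n_ind
  n_ref <- n - n_mut

  # substitution templates: random non-reference base, then the symmetric
  # error channel may re-draw (possibly back to reference)
  sub_bases <- if (n_subt > 0L) sample(others, n_subt, replace = TRUE)
               else character()
  if (n_subt > 0L && eps > 0) {
    hit <- which(runif(n_subt) < eps)
    for (i in hit)
      sub_bases[i] <- sample(setdiff(c("A", "C", "G", "T"), sub_bases[i]), 1L)
  }
  # reference templates: channel errors become uniform non-reference bases
  n_err <- if (n_ref > 0L && eps > 0) rbinom(1L, n_ref, eps) else 0L
  err_bases <- if (n_err > 0L) sample(others, n_err, replace = TRUE)
               else character()
  n_match <- n_ref - n_err

  tok <- character(0)
  if (n_match > 0L) {
    fwd <- rbinom(1L, n_match, 0.5)
    tok <- c(tok, rep(".", fwd), rep(",", n_match - fwd))
  }
  sub_all <- c(sub_bases, err_bases)
  if (length(sub_all)) {
    rev <- runif(length(sub_all)) < 0.5
    tok <- c(tok, ifelse(rev, tolower(sub_all), sub_all))
  }
  if (n_ins > 0L) {
    rev <- runif(n_ins) < 0.5
    ins_base <- sample(c("A", "C", "G", "T"), n_ins, replace = TRUE)
    tok <- c(tok, paste0(ifelse(rev, ",", "."), "+1",
                         ifelse(rev, tolower(ins_base), ins_base)))
  }
  if (n_del > 0L) tok <- c(tok, rep("*", n_del))
  tok <- if (length(tok) > 1L) sample(tok) else tok
  if (cfg$decorate_rate > 0) {
    pre <- runif(n) < cfg$decorate_rate
    post <- runif(n) < cfg$decorate_rate
    tok <- paste0(ifelse(pre, "^~", ""), tok, ifelse(post, "$", ""))
  }
  # realized non-reference observations (match tokens revert sub templates)
  n_nonref <- sum(sub_all != ref_base) + n_ins + n_del
  list(depth = n, bases = paste(tok, collapse = ""),
       quals = strrep(qchar, n),
       n_mut_template = n_mut, n_nonref = as.integer(n_nonref))
}

#' Simulate a multi-sample mpileup file with ground truth
#'
#' Generates valid mpileup text (parseable by [parse_mpileup()]) for
#' `n_treated + n_control` samples (treated columns first) together with a
#' per-position, per-sample truth ledger. At error rate 0 the ledger's
#' non-reference counts match the parsed observation counts exactly.
#'
#' @param config an [sim_config()].
#' @param out_dir if non-`NULL`, write `sim.pileup`, `truth.tsv` and
#'   `reference.fa` into this directory.
#' @return a list with `lines` (mpileup text), `truth` (data frame:
#'   `position`, `reference_base`, `modified`, `theta`, `detection`,
#'   `sample`, `condition`, `depth`, `n_mut_template`, `n_nonref`),
#'   `reference`, `config`, and `paths` when written.
#' @examples
#' sim <- simulate_pileup(sim_config(reference_length = 30, mean_depth = 50,
#'                                   n_treated = 1, n_control = 1, seed = 3))
#' cat(sim$lines[1], "\n")
#' @export
simulate_pileup <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "m7g_sim_config"))
  bases <- strsplit(config$reference, "")[[1L]]
  L <- length(bases)
  S <- config$n_treated + config$n_control
  treated <- c(rep(TRUE, config$n_treated), rep(FALSE, config$n_control))
  eps <- 10^(-config$phred / 10)
  qchar <- intToUtf8(33L + min(round(config$phred), 93))
  mod_idx <- integer(L)
  mod_idx[config$modified$position] <- seq_len(nrow(config$modified))

  sim <- with_seed(config$seed + 2L, {
    lines <- character(L)
    truth <- vector("list", L)
    for (p in seq_len(L)) {
      m <- mod_idx[p]
      theta_r <- if (m > 0L)
        config$modified$theta[m] * config$modified$detection[m] else 0
      cols <- lapply(seq_len(S), function(s)
        sim_sample_column(bases[p], treated[s], theta_r, config, eps, qchar))
      lines[p] <- paste(config$reference_name, p, bases[p],
                        paste(vapply(cols, function(cc)
                          paste(cc$depth, cc$bases, cc$quals, sep = "\t"), ""),
                          collapse = "\t"),
                        sep = "\t")
      truth[[p]] <- data.frame(
        position = p, reference_base = bases[p], modified = m > 0L,
        theta = if (m > 0L) config$modified$theta[m] else 0,
        detection = if (m > 0L) config$modified$detection[m] else 0,
        sample = seq_len(S),
        condition = ifelse(treated, "treated", "control"),
        depth = vapply(cols, `[[`, 0L, "depth"),
        n_mut_template = vapply(cols, `[[`, 0L, "n_mut_template"),
        n_nonref = vapply(cols, `[[`, 0L, "n_nonref"),
        stringsAsFactors = FALSE)
    }
    list(lines = lines, truth = do.call(rbind, truth))
  })
  out <- list(lines = sim$lines, truth = sim$truth,
              reference = config$reference, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(pileup = file.path(out_dir, "sim.pileup"),
                  truth = file.path(out_dir, "truth.tsv"),
                  reference = file.path(out_dir, "reference.fa"))
    writeLines(sim$lines, paths$pileup)
    write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    dna <- Biostrings::DNAStringSet(stats::setNames(config$reference,
                                                    config$reference_name))
    Biostrings::writeXStringSet(dna, paths$reference)
    out$paths <- paths
  }
  out
}

#' Write the canonical test fixture suite
#'
#' Deterministically generates the small fixture files used by the test
#' suite: a null file (no modifications), a two-site file with detection
#' levels 0.10 and 0.05 (the magnitudes seen at the two known E. coli rRNA
#' m7G sites), an indel-rich file exercising the full pileup grammar, and
#' a file with zero-depth sample columns.
#'
#' @param dir output directory (one subdirectory per fixture).
#' @param seed integer seed; the same seed reproduces the directory tree
#'   byte-identically.
#' @return named list of fixture subdirectories, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  seed <- as.integer(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixtures <- list()

  cfg_null <- sim_config(reference_length = 200L, mean_depth = 500L,
                         n_treated = 3L, n_control = 3L, phred = 30,
                         seed = seed)
  simulate_pileup(cfg_null, file.path(dir, "null"))
  fixtures$null <- file.path(dir, "null")

  ref2 <- with_seed(seed + 10L,
    paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE), collapse = ""))
  g_pos <- which(strsplit(ref2, "")[[1L]] == "G")
  two <- with_seed(seed + 11L, sort(sample(g_pos, 2L)))
  cfg_two <- sim_config(reference = ref2, mean_depth = 2000L,
                        n_treated = 3L, n_control = 3L, phred = 30,
                        modified = data.frame(position = two, theta = 1,
                                              detection = c(0.10, 0.05)),
                        seed = seed + 12L)
  simulate_pileup(cfg_two, file.path(dir, "twosite"))
  fixtures$twosite <- file.path(dir, "twosite")

  cfg_ind <- sim_config(reference_length = 100L, mean_depth = 300L,
                        n_treated = 2L, n_control = 2L, n_modified = 5L,
                        theta = 1, detection = 0.2, indel_fraction = 0.8,
                        decorate_rate = 0.1, phred = Inf, seed = seed + 20L)
  simulate_pileup(cfg_ind, file.path(dir, "indelrich"))
  fixtures$indelrich <- file.path(dir, "indelrich")

  cfg_zd <- sim_config(reference_length = 50L, mean_depth = 100L,
                       n_treated = 1L, n_control = 1L, phred = 30,
                       seed = seed + 30L)
  zd <- simulate_pileup(cfg_zd)
  # force the control column of the first five positions to zero depth
  for (p in 1:5) {
    f <- strsplit(zd$lines[p], "\t", fixed = TRUE)[[1L]]
    f[7:9] <- c("0", "*", "*")
    zd$lines[p] <- paste(f, collapse = "\t")
    sel <- zd$truth$position == p & zd$truth$sample == 2L
    zd$truth$depth[sel] <- 0L
    zd$truth$n_mut_template[sel] <- 0L
    zd$truth$n_nonref[sel] <- 0L
  }
  dir.create(file.path(dir, "zerodepth"), showWarnings = FALSE)
  writeLines(zd$lines, file.path(dir, "zerodepth", "sim.pileup"))
  write.table(zd$truth, file.path(dir, "zerodepth", "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fixtures$zerodepth <- file.path(dir, "zerodepth")

  invisible(fixtures)
}
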