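---
title: "Statistical methods for m7G mutational-profiling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for m7G mutational-profiling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m7gmap)
```

## The measurement model

N7-methylguanosine carries its methyl group on the Hoogsteen edge and does
not block reverse transcription, but mild NaBH4 reduction converts m7G
specifically into an abasic site. Reverse transcriptases read through
abasic sites with near-random nucleotide incorporation, so after treatment
a modified G appears in sequencing reads as a mixture of mismatches,
insertions and deletions, while mock-treated control libraries show only
the background of sequencing and alignment error. The analysis problem is
therefore: at each reference position, estimate the fraction of cDNA
molecules derived from a "mutated" (abasic) template in each sample group,
and ask whether the treated rate exceeds the control rate by more than
error and noise can explain.

Two biological quantities factor into the observable signal and are kept
separate throughout the package:

* **stoichiometry** `theta` — the fraction of RNA molecules carrying the
  modification at a position (what a mixing experiment titrates);
* **detection level** `r` — the per-fully-modified-molecule mutation
  yield, i.e. how often read-through of an abasic site actually produces
  a non-reference base call. Detection levels vary between positions
  because flanking sequence influences both reduction and read-through;
  observed values at true m7G sites range from below 1% to about 25%.

A treated read at a modified position is mutated with probability
`theta * r`; controls carry background only.

## Per-read likelihood and EM estimation

Each aligned observation at a site is reduced to a class (reference
match, substitution, or indel) and an error probability `e` from its
Phred quality (`e = 10^(-Q/10)`, capped at 0.75 to keep the two classes
identifiable). Conditional on the template class, emission probabilities
are:

| observation  | P(o given reference) | P(o given mutated) |
|--------------|----------------------|--------------------|
| match        | 1 − e                | e/3                |
| substitution | e                    | 1 − e/3            |
| indel        | e                    | 1 − e              |

The `e/3` factor is the uniform-miscall convention on the four-letter
channel: a sequencing error on a mutated template reverts to the
reference base a third of the time. Indels are not a four-letter channel,
so no `/3` is applied there. All non-reference identities are pooled into
a single mutated class because abasic read-through produces every
mutation type; the per-identity breakdown carries little information
about the modification itself.

The site log-likelihood for mutated-template fraction `f` is
`sum_i log[f P(o_i|mut) + (1−f) P(o_i|ref)]`, maximized by EM: the E-step
computes each read's posterior probability of originating from a mutated
template, and the M-step averages them. The problem is one-dimensional
and well behaved; we initialize at the raw mutated fraction, iterate to
`|Δf| < 1e-8` with a 200-iteration cap, and the log-likelihood is
non-decreasing by construction. Two limits anchor the estimator: with all
`e = 0`, `f̂ = k/n` exactly; and mismatch-free (or mismatch-only) data
sit at the boundary optimum 0 (or 1), which is returned directly. With
identical reads aggregated by (class, quality), one EM iteration costs a
handful of floating-point operations regardless of depth.

## Likelihood-ratio tests

Two chi-square LRTs are computed per position:

* **between conditions** — H0: one shared `f` for the pooled
  treated+control reads; H1: one `f` per condition, each fitted on its
  pooled replicates (pooling is the maximum-likelihood fit under the
  shared-`f` hypothesis). One degree of freedom. The test is two-sided;
  directionality enters only at calling time through the effect-size
  cut-off.
* **within a condition** — H0: replicates share `f`; H1: one `f` per
  replicate; `k − 1` degrees of freedom. This is the replicate-consistency
  screen: a position whose replicates disagree strongly is unreliable
  whatever its between-condition p-value.

P-values are floored at 1e-320 and reported alongside `-10 log10(p)`
capped at 3200, which keeps the tables printable while preserving the
ordering of extremely significant sites (calling uses thresholds as small
as 1e-50).

When the true mutation rate is zero and the per-read error probabilities
are correctly specified, the MLE sits at the boundary `f = 0` and the
plain chi-square reference makes both tests *conservative* — fewer than
the nominal fraction of null sites reach any given significance level. We
keep the plain chi-square rather than a boundary mixture: conservatism is
the safe direction for a screen whose calling threshold is many orders of
magnitude below any calibration regime. Calibration in the usual sense
applies under the tests' own null hypothesis — equal rates with an
interior shared frequency, e.g. a genuine shared background mutation
process — where simulated p-value distributions are close to uniform
(the type-I fraction at 0.05 is within a few tenths of a percent of
nominal for Q30-magnitude backgrounds at depth 1000 per group). The same
view drives the power module: its Monte-Carlo trials treat the background
as a true shared rate absorbed by the free shared-frequency parameter,
rather than as quality-annotated error, so estimated power at
`theta = 0` equals the significance level.

## Filters and calling

The per-position filters mirror the published analysis and are applied
as independent flags (order-independent):

* combined sequencing depth strictly greater than 1500 across all
  samples (500 in single-replicate analyses such as the rRNA runs);
* unweighted mean of the per-replicate control frequencies below 1%;
* within-replicate heterogeneity p-value at least 1e-5 in both
  conditions;
* positions where a condition has no observations are marked untestable.

Candidates among passing positions require a mutation-rate difference
`Δ = f̂_treated − f̂_control ≥ 0.5%` and a between-condition p-value
below 1e-50. Calling is restricted to reference-base G by default since
m7G occurs on G, but the full table reports every position: other
NaBH4-sensitive modifications (m1A, dihydrouridine, ac4C) leave similar
signatures and are visible with `g_only = FALSE`. All thresholds are
arguments of `calling_thresholds()` and CLI flags.

Coordinates are 1-based mpileup-native everywhere; only the optional BED
export converts to 0-based half-open.

## What the simulator emulates — and what it does not

`simulate_pileup()` generates multi-sample mpileup text directly at the
pileup level: per-sample depths are Poisson; treated reads at a modified
position are mutated with probability `theta * r`, presenting as a
uniform non-reference base or (with configurable probability, default
0.2) an insertion or deletion; every base call then passes a symmetric
error channel at the configured Phred rate, in controls as in treated
samples. Deletions are emitted as `*` placeholders and insertions as
`+1N` tokens on their anchor; read-start/end decorations can be switched
on to exercise the full grammar. A truth ledger records planted and
realized counts per position and sample, and at error rate 0 the parsed
non-reference counts equal the ledger exactly — the round-trip that
anchors the parser tests.

Deliberately not simulated: read-level effects (alignment error
correlated along reads, soft-clipping, BAQ), RT-stop attrition at abasic
sites (small for the read-through enzymes the protocol uses), PCR
duplicate structure, and coverage heterogeneity along transcripts.
Passing tests therefore demonstrate the statistical machinery under the
model's own assumptions, not robustness to alignment artefacts — which
is also why the parser is separately validated against samtools output
on constructed alignments.

Default conditions used by the test suite follow the study design the
package targets: three treated and three control replicates at a mean
depth of 2000 reads per sample, Q30 base qualities, detection levels
between 0.05 and 0.25 at fully modified sites, and a 10 kb reference for
the end-to-end recovery run (about 2500 G positions). The mixing
analogue plants stoichiometries {0, 0.25, 0.5, 0.75, 1} at detection
level 0.1 and depth 5000, where the mean rate difference is linear in
`theta` with slope ≈ `r`. These sizes keep the full suite to a few
minutes on one CPU while leaving Monte-Carlo error well below every
asserted margin.

## Power analysis

`estimate_power()` profiles the between-condition LRT on a grid of
stoichiometry and detection level at given group depths: treated counts
are Binomial(depth, `theta*r` + background), control counts
Binomial(depth, background), and power is the fraction of trials with
p below `alpha` (default 1e-5, the threshold used for the
single-position claims the method was applied to; the calling threshold
1e-50 is deliberately far stricter for transcriptome-wide screens).
Because the p-value depends only on the count pair, trials are
deduplicated before testing, which makes dense grids cheap. An exact
binomial-tail oracle (brute-force inversion of the test at zero error
and empty controls) pins the implementation in tests. The default
background rate is 0.001 (Q30 magnitude); it is a visible knob because
published power statements depend on the background assumed.

## Preprocessing

Libraries built with a 7-nt random barcode are handled by
`extract_barcodes()` (barcode into the read name and a sidecar table,
nine bases trimmed in total, reads with N in the barcode discarded) and
`collapse_duplicates()`, which keeps one read per (reference, leftmost
position, strand, barcode) group. Strand is part of the key: leftmost
coordinates of opposite-strand reads rarely coincide, but when they do
the reads are distinct molecules. Within a group the lexicographically
smallest read id is retained, making the operation deterministic and
order-independent (and hence idempotent); which duplicate survives is
immaterial downstream since only counts enter the model. Small-RNA
libraries, which lack the barcode, skip both steps.

## Numerical and design notes

* Error probabilities are capped at 0.75; beyond that the two emission
  classes lose identifiability and Q0 bases would otherwise invert the
  model.
* Indel tokens in mpileup carry no quality character; an indel-upgraded
  observation inherits its anchor base's error probability — the only
  per-read proxy available.
* `N` base calls are discarded before modelling (uninformative under a
  two-class model); reference skips (`>`/`<`) occupy depth slots but
  yield no observation.
* The depth filter is strict ("higher than 1500"), so a combined depth
  of exactly 1500 is flagged low-depth.
* The control-rate filter averages per-replicate estimates unweighted;
  with balanced depths this differs from the pooled estimate by less
  than 1e-3.
* Empty replicates are dropped from the within-condition test and its
  degrees of freedom; with fewer than two contributing replicates the
  test is skipped and the position is screened by the between-condition
  test alone, as in single-replicate rRNA analyses.
* Ties and degenerate inputs return typed markers (`NA` estimates,
  untestable flags) rather than errors, so one bad column never aborts a
  transcriptome-scale run.

## Known limitations

The error model treats reads as independent Bernoulli observations;
correlated alignment error (e.g. around homopolymers) can defeat the
per-read error absorption and is only partly mitigated by upstream BAQ.
Base qualities are consumed as given — no re-estimation from data is
attempted. Detection levels confound stoichiometry in a single
experiment (`theta * r` is the only identified product), which is why
mixing designs or orthogonal validation are needed to read stoichiometry
off a rate difference. Finally, the simulator's idealizations listed
above mean that real-data false-positive rates depend on mapping quality
in ways no desk-scale simulation captures.
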