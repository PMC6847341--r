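# Volcano-style tables and figures from a results table: mutation-rate
# difference versus -10*log10(p), and per-reference coverage / significance
# tracks. Tables are the authoritative artifact; plots render headlessly
# with deterministic layout.

#' Volcano table
#'
#' One row per filtered position with the effect size (`delta`), the
#' capped `-10*log10(p)` of the between-condition test, and the `called`
#' flag per the calling rules.
#'
#' @param results results table from [analyze_pileup()] (or any table with
#'   columns `reference_name`, `position`, `delta`, `neg10log10_p`,
#'   `passed`).
#' @param thresholds a [calling_thresholds()]; used to (re)compute
#'   `called` when the column is absent.
#' @return data frame with columns `reference_name`, `position`, `delta`,
#'   `neg10log10_p`, `called`.
#' @export
volcano_table <- function(results, thresholds = calling_thresholds()) {
  need <- c("reference_name", "position", "delta", "neg10log10_p")
  missing <- setdiff(need, names(results))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  called <- if ("called" %in% names(results)) results$called
            else called_flag(results, thresholds)
  out <- results[, need, drop = FALSE]
  out$called <- called
  rownames(out) <- NULL
  out
}

#' Volcano plot of mutation-rate difference versus significance
#'
#' @param results results or volcano table.
#' @param thresholds a [calling_thresholds()]; drawn as dashed cut-off
#'   lines.
#' @param annotations optional data frame (`position`, `label`) of
#'   positions to label.
#' @return a ggplot object.
#' @export
plot_volcano <- function(results, thresholds = calling_thresholds(),
                         annotations = NULL) {
  vt <- volcano_table(results, thresholds)
  p <- ggplot2::ggplot(vt, ggplot2::aes(x = .data$delta,
                                        y = .data$neg10log10_p,
                                        colour = .data$called)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = thresholds$min_delta,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -10 * log10(thresholds$max_between_p),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mutation rate difference (treated - control)",
                  y = "-10*log10(P)", colour = "called") +
    ggplot2::theme_bw()
  if (!is.null(annotations)) {
    ann <- merge(vt, annotations, by = "position")
    p <- p + ggplot2::geom_text(
      data = ann, ggplot2::aes(label = .data$label),
      colour = "black", vjust = -0.6, size = 3)
  }
  p
}

#' Per-reference coverage / significance track
#'
#' @param results results table.
#' @param reference name of the reference to plot (default: first).
#' @param what `"depth"` (combined sequencing depth) or `"p"`
#'   (`-10*log10` between-condition p-value), by position.
#' @return a ggplot object.
#' @export
plot_track <- function(results, reference = NULL,
                       what = c("depth", "p")) {
  what <- match.arg(what)
  reference <- reference %||% results$reference_name[1L]
  d <- results[results$reference_name == reference, , drop = FALSE]
  if (what == "depth") {
    d$y <- d$depth_treated + d$depth_control
    ylab <- "combined depth"
  } else {
    d$y <- d$neg10log10_p
    ylab <- "-10*log10(P)"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$y)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = sprintf("position on %s", reference), y = ylab) +
    ggplot2::theme_bw()
}
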