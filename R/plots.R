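# ggplot2 displays: per-CpG methylation profiles, read-class bars, and the
# per-read epiallele (lollipop-style) matrix.

#' Per-CpG methylation profile plot
#'
#' One panel per amplicon; points/lines at each CpG's methylation
#' percentage, per allele where available. Imprinted regions are expected
#' to track ~50%, controls <10% or >90%.
#'
#' @param cpg_table [build_table()] output (or `tidy()` of a result).
#' @return A ggplot object.
#' @export
plot_cpg_profile <- function(cpg_table) {
  dat <- filter(cpg_table, !is.na(.data$methylation_pct))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$offset,
                                    y = .data$methylation_pct,
                                    colour = .data$allele)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~amplicon, scales = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "CpG offset in amplicon (bp)",
                  y = "Methylation (%)", colour = "Allele") +
    ggplot2::theme_bw()
}

#' Read-class composition plot
#'
#' Stacked fractions of fully methylated, fully unmethylated and
#' intermediate reads per amplicon; an imprinted region shows an ~50/50
#' methylated/unmethylated split.
#'
#' @param regions [region_summary()] output.
#' @return A ggplot object.
#' @export
plot_read_classes <- function(regions) {
  long <- tidyr::pivot_longer(
    select(regions, "amplicon", "frac_methylated", "frac_unmethylated",
           "frac_intermediate"),
    cols = -"amplicon", names_to = "class", names_prefix = "frac_",
    values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$amplicon,
                                     y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of reads", fill = "Read class") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-read epiallele matrix ("lollipop") plot
#'
#' Rows are individual deduplicated reads, columns the amplicon's CpGs;
#' filled circles are methylated calls, open circles unmethylated.
#'
#' @param aligned Deduplicated aligned reads for one amplicon.
#' @param amplicon_name Amplicon to draw.
#' @param max_reads Downsample cap on rows drawn.
#' @return A ggplot object.
#' @export
plot_read_matrix <- function(aligned, amplicon_name, max_reads = 100L) {
  sub <- filter(aligned, .data$amplicon == amplicon_name)
  if (nrow(sub) == 0L) abort(sprintf("No reads for amplicon '%s'.", amplicon_name))
  sub <- head(sub, max_reads)
  dat <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    v <- sub$cpg_calls[[i]]
    tibble(read = i, cpg = seq_along(v), call = v)
  }) %>% filter(!is.na(.data$call))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cpg, y = .data$read,
                                    fill = factor(.data$call))) +
    ggplot2::geom_point(shape = 21, size = 2) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               labels = c(`0` = "unmethylated",
                                          `1` = "methylated")) +
    ggplot2::labs(x = "CpG index", y = "Read", fill = NULL,
                  title = amplicon_name) +
    ggplot2::theme_bw()
}

#' @method autoplot ampmeth_result
#' @export
autoplot.ampmeth_result <- function(object, type = c("profile", "classes"),
                                    ...) {
  type <- match.arg(type)
  if (type == "profile") plot_cpg_profile(object$cpg_table)
  else plot_read_classes(object$regions)
}
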