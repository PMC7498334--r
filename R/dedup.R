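# Dedup module: collapse PCR duplicates by (amplicon, start, UMI), the
# UMI-aware analogue of barcode-aware bisulfite deduplication. Exact UMI
# matching by default; optional 1-mismatch collapsing for real data.

umi_key_check <- function(aligned) {
  bad <- is.na(aligned$umi) | !nzchar(aligned$umi)
  if (any(bad)) {
    abort(sprintf("Read(s) lacking a UMI: %s.",
                  paste(head(aligned$id[bad], 3L), collapse = ", ")))
  }
}

# Collapse UMIs within one (amplicon, start) group so that UMIs within
# Hamming distance 1 of a more frequent UMI adopt it (directional-style).
collapse_umis_1mm <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  canon <- setNames(names(tab), names(tab))
  us <- names(tab)
  if (length(us) > 1L) {
    split_us <- strsplit(us, "", fixed = TRUE)
    for (i in seq_along(us)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (sum(split_us[[i]] != split_us[[j]]) == 1L) {
          canon[us[i]] <- canon[us[j]]
          break
        }
      }
    }
  }
  unname(canon[umis])
}

#' Collapse PCR duplicates by UMI and position
#'
#' Reads are grouped by (amplicon, start offset, UMI) — the targeted strand
#' is a property of the amplicon, so it is implicit in the key — and exactly
#' one representative per group is kept: the first after a stable sort by
#' read id, which is deterministic across runs and platforms. The
#' duplication rate is `100 * (1 - unique/total)`.
#'
#' @param aligned Aligned read tibble (must carry `umi`, `amplicon`, `start`).
#' @param umi_mismatch `0` (exact, default) or `1` to additionally collapse
#'   UMIs at Hamming distance 1 within a position group (for real data with
#'   UMI sequencing errors).
#' @return List: `unique` — representative reads; `stats` — per-amplicon
#'   tibble (`amplicon`, `total`, `unique`, `duplication_pct`) with a
#'   global row labelled `"_all_"`.
#' @examples
#' # three reads sharing one key collapse to one (rate 66.7%)
#' @export
deduplicate <- function(aligned, umi_mismatch = 0L) {
  umi_key_check(aligned)
  x <- aligned
  x$.umi_eff <- x$umi
  if (umi_mismatch > 0L && nrow(x) > 0L) {
    x <- x %>%
      group_by(.data$amplicon, .data$start) %>%
      mutate(.umi_eff = collapse_umis_1mm(.data$umi)) %>%
      ungroup()
  }
  x <- arrange(x, .data$amplicon, .data$start, .data$.umi_eff, .data$id)
  key <- paste(x$amplicon, x$start, x$.umi_eff, sep = "\r")
  keep <- !duplicated(key)
  uniq <- select(x[keep, , drop = FALSE], -".umi_eff")

  per <- x %>%
    group_by(amplicon = .data$amplicon) %>%
    summarise(total = n(),
              unique = dplyr::n_distinct(paste(.data$start, .data$.umi_eff)),
              .groups = "drop")
  all_row <- tibble(amplicon = "_all_", total = nrow(x),
                    unique = sum(keep))
  stats <- bind_rows(per, all_row) %>%
    mutate(duplication_pct = 100 * (1 - .data$unique / .data$total))
  list(unique = uniq, stats = stats)
}

#' Methylation shift between pre- and post-deduplication read sets
#'
#' QC metric: signed percentage-point difference in per-amplicon mean
#' methylation before vs after deduplication. A well-behaved amplicon shows
#' little or no shift; a large shift indicates amplification bias toward
#' the methylated or unmethylated allele. No filtering is applied.
#'
#' @param before,after Aligned read tibbles quantified on the same amplicons
#'   (typically the input and `$unique` output of [deduplicate()]).
#' @param panel Amplicon panel.
#' @return Tibble: `amplicon`, `mean_pct_before`, `mean_pct_after`,
#'   `delta_pct` (after minus before).
#' @export
methylation_shift_check <- function(before, after, panel) {
  amps_b <- sort(unique(before$amplicon))
  amps_a <- sort(unique(after$amplicon))
  if (!identical(amps_b, amps_a)) {
    abort("`before` and `after` cover different amplicon sets.")
  }
  mean_tab <- function(x, col) {
    build_table(x, panel) %>%
      filter(.data$amplicon %in% amps_b) %>%
      group_by(amplicon = .data$amplicon) %>%
      summarise({{ col }} := mean(.data$methylation_pct, na.rm = TRUE),
                .groups = "drop")
  }
  left_join(mean_tab(before, mean_pct_before),
            mean_tab(after, mean_pct_after), by = "amplicon") %>%
    mutate(delta_pct = .data$mean_pct_after - .data$mean_pct_before)
}
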