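# Allele-splitting module: assign deduplicated reads to parental strains
# via usable SNPs, with conversion-aware base matching.

# Bases an allele can legitimately present on the read, in top-strand
# coordinates: on a top-strand amplicon an allele C may appear as C or T;
# on a bottom-strand amplicon an allele G may appear as G or A.
allele_match <- function(observed, allele, targeted_strand) {
  observed %in% snp_observable_bases(allele, targeted_strand)
}

#' Genotype one aligned read from its SNP observations
#'
#' Each covered usable SNP votes for the allele its observed base matches
#' under conversion-aware comparison. If all votes agree the read gets that
#' strain label; conflicting votes yield `unassigned` with `conflict =
#' TRUE`; no informative observation yields `unassigned`.
#'
#' @param aligned_read One-row aligned tibble (with `snp_obs` filled).
#' @param amplicon The matching panel row.
#' @return One-row tibble: `id`, `label`, `n_informative`, `conflict`.
#' @export
genotype_read <- function(aligned_read, amplicon) {
  stopifnot(nrow(aligned_read) == 1L)
  snps <- amplicon$snps[[1L]]
  obs <- aligned_read$snp_obs[[1L]]
  strand <- amplicon$targeted_strand
  votes <- character(0)
  for (i in seq_len(nrow(obs))) {
    s <- snps[snps$offset == obs$offset[i], ]
    if (nrow(s) != 1L || !isTRUE(s$usable)) next
    ma <- allele_match(obs$base[i], s$allele_a, strand)
    mb <- allele_match(obs$base[i], s$allele_b, strand)
    if (ma && !mb) votes <- c(votes, s$label_a)
    if (mb && !ma) votes <- c(votes, s$label_b)
  }
  if (length(votes) == 0L) {
    return(tibble(id = aligned_read$id, label = "unassigned",
                  n_informative = 0L, conflict = FALSE))
  }
  if (length(unique(votes)) > 1L) {
    return(tibble(id = aligned_read$id, label = "unassigned",
                  n_informative = length(votes), conflict = TRUE))
  }
  tibble(id = aligned_read$id, label = votes[1L],
         n_informative = length(votes), conflict = FALSE)
}

#' Genotype a whole aligned read set
#'
#' @param aligned Aligned read tibble.
#' @param panel Amplicon panel.
#' @return Tibble: `id`, `amplicon`, `label`, `n_informative`, `conflict`.
#' @export
genotype_reads <- function(aligned, panel) {
  if (nrow(aligned) == 0L) {
    return(tibble(id = character(0), amplicon = character(0),
                  label = character(0), n_informative = integer(0),
                  conflict = logical(0)))
  }
  purrr::map_dfr(seq_len(nrow(aligned)), function(i) {
    amp <- panel[panel$name == aligned$amplicon[i], ]
    mutate(genotype_read(aligned[i, ], amp), amplicon = amp$name,
           .after = "id")
  })
}

#' Per-amplicon allele split percentages
#'
#' @param assignments Tibble from [genotype_reads()] (at least one read).
#' @return Tibble per amplicon: `amplicon`, `label_a`, `label_b`,
#'   `pct_a`, `pct_b`, `pct_unassigned`, `n_reads`. Percentages sum to 100
#'   within rounding; amplicons without usable SNPs report 100% unassigned.
#' @export
split_counts <- function(assignments) {
  if (nrow(assignments) == 0L) abort("No assignments to summarise.")
  assignments %>%
    group_by(amplicon = .data$amplicon) %>%
    dplyr::group_modify(function(.x, .key) {
      labs <- sort(setdiff(unique(.x$label), "unassigned"))
      n <- nrow(.x)
      tibble(
        label_a = if (length(labs) >= 1L) labs[1L] else NA_character_,
        label_b = if (length(labs) >= 2L) labs[2L] else NA_character_,
        pct_a = 100 * sum(.x$label %in% labs[1L]) / n,
        pct_b = 100 * sum(.x$label %in% labs[2L]) / n,
        pct_unassigned = 100 * sum(.x$label == "unassigned") / n,
        n_reads = n)
    }) %>%
    ungroup()
}
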