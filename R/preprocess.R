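# Preprocess module: move the in-line UMI from read 2 into both read IDs,
# then quality- and adapter-trim. Trimming is a deliberately minimal
# re-implementation (trailing-quality run + single 3' adapter per mate);
# simulated reads are clean, and this stage exists so real data behaves
# plausibly.

#' Extract the in-line UMI from read 2 into both read IDs
#'
#' The first `umi_len` bases of read 2 are removed (sequence and quality)
#' and appended to both mates' IDs after a `':'` separator; downstream
#' stages treat the final colon-delimited ID field as the UMI. Pairs whose
#' read 2 is not longer than the UMI are rejected and counted.
#'
#' @param reads Read tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param umi_len UMI length (8 for this assay).
#' @return List: `reads` — tagged tibble with an added `umi` column and
#'   shortened read 2; `n_rejected` — pairs dropped for short read 2.
#' @examples
#' r <- tibble::tibble(id = "r1", seq1 = "ACGT", qual1 = "FFFF",
#'                     seq2 = "ACGTACGTTTTT", qual2 = strrep("F", 12))
#' extract_umi(r)$reads$umi
#' @export
extract_umi <- function(reads, umi_len = 8L) {
  ok <- nchar(reads$seq2) > umi_len
  rejected <- sum(!ok)
  out <- reads[ok, , drop = FALSE]
  umi <- substr(out$seq2, 1L, umi_len)
  out <- mutate(out,
    umi = umi,
    id = paste0(.data$id, ":", umi),
    seq2 = substr(.data$seq2, umi_len + 1L, nchar(.data$seq2)),
    qual2 = substr(.data$qual2, umi_len + 1L, nchar(.data$qual2)))
  list(reads = as_tibble(out), n_rejected = rejected)
}

phred_scores <- function(qual) utf8ToInt(qual) - 33L

# Length to keep after removing the trailing run of bases below `cutoff`.
quality_keep_len <- function(qual, cutoff) {
  q <- phred_scores(qual)
  n <- length(q)
  keep <- n
  while (keep > 0L && q[keep] < cutoff) keep <- keep - 1L
  keep
}

# 3' adapter search: longest read suffix matching a prefix of the adapter
# with >= `min_overlap` bases and <= `max_mismatch_frac` mismatches.
# Returns the keep-length (position before the adapter starts).
adapter_keep_len <- function(seq, adapter, min_overlap = 3L,
                             max_mismatch_frac = 0.1) {
  n <- nchar(seq)
  a <- seq_chars(adapter)
  s <- seq_chars(seq)
  max_o <- min(n, length(a))
  for (o in rev(seq_len(max_o))) {
    if (o < min_overlap) break
    mism <- sum(s[(n - o + 1L):n] != a[1:o])
    if (mism <= floor(max_mismatch_frac * o)) return(n - o)
  }
  n
}

#' Quality- and adapter-trim tagged read pairs
#'
#' 3' bases below the Phred cutoff are removed as a trailing run, then a 3'
#' adapter match (at least 3 bases overlap, at most 10% mismatches) is cut.
#' Pairs with either mate shorter than `min_len` afterwards are discarded
#' and counted. UMI suffixes in the IDs are never touched.
#'
#' @param tagged Tagged read tibble from [extract_umi()] (`$reads`).
#' @param quality_cutoff Phred cutoff for 3' quality trimming.
#' @param adapters Character vector of 3' adapter sequences searched in both
#'   mates; defaults to the two library tails.
#' @param min_len Minimum surviving mate length.
#' @return List: `reads` — trimmed tibble; `n_discarded` — dropped pairs;
#'   `report` — one-row tibble of counts.
#' @export
trim_pairs <- function(tagged, quality_cutoff = 20L,
                       adapters = unlist(primer_tails()[c("fwd_tail",
                                                          "rev_tail_constant")]),
                       min_len = 20L) {
  trim_one <- function(seq, qual) {
    keep <- quality_keep_len(qual, quality_cutoff)
    seq <- substr(seq, 1L, keep); qual <- substr(qual, 1L, keep)
    for (ad in adapters) {
      if (nchar(seq) == 0L) break
      keep <- adapter_keep_len(seq, ad)
      seq <- substr(seq, 1L, keep); qual <- substr(qual, 1L, keep)
    }
    c(seq, qual)
  }
  n_in <- nrow(tagged)
  out <- tagged
  for (i in seq_len(n_in)) {
    t1 <- trim_one(out$seq1[i], out$qual1[i])
    t2 <- trim_one(out$seq2[i], out$qual2[i])
    out$seq1[i] <- t1[1]; out$qual1[i] <- t1[2]
    out$seq2[i] <- t2[1]; out$qual2[i] <- t2[2]
  }
  keep <- nchar(out$seq1) >= min_len & nchar(out$seq2) >= min_len
  discarded <- sum(!keep)
  list(reads = as_tibble(out[keep, , drop = FALSE]),
       n_discarded = discarded,
       report = tibble(input_pairs = n_in, kept = sum(keep),
                       discarded_short = discarded))
}
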