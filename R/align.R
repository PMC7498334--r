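# Align module: amplicon assignment and per-CpG / SNP base calling in
# three-letter bisulfite space. Alignment is ungapped: amplicons are
# primer-defined and reads start at the primer, so placement is anchored at
# offset 0 on the targeted strand; indel-bearing reads simply fail the
# anchor and are reported as unassigned.

collapse_three_letter <- function(x) gsub("C", "T", x, fixed = TRUE)

# Internal per-panel cache of demultiplexing anchors.
panel_anchors <- function(panel, anchor_len) {
  vapply(seq_len(nrow(panel)), function(i) {
    amplicon_anchor(panel$ref_seq[i], panel$targeted_strand[i], anchor_len)
  }, character(1))
}

#' Assign read pairs to panel amplicons
#'
#' Read 1's first `anchor_len` bases are compared in three-letter space
#' (C/T collapsed, i.e. methylation-blind) against each amplicon's
#' bisulfite-converted targeted-strand prefix. The best amplicon wins only
#' if its mismatch fraction is at most `max_mismatch_frac` and it beats the
#' runner-up by at least `tie_margin` mismatches; otherwise the pair is
#' `NA` (unassigned).
#'
#' @param tagged Tagged read tibble ([extract_umi()] / [trim_pairs()]).
#' @param panel Amplicon panel.
#' @param max_mismatch_frac Maximum tolerated anchor mismatch fraction.
#' @param anchor_len Anchor length in bases.
#' @param tie_margin Minimum mismatch gap to the runner-up.
#' @return The tibble with added `amplicon` (character, `NA` = unassigned)
#'   and `anchor_mismatches` columns.
#' @export
assign_amplicons <- function(tagged, panel, max_mismatch_frac = 0.1,
                             anchor_len = 30L, tie_margin = 2L) {
  if (nrow(panel) == 0L) abort("Panel is empty.")
  anchors <- collapse_three_letter(panel_anchors(panel, anchor_len))
  anchor_mat <- t(vapply(anchors, function(a) seq_chars(a)[seq_len(anchor_len)],
                         character(anchor_len)))
  n <- nrow(tagged)
  amplicon <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- collapse_three_letter(substr(tagged$seq1[i], 1L, anchor_len))
    rc <- seq_chars(r)
    if (length(rc) < anchor_len) next
    d <- rowSums(sweep(anchor_mat, 2L, rc, FUN = "!="))
    best <- which.min(d)
    runner <- if (nrow(panel) > 1L) min(d[-best]) else Inf
    if (d[best] <= max_mismatch_frac * anchor_len &&
        runner - d[best] >= tie_margin) {
      amplicon[i] <- panel$name[best]
      mism[i] <- as.integer(d[best])
    }
  }
  mutate(tagged, amplicon = amplicon, anchor_mismatches = mism)
}

# Observed targeted-strand base vector for one pair: read 2 (reverse-
# complemented, anchored at the amplicon 3' end) laid down first, then
# read 1 (anchored at offset 0) on top — read 1 wins in the overlap.
observed_target_vector <- function(seq1, seq2, len) {
  obs <- rep(NA_character_, len)
  r2rc <- seq_chars(revcomp(seq2))
  n2 <- length(r2rc)
  if (n2 > 0L) {
    from <- max(1L, len - n2 + 1L)
    obs[from:len] <- r2rc[(n2 - (len - from)):n2]
  }
  r1 <- seq_chars(seq1)
  n1 <- min(length(r1), len)
  if (n1 > 0L) obs[1:n1] <- r1[1:n1]
  obs
}

# Positions (1-based, targeted-strand coords) of non-CpG, non-SNP reference
# cytosines on the targeted strand — the conversion-efficiency denominators.
noncpg_c_positions <- function(amplicon) {
  len <- nchar(amplicon$ref_seq)
  target_ref <- if (amplicon$targeted_strand == "top") amplicon$ref_seq
    else revcomp(amplicon$ref_seq)
  ch <- seq_chars(target_ref)
  cpg_pos <- cpg_positions_on_target(amplicon$cpg_offsets[[1L]],
                                     amplicon$targeted_strand, len) + 1L
  snp_top <- amplicon$snps[[1L]]$offset
  snp_pos <- if (amplicon$targeted_strand == "top") snp_top + 1L
    else len - snp_top
  setdiff(which(ch == "C"), c(cpg_pos, snp_pos))
}

#' Call per-CpG methylation for one assigned read pair
#'
#' Places the pair ungapped on the amplicon's converted targeted strand and
#' reads each CpG cytosine: observed C means methylated (protected), T
#' means converted (unmethylated), anything else — including positions not
#' covered by either mate — is unknown. Where the mates overlap, read 1's
#' call is used. Non-CpG reference cytosines observed as C count toward
#' `unconverted_noncpg` (incomplete conversion); observed as T toward the
#' converted total.
#'
#' @param pair One-row tagged read tibble (must carry `umi`).
#' @param amplicon One panel row the pair is assigned to.
#' @param max_mismatch_frac Sanity bound on the anchor mismatch fraction;
#'   exceeding it errors (the pair is not assignable to this amplicon).
#' @return One-row tibble: `id`, `umi`, `amplicon`, `start`, `cpg_calls`
#'   (list; 1 = methylated, 0 = unmethylated, `NA` = unknown), `snp_obs`
#'   (list-tibble, filled by [observe_snps()]), `mismatches` (three-letter
#'   space, SNP sites excluded), `unconverted_noncpg`, `noncpg_total`, and
#'   the internal `obs_target` vector.
#' @export
call_cpgs <- function(pair, amplicon, max_mismatch_frac = 0.1) {
  stopifnot(nrow(pair) == 1L, nrow(amplicon) == 1L)
  len <- nchar(amplicon$ref_seq)
  anchor <- collapse_three_letter(amplicon_anchor(amplicon$ref_seq,
                                                  amplicon$targeted_strand))
  read_anchor <- collapse_three_letter(substr(pair$seq1, 1L, nchar(anchor)))
  a1 <- seq_chars(anchor); a2 <- seq_chars(read_anchor)
  k <- min(length(a1), length(a2))
  if (k == 0L || sum(a1[1:k] != a2[1:k]) > max_mismatch_frac * k) {
    abort(sprintf("Read '%s' is not assignable to amplicon '%s'.",
                  pair$id, amplicon$name))
  }
  obs <- observed_target_vector(pair$seq1, pair$seq2, len)

  cpg_target <- cpg_positions_on_target(amplicon$cpg_offsets[[1L]],
                                        amplicon$targeted_strand, len) + 1L
  base <- obs[cpg_target]
  calls <- ifelse(is.na(base), NA_integer_,
                  ifelse(base == "C", 1L, ifelse(base == "T", 0L, NA_integer_)))

  ncp <- noncpg_c_positions(amplicon)
  ncp_base <- obs[ncp]
  unconverted <- sum(ncp_base == "C", na.rm = TRUE)
  converted <- sum(ncp_base == "T", na.rm = TRUE)

  target_ref <- if (amplicon$targeted_strand == "top") amplicon$ref_seq
    else revcomp(amplicon$ref_seq)
  conv_ref <- seq_chars(collapse_three_letter(
    bisulfite_reference(target_ref, "cpg_methylated", "top")))
  obs3 <- obs
  obs3[obs3 == "C"] <- "T"
  snp_top <- amplicon$snps[[1L]]$offset
  snp_pos <- if (amplicon$targeted_strand == "top") snp_top + 1L
    else len - snp_top
  covered <- which(!is.na(obs3))
  covered <- setdiff(covered, snp_pos)
  mismatches <- sum(obs3[covered] != conv_ref[covered])

  tibble(id = pair$id, umi = pair$umi, amplicon = amplicon$name, start = 0L,
         cpg_calls = list(as.integer(calls)),
         snp_obs = list(tibble(offset = integer(0), base = character(0))),
         mismatches = as.integer(mismatches),
         unconverted_noncpg = as.integer(unconverted),
         noncpg_total = as.integer(unconverted + converted),
         obs_target = list(obs))
}

#' Record observed bases at usable SNP sites
#'
#' For every usable SNP covered by the read, the observed base is recorded
#' in top-strand coordinates (bottom-strand observations are complemented).
#' Bases are recorded as-is even when they match neither allele;
#' conversion-aware allele matching is the allele-splitting step's job.
#'
#' @param aligned Aligned read tibble (rows from [call_cpgs()], carrying
#'   `obs_target`).
#' @param amplicon The matching panel row.
#' @return `aligned` with its `snp_obs` list-column filled.
#' @export
observe_snps <- function(aligned, amplicon) {
  snps <- amplicon$snps[[1L]]
  usable <- snps[!is.na(snps$usable) & snps$usable, , drop = FALSE]
  if (nrow(usable) == 0L) return(aligned)
  len <- nchar(amplicon$ref_seq)
  for (i in seq_len(nrow(aligned))) {
    obs <- aligned$obs_target[[i]]
    tpos <- if (amplicon$targeted_strand == "top") usable$offset + 1L
      else len - usable$offset
    base <- obs[tpos]
    if (amplicon$targeted_strand == "bottom") {
      base <- ifelse(is.na(base), base, complement_chars(base))
    }
    keep <- !is.na(base)
    aligned$snp_obs[[i]] <- tibble(offset = usable$offset[keep],
                                   base = unname(base[keep]))
  }
  aligned
}

#' Assign, place and call a whole read set
#'
#' Pipeline convenience wrapper: runs [assign_amplicons()], then
#' [call_cpgs()] and [observe_snps()] for every assigned pair. Reads with
#' `unconverted_noncpg >= conversion_suspect_min` are flagged
#' `conversion_suspect` but retained.
#'
#' @inheritParams assign_amplicons
#' @param conversion_suspect_min Unconverted non-CpG cytosines at or above
#'   which a read is flagged (QC only; no filtering).
#' @return List: `aligned` — tibble of called reads; `n_unassigned` —
#'   pairs failing amplicon assignment.
#' @export
align_reads <- function(tagged, panel, max_mismatch_frac = 0.1,
                        anchor_len = 30L, tie_margin = 2L,
                        conversion_suspect_min = 3L) {
  assigned <- assign_amplicons(tagged, panel, max_mismatch_frac,
                               anchor_len, tie_margin)
  n_unassigned <- sum(is.na(assigned$amplicon))
  rows <- vector("list", nrow(panel))
  for (j in seq_len(nrow(panel))) {
    amp <- panel[j, ]
    sub <- assigned[!is.na(assigned$amplicon) &
                      assigned$amplicon == amp$name, , drop = FALSE]
    if (nrow(sub) == 0L) next
    called <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
      call_cpgs(sub[i, ], amp, max_mismatch_frac)
    })
    rows[[j]] <- observe_snps(called, amp)
  }
  aligned <- bind_rows(rows)
  if (nrow(aligned) > 0L) {
    aligned$conversion_suspect <-
      aligned$unconverted_noncpg >= conversion_suspect_min
  }
  list(aligned = aligned, n_unassigned = n_unassigned)
}

#' Export aligned reads as a SAM-like debug table
#'
#' One row per read: id, amplicon, 1-based start, an all-match CIGAR, the
#' per-CpG call string (`1`/`0`/`.`) and the UMI.
#'
#' @param aligned Aligned read tibble.
#' @param path Output TSV path.
#' @return The input, invisibly.
#' @export
write_aligned_tsv <- function(aligned, path) {
  calls <- vapply(aligned$cpg_calls, function(v) {
    paste(ifelse(is.na(v), ".", as.character(v)), collapse = "")
  }, character(1))
  span <- vapply(aligned$obs_target, function(o) sum(!is.na(o)), integer(1))
  readr::write_tsv(tibble(
    id = aligned$id, amplicon = aligned$amplicon,
    pos = aligned$start + 1L, cigar = paste0(span, "M"),
    cpg_calls = calls, umi = aligned$umi), path)
  invisible(aligned)
}
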