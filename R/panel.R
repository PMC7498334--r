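# Panel module: amplicon data model, primer-design rules, bisulfite-converted
# references and SNP usability. An amplicon panel is a tibble with one row per
# amplicon and list-columns for CpG offsets and SNP annotation.

REGION_CLASSES <- c("imprinted_icr", "control_unmethylated",
                    "control_methylated", "other")

#' Adapter tails attached to bisulfite PCR primers
#'
#' The constant 5' tails added to panel primers during the first PCR. The
#' reverse tail carries an 8-nt random segment that becomes the unique
#' molecular identifier (UMI) read as the first 8 bases of read 2.
#'
#' @return A list with `fwd_tail`, `rev_tail_constant` and `umi_len`.
#' @examples
#' primer_tails()$umi_len
#' @export
primer_tails <- function() {
  list(
    fwd_tail = "CTACACGACGCTCTTCCGATCT",
    rev_tail_constant = "TGCTGAACCGCTCTTCCGATCT",
    umi_len = 8L
  )
}

#' Find CpG dinucleotides in a DNA sequence
#'
#' Returns the 0-based offsets of the 'C' of every CpG dinucleotide on the
#' given (top) strand. Overlapping scans are handled (CGCG yields 0 and 2).
#'
#' @param seq Single uppercase DNA string (A/C/G/T/N).
#' @return Integer vector of 0-based offsets, sorted ascending.
#' @examples
#' find_cpg_sites("ACGCGA")
#' @export
find_cpg_sites <- function(seq) {
  assert_dna(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < 2L) return(integer(0))
  hits <- which(ch[-n] == "C" & ch[-1L] == "G")
  as.integer(hits - 1L)
}

#' Check a bisulfite PCR primer pair against the panel design rules
#'
#' Applies the three sequence-level design rules for amplicon bisulfite PCR:
#' the product must be at most 430 bp (optimally at most 300 bp), contain at
#' least five CpGs, and neither primer may contain a CpG (so that methylated
#' and unmethylated alleles amplify equally).
#'
#' @param fwd,rev Genome-binding primer sequences (pre-bisulfite space).
#' @param product_seq Full PCR product sequence including primer-binding ends.
#' @return A one-row tibble with logical columns `size_rule`, `min_cpg_rule`,
#'   `primer_cpg_rule`, `optimal`, `pass`, plus `product_len`, `n_cpg` and a
#'   `messages` character column describing any failures.
#' @examples
#' check_primer_pair("ATTGATT", "TGGTTGA", strrep("ATCGAT", 20))
#' @export
check_primer_pair <- function(fwd, rev, product_seq) {
  assert_dna(fwd, "fwd"); assert_dna(rev, "rev")
  assert_dna(product_seq, "product_seq")
  if (!nzchar(fwd) || !nzchar(rev)) abort("Primers must be non-empty.")

  product_len <- nchar(product_seq)
  n_cpg <- length(find_cpg_sites(product_seq))
  size_rule <- product_len <= 430L
  min_cpg_rule <- n_cpg >= 5L
  primer_cpg_rule <- !grepl("CG", fwd, fixed = TRUE) &&
    !grepl("CG", rev, fixed = TRUE)

  msgs <- c(
    if (!size_rule) sprintf("product is %d bp (max 430)", product_len),
    if (!min_cpg_rule) sprintf("product has %d CpGs (min 5)", n_cpg),
    if (!primer_cpg_rule) "primer contains a CpG"
  )
  tibble(
    size_rule = size_rule,
    min_cpg_rule = min_cpg_rule,
    primer_cpg_rule = primer_cpg_rule,
    optimal = product_len <= 300L,
    pass = size_rule && min_cpg_rule && primer_cpg_rule,
    product_len = product_len,
    n_cpg = n_cpg,
    messages = if (length(msgs)) paste(msgs, collapse = "; ") else ""
  )
}

#' Bisulfite-convert a reference sequence in silico
#'
#' Emulates complete bisulfite conversion of one strand of a reference:
#' unmethylated cytosines deaminate and read as thymine, methylated cytosines
#' are retained. In `cpg_methylated` mode every CpG cytosine is treated as
#' methylated (the usual reference for aligning reads from methylated or mixed
#' templates in three-letter space); in `all_unmethylated` mode every C
#' converts. For `strand = "bottom"` the conversion applies to the reverse
#' complement and the result is returned re-complemented into top-strand
#' coordinates, where it is visible as G-to-A substitutions.
#'
#' @param seq Reference sequence, top-strand coordinates.
#' @param mode `"all_unmethylated"` or `"cpg_methylated"`.
#' @param strand `"top"` or `"bottom"`: the strand the assay targets.
#' @return Converted sequence, always in top-strand coordinates.
#' @examples
#' bisulfite_reference("CCGG", "all_unmethylated", "top")
#' bisulfite_reference("ACGT", "cpg_methylated", "top")
#' @export
bisulfite_reference <- function(seq,
                                mode = c("cpg_methylated", "all_unmethylated"),
                                strand = c("top", "bottom")) {
  assert_dna(seq)
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  if (strand == "bottom") {
    return(revcomp(bisulfite_reference(revcomp(seq), mode, "top")))
  }
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n == 0L) return(seq)
  is_c <- ch == "C"
  is_cpg_c <- is_c & c(ch[-1L] == "G", FALSE)
  convert <- if (mode == "all_unmethylated") is_c else (is_c & !is_cpg_c)
  ch[convert] <- "T"
  chars_seq(ch)
}

# Set of bases an allele can present on the sequenced strand, in top-strand
# coordinates, under either methylation assumption. On the top strand any C
# may read C (protected) or T (converted); on the bottom strand the strand's
# Cs are top-strand Gs, which may read G or A.
snp_observable_bases <- function(allele, targeted_strand) {
  if (targeted_strand == "top" && allele == "C") return(c("C", "T"))
  if (targeted_strand == "bottom" && allele == "G") return(c("G", "A"))
  allele
}

#' Flag SNPs masked by bisulfite conversion
#'
#' A SNP is usable for allele splitting only if the two alleles remain
#' distinguishable after bisulfite conversion of the targeted strand under
#' every methylation assumption. On a top-strand amplicon C/T pairs are
#' masked (an unconverted-vs-converted C mimics the T allele); on a
#' bottom-strand amplicon the mirrored G/A pairs are masked.
#'
#' @param snps Tibble of SNP sites with columns `offset`, `allele_a`,
#'   `allele_b`, `label_a`, `label_b` (zero rows allowed).
#' @param targeted_strand `"top"` or `"bottom"`.
#' @return The same tibble with a logical `usable` column set.
#' @examples
#' snps <- tibble::tibble(offset = 5L, allele_a = "C", allele_b = "T",
#'                        label_a = "BL6", label_b = "CAST")
#' filter_snps(snps, "top")$usable
#' @export
filter_snps <- function(snps, targeted_strand = c("top", "bottom")) {
  targeted_strand <- match.arg(targeted_strand)
  stopifnot(is.data.frame(snps))
  if (nrow(snps) == 0L) {
    snps$usable <- logical(0)
    return(as_tibble(snps))
  }
  if (any(snps$allele_a == snps$allele_b)) {
    abort("SNP alleles must differ.")
  }
  if (any(!nzchar(snps$label_a)) || any(!nzchar(snps$label_b)) ||
      any(snps$label_a == snps$label_b)) {
    abort("SNP strain labels must be non-empty and distinct.")
  }
  snps$usable <- mapply(function(a, b) {
    obs_a <- snp_observable_bases(a, targeted_strand)
    obs_b <- snp_observable_bases(b, targeted_strand)
    length(intersect(obs_a, obs_b)) == 0L
  }, snps$allele_a, snps$allele_b, USE.NAMES = FALSE)
  as_tibble(snps)
}

empty_snp_tibble <- function() {
  tibble(offset = integer(0), allele_a = character(0),
         allele_b = character(0), label_a = character(0),
         label_b = character(0), usable = logical(0))
}

# The anchor used for amplicon demultiplexing: first `anchor_len` bases of
# the targeted strand in three-letter (C/T-collapsed) bisulfite space.
amplicon_anchor <- function(ref_seq, targeted_strand, anchor_len = 30L) {
  target <- if (targeted_strand == "top") ref_seq else revcomp(ref_seq)
  conv <- bisulfite_reference(target, "cpg_methylated", "top")
  gsub("C", "T", substr(conv, 1L, anchor_len), fixed = TRUE)
}

validate_amplicon_row <- function(row) {
  name <- row$name
  assert_dna(row$ref_seq, paste0("ref_seq[", name, "]"))
  if (nchar(row$ref_seq) != row$end - row$start) {
    abort(sprintf("Amplicon '%s': ref_seq length %d does not match end-start %d.",
                  name, nchar(row$ref_seq), row$end - row$start))
  }
  cpgs <- find_cpg_sites(row$ref_seq)
  if (length(cpgs) < 1L) {
    abort(sprintf("Amplicon '%s': reference contains no CpG.", name))
  }
  if (!identical(as.integer(row$cpg_offsets[[1L]]), cpgs)) {
    abort(sprintf("Amplicon '%s': cpg_offsets disagree with the CpG scan.", name))
  }
  snps <- row$snps[[1L]]
  if (nrow(snps) > 0L &&
      (any(snps$offset < 0L) || any(snps$offset >= nchar(row$ref_seq)))) {
    abort(sprintf("Amplicon '%s': SNP offset outside the amplicon.", name))
  }
  if (!row$targeted_strand %in% c("top", "bottom")) {
    abort(sprintf("Amplicon '%s': targeted_strand must be top or bottom.", name))
  }
  if (!row$region_class %in% REGION_CLASSES) {
    abort(sprintf("Amplicon '%s': unknown region class '%s'.",
                  name, row$region_class))
  }
  invisible(row)
}

#' Validate an amplicon panel
#'
#' Recomputes CpG offsets from each reference, re-derives SNP usability, and
#' enforces the panel invariants (DNA alphabet, coordinate consistency, at
#' least one CpG, SNP offsets in range, unique names). Warns when two
#' amplicons share the same three-letter demultiplexing anchor, which would
#' make their reads unassignable.
#'
#' @param panel Amplicon panel tibble (see [load_panel()]).
#' @return The validated panel, invisibly classed `ampmeth_panel`.
#' @export
validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  if (anyDuplicated(panel$name)) {
    abort(sprintf("Duplicate amplicon name(s): %s.",
                  paste(unique(panel$name[duplicated(panel$name)]),
                        collapse = ", ")))
  }
  panel <- as_tibble(panel)
  panel$cpg_offsets <- lapply(panel$ref_seq, find_cpg_sites)
  panel$snps <- lapply(seq_len(nrow(panel)), function(i) {
    filter_snps(panel$snps[[i]], panel$targeted_strand[i])
  })
  for (i in seq_len(nrow(panel))) validate_amplicon_row(panel[i, ])
  anchors <- mapply(amplicon_anchor, panel$ref_seq, panel$targeted_strand,
                    USE.NAMES = FALSE)
  if (anyDuplicated(anchors)) {
    dup <- panel$name[anchors %in% anchors[duplicated(anchors)]]
    warn(sprintf(
      "Amplicons share identical three-letter anchors (reads will tie as unassigned): %s.",
      paste(dup, collapse = ", ")))
  }
  class(panel) <- c("ampmeth_panel", class(panel))
  invisible(panel)
}
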