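# Panel file I/O. On disk a panel is three diff-friendly text files:
#   - FASTA of amplicon reference sequences (top-strand, record id = name)
#   - TSV annotation: name, chrom, start, end, strand, class,
#     fwd_primer, rev_primer
#   - optional BED-like SNP file: chrom, start, end, name (amplicon),
#     alleles "A/G", labels "BL6/CAST"

PANEL_TSV_COLS <- c("name", "chrom", "start", "end", "strand", "class",
                    "fwd_primer", "rev_primer")

#' Load and validate an amplicon panel from FASTA + TSV (+ SNP file)
#'
#' FASTA records are matched to annotation rows by name; CpG offsets are
#' recomputed from the sequences and SNP usability flags derived from the
#' targeted strand, so neither can go stale on disk.
#'
#' @param fasta_path FASTA of amplicon reference sequences.
#' @param annotation_path TSV with header
#'   `name chrom start end strand class fwd_primer rev_primer`
#'   (coordinates 0-based half-open).
#' @param snp_path Optional BED-like TSV with header
#'   `chrom start end name alleles labels` where `alleles` is e.g. `"A/G"`
#'   and `labels` e.g. `"BL6/CAST"`; `name` is the amplicon the SNP falls in.
#' @return A validated panel tibble (one row per amplicon) with list-columns
#'   `cpg_offsets` and `snps`.
#' @export
load_panel <- function(fasta_path, annotation_path, snp_path = NULL) {
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           .default = readr::col_character()))
  missing_cols <- setdiff(PANEL_TSV_COLS, names(ann))
  if (length(missing_cols)) {
    abort(sprintf("Panel annotation is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  seq_names <- sub("\\s.*$", "", names(seqs))
  missing_seq <- setdiff(ann$name, seq_names)
  if (length(missing_seq)) {
    abort(sprintf("No FASTA record for amplicon(s): %s.",
                  paste(missing_seq, collapse = ", ")))
  }
  ref <- unname(toupper(as.character(seqs))[match(ann$name, seq_names)])

  snp_tab <- if (!is.null(snp_path)) {
    readr::read_tsv(snp_path, show_col_types = FALSE,
                    col_types = readr::cols(
                      start = readr::col_integer(),
                      end = readr::col_integer(),
                      .default = readr::col_character()))
  } else {
    tibble(chrom = character(0), start = integer(0), end = integer(0),
           name = character(0), alleles = character(0), labels = character(0))
  }
  unknown_snp <- setdiff(snp_tab$name, ann$name)
  if (length(unknown_snp)) {
    abort(sprintf("SNP file names unknown amplicon(s): %s.",
                  paste(unknown_snp, collapse = ", ")))
  }

  panel <- tibble(
    name = ann$name,
    chrom = ann$chrom,
    start = ann$start,
    end = ann$end,
    targeted_strand = ann$strand,
    region_class = ann$class,
    ref_seq = ref,
    fwd_primer = toupper(ann$fwd_primer),
    rev_primer = toupper(ann$rev_primer),
    cpg_offsets = lapply(ref, find_cpg_sites),
    snps = lapply(seq_along(ref), function(i) empty_snp_tibble())
  )
  for (i in seq_len(nrow(snp_tab))) {
    row <- snp_tab[i, ]
    j <- match(row$name, panel$name)
    offset <- row$start - panel$start[j]
    if (is.na(offset) || offset < 0L || offset >= nchar(panel$ref_seq[j])) {
      abort(sprintf("SNP at %s:%d is outside amplicon '%s'.",
                    row$chrom, row$start, row$name))
    }
    al <- strsplit(row$alleles, "/", fixed = TRUE)[[1L]]
    lb <- strsplit(row$labels, "/", fixed = TRUE)[[1L]]
    if (length(al) != 2L || length(lb) != 2L) {
      abort(sprintf("SNP in '%s': alleles and labels must be 'X/Y' pairs.",
                    row$name))
    }
    panel$snps[[j]] <- bind_rows(
      panel$snps[[j]],
      tibble(offset = as.integer(offset), allele_a = al[1], allele_b = al[2],
             label_a = lb[1], label_b = lb[2], usable = NA))
  }
  validate_panel(panel)
}

#' Write an amplicon panel to FASTA + TSV (+ SNP file)
#'
#' Inverse of [load_panel()]; useful for generating fixtures and for
#' exporting programmatically built panels.
#'
#' @param panel Panel tibble.
#' @param fasta_path,annotation_path,snp_path Output paths; `snp_path` may be
#'   `NULL` to skip the SNP file.
#' @return The panel, invisibly.
#' @export
write_panel <- function(panel, fasta_path, annotation_path, snp_path = NULL) {
  seqs <- Biostrings::DNAStringSet(setNames(panel$ref_seq, panel$name))
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- tibble(
    name = panel$name, chrom = panel$chrom, start = panel$start,
    end = panel$end, strand = panel$targeted_strand,
    class = panel$region_class, fwd_primer = panel$fwd_primer,
    rev_primer = panel$rev_primer)
  readr::write_tsv(ann, annotation_path)
  if (!is.null(snp_path)) {
    snp_rows <- purrr::map2_dfr(panel$name, seq_len(nrow(panel)), function(nm, i) {
      s <- panel$snps[[i]]
      if (nrow(s) == 0L) return(NULL)
      tibble(chrom = panel$chrom[i],
             start = panel$start[i] + s$offset,
             end = panel$start[i] + s$offset + 1L,
             name = nm,
             alleles = paste(s$allele_a, s$allele_b, sep = "/"),
             labels = paste(s$label_a, s$label_b, sep = "/"))
    })
    readr::write_tsv(snp_rows, snp_path)
  }
  invisible(panel)
}

# Deterministic base generator (internal LCG) so panel construction never
# touches or depends on the session RNG.
lcg_bases <- function(n, seed) {
  state <- as.double(seed %% 2147483647L)
  out <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    state <- (1103515245 * state + 12345) %% 2147483648
    out[i] <- bases[(state %/% 1024) %% 4 + 1]
  }
  out
}

# Build one synthetic amplicon reference: random-looking background with no
# incidental CpGs, `n_cpg` planted CpG dinucleotides clear of the primer
# regions, and optionally one planted SNP site carrying allele_a.
synth_amplicon_seq <- function(len, n_cpg, lcg_seed, snp_offset = NULL,
                               snp_ref_base = "A") {
  ch <- lcg_bases(len, lcg_seed)
  cg <- which(ch[-len] == "C" & ch[-1L] == "G")
  ch[cg + 1L] <- "A"
  margin <- 40L
  offs <- as.integer(round(seq(margin, len - margin, length.out = n_cpg)))
  for (o in offs) {   # 1-based plant position
    ch[o] <- "C"; ch[o + 1L] <- "G"
    if (o + 2L <= len && ch[o + 2L] == "G") ch[o + 2L] <- "T"
  }
  if (!is.null(snp_offset)) {
    p <- snp_offset + 1L
    ch[p] <- snp_ref_base
    ch[p - 1L] <- "T"
    ch[p + 1L] <- "T"
  }
  cg <- which(ch[-len] == "C" & ch[-1L] == "G")
  keep <- cg %in% offs
  ch[cg[!keep] + 1L] <- "A"
  chars_seq(ch)
}

#' Build a small synthetic amplicon panel
#'
#' Constructs a fully synthetic panel emulating a minimal imprinting assay:
#' an imprinted control-region amplicon carrying one usable A/G strain SNP,
#' unmethylated and methylated control amplicons, and a bottom-strand
#' imprinted amplicon with a usable T/C SNP. Sequences are deterministic,
#' satisfy the primer-design rules (no CpG in the primer-binding ends, 12
#' CpGs each, 240 bp) and carry non-CpG cytosines so conversion efficiency
#' is measurable. Coordinates are arbitrary; this panel exists for
#' simulation and testing, not for any real genome.
#'
#' @param n_cpg CpGs planted per amplicon.
#' @param len Amplicon length in bp.
#' @return A validated panel tibble of four amplicons.
#' @examples
#' panel <- synthetic_panel()
#' panel$name
#' @export
synthetic_panel <- function(n_cpg = 12L, len = 240L) {
  primer_len <- 22L
  mk <- function(name, chrom, start, strand, class, lcg_seed,
                 snp = NULL) {
    seq <- synth_amplicon_seq(len, n_cpg, lcg_seed,
                              snp_offset = if (is.null(snp)) NULL else snp$offset,
                              snp_ref_base = if (is.null(snp)) "A" else snp$allele_a)
    fwd <- substr(seq, 1L, primer_len)
    rev <- revcomp(substr(seq, len - primer_len + 1L, len))
    if (strand == "bottom") { tmp <- fwd; fwd <- rev; rev <- tmp }
    tibble(
      name = name, chrom = chrom, start = start, end = start + len,
      targeted_strand = strand, region_class = class, ref_seq = seq,
      fwd_primer = fwd, rev_primer = rev,
      cpg_offsets = list(find_cpg_sites(seq)),
      snps = list(if (is.null(snp)) empty_snp_tibble() else
        tibble(offset = snp$offset, allele_a = snp$allele_a,
               allele_b = snp$allele_b, label_a = snp$label_a,
               label_b = snp$label_b, usable = NA)))
  }
  panel <- bind_rows(
    mk("ICR1", "chrS1", 100000L, "top", "imprinted_icr", 11L,
       snp = list(offset = 120L, allele_a = "A", allele_b = "G",
                  label_a = "BL6", label_b = "CAST")),
    mk("CTRL_UNMETH", "chrS2", 200000L, "top", "control_unmethylated", 23L),
    mk("CTRL_METH", "chrS3", 300000L, "top", "control_methylated", 37L),
    mk("ICR2B", "chrS4", 400000L, "bottom", "imprinted_icr", 53L,
       snp = list(offset = 117L, allele_a = "T", allele_b = "C",
                  label_a = "BL6", label_b = "CAST")))
  validate_panel(panel)
}
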