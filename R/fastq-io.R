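# FASTQ I/O for paired reads, via Biostrings. Reads are held in memory as a
# tibble (id, seq1, qual1, seq2, qual2); amplicon read sets are small.

#' Write paired reads to two FASTQ files
#'
#' @param reads Tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param r1_path,r2_path Output FASTQ paths (read 1 / read 2). A `.gz`
#'   suffix triggers gzip compression.
#' @return `reads`, invisibly.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path))
  }
  write_one(reads$seq1, reads$qual1, reads$id, r1_path)
  write_one(reads$seq2, reads$qual2, reads$id, r2_path)
  invisible(reads)
}

#' Read paired FASTQ files into a read tibble
#'
#' Pairs are matched by file order; ids must agree between mates (any
#' `/1`-style suffix after whitespace is dropped).
#'
#' @param r1_path,r2_path FASTQ paths.
#' @return Tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    abort("Mate files contain different numbers of reads.")
  }
  id1 <- sub("\\s.*$", "", names(r1))
  id2 <- sub("\\s.*$", "", names(r2))
  if (!identical(id1, id2)) abort("Read ids differ between mate files.")
  tibble(id = id1,
         seq1 = unname(as.character(r1)),
         qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
         seq2 = unname(as.character(r2)),
         qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)))
}
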