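# Low-level sequence helpers shared across modules. All sequences are
# uppercase ACGTN character scalars unless noted; coordinates are 0-based
# half-open internally and only converted to 1-based in human-readable output.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

assert_dna <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single DNA string.", arg))
  }
  if (grepl("[^ACGTN]", seq)) {
    abort(sprintf("`%s` contains non-DNA characters (allowed: A C G T N).", arg))
  }
  invisible(seq)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

chars_seq <- function(x) paste(x, collapse = "")

COMPLEMENT_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

complement_chars <- function(x) unname(COMPLEMENT_MAP[x])

#' Reverse complement of a DNA string
#'
#' @param seq Single uppercase DNA string (A/C/G/T/N).
#' @return The reverse complement, same alphabet.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  assert_dna(seq)
  chars_seq(rev(complement_chars(seq_chars(seq))))
}

# Vectorised revcomp for many sequences (hot path in read synthesis).
revcomp_many <- function(seqs) {
  vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)
}

match_arg2 <- function(arg, choices, name) {
  if (!is.character(arg) || length(arg) != 1L || !arg %in% choices) {
    abort(sprintf("`%s` must be one of: %s.", name,
                  paste(choices, collapse = ", ")))
  }
  arg
}
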