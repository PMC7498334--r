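# Read simulator: ground-truthed paired-end amplicon bisulfite reads.
# A molecule is one bisulfite-converted template drawn from a parental
# allele; PCR copies of a molecule share its UMI and its conversion outcome
# (conversion happens before PCR) but receive fresh sequencing errors.

#' Bisulfite chemistry and sequencing parameters
#'
#' @param conversion_rate Probability an unmethylated cytosine reads as T
#'   (bisulfite conversion efficiency). Default 0.995.
#' @param inappropriate_conversion Probability a methylated cytosine reads
#'   as T. Default 0.005.
#' @param seq_error_rate Per-base substitution probability. Default 0.001.
#' @param read_len Read length in bases (paired 2 x 250 by default).
#' @param umi_len UMI length; fixed at 8 by the primer design.
#' @param mean_pcr_copies Mean PCR copies per molecule (shifted Poisson,
#'   minimum 1). Default 1.25, i.e. ~20% expected duplication.
#' @return A validated list of class `ampmeth_chemistry`.
#' @export
chemistry_params <- function(conversion_rate = 0.995,
                             inappropriate_conversion = 0.005,
                             seq_error_rate = 0.001,
                             read_len = 250L,
                             umi_len = 8L,
                             mean_pcr_copies = 1.25) {
  rates <- c(conversion_rate, inappropriate_conversion, seq_error_rate)
  if (any(rates < 0) || any(rates > 1)) abort("Rates must lie in [0, 1].")
  if (umi_len != 8L) abort("umi_len is fixed at 8 by the primer design.")
  if (mean_pcr_copies < 1) abort("mean_pcr_copies must be >= 1.")
  if (read_len < 1L) abort("read_len must be positive.")
  structure(list(conversion_rate = conversion_rate,
                 inappropriate_conversion = inappropriate_conversion,
                 seq_error_rate = seq_error_rate,
                 read_len = as.integer(read_len),
                 umi_len = 8L,
                 mean_pcr_copies = mean_pcr_copies),
            class = "ampmeth_chemistry")
}

#' Per-amplicon allele specification for simulation
#'
#' Describes the two parental alleles of one amplicon: per-CpG methylation
#' probabilities, strain labels (which pick the SNP alleles), the maternal
#' molecule fraction, and an optional whole-allele deletion.
#'
#' @param amplicon Amplicon name.
#' @param maternal_meth_p,paternal_meth_p Per-CpG methylation probability,
#'   scalar or one value per CpG.
#' @param maternal_label,paternal_label Strain labels.
#' @param maternal_fraction Proportion of molecules of maternal origin.
#' @param allele_deleted `"none"`, `"maternal"` or `"paternal"`; a deleted
#'   allele must have fraction 0.
#' @return One-row tibble; rows for several amplicons can be `bind_rows()`ed.
#' @examples
#' allele_spec("ICR1", maternal_meth_p = 0.98, paternal_meth_p = 0.02)
#' @export
allele_spec <- function(amplicon,
                        maternal_meth_p = 0.98,
                        paternal_meth_p = 0.02,
                        maternal_label = "BL6",
                        paternal_label = "CAST",
                        maternal_fraction = 0.5,
                        allele_deleted = c("none", "maternal", "paternal")) {
  allele_deleted <- match.arg(allele_deleted)
  if (any(c(maternal_meth_p, paternal_meth_p) < 0) ||
      any(c(maternal_meth_p, paternal_meth_p) > 1) ||
      maternal_fraction < 0 || maternal_fraction > 1) {
    abort("Methylation probabilities and maternal_fraction must lie in [0, 1].")
  }
  tibble(amplicon = amplicon,
         maternal_meth_p = list(maternal_meth_p),
         paternal_meth_p = list(paternal_meth_p),
         maternal_label = maternal_label,
         paternal_label = paternal_label,
         maternal_fraction = maternal_fraction,
         allele_deleted = allele_deleted)
}

check_deleted_fraction <- function(spec) {
  bad <- (spec$allele_deleted == "maternal" && spec$maternal_fraction > 0) ||
    (spec$allele_deleted == "paternal" && spec$maternal_fraction < 1)
  if (bad) {
    abort(sprintf("Amplicon '%s': deleted %s allele has nonzero fraction.",
                  spec$amplicon, spec$allele_deleted))
  }
}

#' Draw template molecules for one amplicon
#'
#' Each molecule's parental origin is drawn from `maternal_fraction` and its
#' per-CpG methylation bits independently from that parent's probabilities.
#' Uses the current RNG state; seed once at the [simulate_reads()] level for
#' reproducibility.
#'
#' @param amplicon One panel row (tibble).
#' @param spec One [allele_spec()] row for that amplicon.
#' @param n Number of molecules (>= 1).
#' @return Tibble: `molecule_id`, `amplicon`, `parent`, `strain`,
#'   `meth_vector` (list of 0/1 integer vectors, one bit per CpG).
#' @export
draw_molecules <- function(amplicon, spec, n) {
  stopifnot(nrow(amplicon) == 1L, nrow(spec) == 1L, n >= 1L)
  check_deleted_fraction(spec)
  n_cpg <- length(amplicon$cpg_offsets[[1L]])
  mat_p <- rep_len(spec$maternal_meth_p[[1L]], n_cpg)
  pat_p <- rep_len(spec$paternal_meth_p[[1L]], n_cpg)
  parent <- ifelse(runif(n) < spec$maternal_fraction, "maternal", "paternal")
  meth <- lapply(parent, function(p) {
    rbinom(n_cpg, 1L, if (p == "maternal") mat_p else pat_p)
  })
  tibble(
    molecule_id = sprintf("%s_m%06d", amplicon$name, seq_len(n)),
    amplicon = amplicon$name,
    parent = parent,
    strain = ifelse(parent == "maternal",
                    spec$maternal_label, spec$paternal_label),
    meth_vector = meth)
}

#' Assign PCR copy numbers to molecules
#'
#' Copy numbers follow a shifted Poisson: `1 + Poisson(mean_pcr_copies - 1)`,
#' so every molecule is sequenced at least once. All copies of a molecule
#' share its UMI; the deduplication module later collapses them.
#'
#' @param molecules Molecule tibble from [draw_molecules()].
#' @param mean_pcr_copies Mean copies per molecule (>= 1).
#' @param copies Optional integer vector overriding the random draw (e.g. a
#'   zero-variance control or a forced duplication fixture).
#' @return The tibble with an integer `copies` column.
#' @export
pcr_amplify <- function(molecules, mean_pcr_copies = 1.25, copies = NULL) {
  if (is.null(copies)) {
    if (mean_pcr_copies < 1) abort("mean_pcr_copies must be >= 1.")
    copies <- 1L + rpois(nrow(molecules), mean_pcr_copies - 1)
  }
  copies <- as.integer(rep_len(copies, nrow(molecules)))
  if (any(copies < 1L)) abort("Every molecule must have at least one copy.")
  molecules$copies <- copies
  molecules
}

# Substitute strain-specific SNP alleles into the top-strand reference.
apply_strain_alleles <- function(ref_seq, snps, strain) {
  if (nrow(snps) == 0L) return(ref_seq)
  ch <- seq_chars(ref_seq)
  for (i in seq_len(nrow(snps))) {
    allele <- if (strain == snps$label_a[i]) snps$allele_a[i]
      else if (strain == snps$label_b[i]) snps$allele_b[i]
      else NA_character_
    if (!is.na(allele)) ch[snps$offset[i] + 1L] <- allele
  }
  chars_seq(ch)
}

# Map canonical (top-strand C) CpG offsets to 0-based positions of the
# corresponding cytosine on the targeted strand, in targeted-strand coords.
cpg_positions_on_target <- function(cpg_offsets, targeted_strand, len) {
  if (targeted_strand == "top") as.integer(cpg_offsets)
  else as.integer(len - cpg_offsets - 2L)
}

#' Bisulfite-convert one molecule's template
#'
#' Stochastic in-silico bisulfite treatment of a single template molecule:
#' every cytosine on the targeted strand converts to T with the appropriate
#' probability — `conversion_rate` for unmethylated CpG and all non-CpG
#' cytosines, `inappropriate_conversion` for methylated CpG cytosines (per
#' the molecule's `meth_vector`). Conversion happens once per molecule,
#' before PCR, so all PCR copies share the outcome.
#'
#' @param template_top Top-strand template (reference with strain alleles
#'   substituted).
#' @param amplicon The panel row (for strand and CpG offsets).
#' @param meth_vector 0/1 methylation bit per CpG.
#' @param chemistry [chemistry_params()].
#' @return Converted targeted-strand sequence (5'->3' of that strand).
#' @export
convert_template <- function(template_top, amplicon, meth_vector, chemistry) {
  len <- nchar(template_top)
  target <- if (amplicon$targeted_strand == "top") template_top
    else revcomp(template_top)
  ch <- seq_chars(target)
  cpg_pos <- cpg_positions_on_target(amplicon$cpg_offsets[[1L]],
                                     amplicon$targeted_strand, len) + 1L
  is_c <- ch == "C"
  is_cpg <- rep(FALSE, len)
  is_cpg[cpg_pos] <- TRUE
  # CpG cytosines: protected when the molecule's bit is methylated
  meth <- rep(FALSE, len)
  meth[cpg_pos[meth_vector == 1L]] <- TRUE
  p_convert <- numeric(len)
  p_convert[is_c & !is_cpg] <- chemistry$conversion_rate
  p_convert[is_c & is_cpg & !meth] <- chemistry$conversion_rate
  p_convert[is_c & is_cpg & meth] <- chemistry$inappropriate_conversion
  idx <- which(is_c)
  hit <- idx[runif(length(idx)) < p_convert[idx]]
  ch[hit] <- "T"
  chars_seq(ch)
}

inject_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  chars_seq(ch)
}

#' Synthesize one paired-end read from a converted template
#'
#' Read 1 starts at the forward-primer end of the targeted strand; read 2 is
#' the mate from the reverse end and begins with the 8-nt UMI. Base
#' qualities are constant Q37. Sequencing errors (if any) are injected after
#' conversion, independently for the pair.
#'
#' @param converted Converted targeted-strand sequence (from one molecule).
#' @param umi 8-mer UMI shared by all PCR copies of the molecule.
#' @param chemistry [chemistry_params()].
#' @param id Read id (without the leading `@`).
#' @param fwd_primer_len Length of the genome-binding forward primer; the
#'   read must at least span it.
#' @return One-row tibble: `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
synthesize_read_pair <- function(converted, umi, chemistry, id,
                                 fwd_primer_len = 0L) {
  if (nchar(umi) != chemistry$umi_len) abort("UMI must be exactly 8 nt.")
  if (chemistry$read_len < fwd_primer_len) {
    abort("read_len is shorter than the primer region.")
  }
  len <- nchar(converted)
  r1 <- substr(converted, 1L, min(chemistry$read_len, len))
  r2_full <- paste0(umi, revcomp(converted))
  r2 <- substr(r2_full, 1L, min(chemistry$read_len, nchar(r2_full)))
  r1 <- inject_errors(r1, chemistry$seq_error_rate)
  r2 <- inject_errors(r2, chemistry$seq_error_rate)
  tibble(id = id,
         seq1 = r1, qual1 = strrep("F", nchar(r1)),
         seq2 = r2, qual2 = strrep("F", nchar(r2)))
}

random_umis <- function(n, umi_len = 8L, mode = c("random", "unique")) {
  mode <- match.arg(mode)
  draw <- function(k) {
    vapply(seq_len(k), function(i) {
      chars_seq(sample(c("A", "C", "G", "T"), umi_len, replace = TRUE))
    }, character(1))
  }
  umis <- draw(n)
  if (mode == "unique") {
    while (anyDuplicated(umis)) {
      dup <- which(duplicated(umis))
      umis[dup] <- draw(length(dup))
    }
  }
  umis
}

#' Simulate a ground-truthed paired-end amplicon bisulfite read set
#'
#' End-to-end generator: draws molecules per amplicon, assigns UMIs, applies
#' stochastic bisulfite conversion once per molecule, PCR-amplifies with
#' shared UMIs, and synthesizes paired 250-bp reads with sequencing error.
#' Fully deterministic for a given seed and configuration.
#'
#' @param panel Amplicon panel tibble.
#' @param specs Tibble of [allele_spec()] rows (one per amplicon to simulate).
#' @param n_molecules Molecules per amplicon.
#' @param chemistry [chemistry_params()].
#' @param seed Integer seed governing every random draw.
#' @param umi_mode `"random"` (uniform over 4^8, collisions possible) or
#'   `"unique"` (sampled without replacement within the run).
#' @param copies Optional forced copy-count vector passed to [pcr_amplify()].
#' @return List with `reads` (tibble: id, seq1, qual1, seq2, qual2) and
#'   `truth` (tibble: molecule_id, amplicon, parent, strain, meth_vector,
#'   umi, copies).
#' @examples
#' panel <- synthetic_panel()
#' sim <- simulate_reads(panel[1, ], allele_spec("ICR1"), n_molecules = 5,
#'                       seed = 1)
#' sim$truth
#' @export
simulate_reads <- function(panel, specs, n_molecules,
                           chemistry = chemistry_params(), seed = 1L,
                           umi_mode = c("random", "unique"), copies = NULL) {
  umi_mode <- match.arg(umi_mode)
  if (n_molecules < 1L) abort("n_molecules must be >= 1.")
  missing_amp <- setdiff(specs$amplicon, panel$name)
  if (length(missing_amp)) {
    abort(sprintf("Spec names amplicon(s) not in the panel: %s.",
                  paste(missing_amp, collapse = ", ")))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  truth_list <- list()
  read_list <- list()
  for (k in seq_len(nrow(specs))) {
    spec <- specs[k, ]
    amp <- panel[panel$name == spec$amplicon, ]
    mols <- draw_molecules(amp, spec, n_molecules)
    mols$umi <- random_umis(nrow(mols), chemistry$umi_len, umi_mode)
    mols <- pcr_amplify(mols, chemistry$mean_pcr_copies, copies = copies)
    pairs <- vector("list", nrow(mols))
    for (i in seq_len(nrow(mols))) {
      template <- apply_strain_alleles(amp$ref_seq, amp$snps[[1L]],
                                       mols$strain[i])
      converted <- convert_template(template, amp, mols$meth_vector[[i]],
                                    chemistry)
      ids <- sprintf("SIM001:1:%s:%d:%d", amp$name, i, seq_len(mols$copies[i]))
      pairs[[i]] <- purrr::map_dfr(seq_len(mols$copies[i]), function(cp) {
        synthesize_read_pair(converted, mols$umi[i], chemistry, ids[cp],
                             fwd_primer_len = nchar(amp$fwd_primer))
      })
    }
    truth_list[[k]] <- mols
    read_list[[k]] <- bind_rows(pairs)
  }
  list(reads = bind_rows(read_list), truth = bind_rows(truth_list))
}

#' Write / read the simulation truth table
#'
#' One row per molecule; the methylation bit-vector is serialised as a
#' 0/1 string. Round-trips exactly through [read_truth()].
#'
#' @param molecules Truth tibble from [simulate_reads()].
#' @param path Output TSV path.
#' @return The input, invisibly.
#' @export
write_truth <- function(molecules, path) {
  if (anyDuplicated(molecules$molecule_id)) {
    abort("Duplicate molecule ids in truth table.")
  }
  out <- molecules
  out$meth_vector <- vapply(molecules$meth_vector, paste,
                            character(1), collapse = "")
  readr::write_tsv(out, path)
  invisible(molecules)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           meth_vector = readr::col_character(),
                           copies = readr::col_integer(),
                           .default = readr::col_character()))
  tab$meth_vector <- lapply(strsplit(tab$meth_vector, ""),
                            function(x) as.integer(x))
  as_tibble(tab)
}
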