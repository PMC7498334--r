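test_that("CpG scanner finds overlapping dinucleotides and rejects bad input", {
  expect_identical(find_cpg_sites("ACGCGA"), c(1L, 3L))
  expect_identical(find_cpg_sites("ATTA"), integer(0))
  expect_identical(find_cpg_sites("CGCG"), c(0L, 2L))
  expect_identical(find_cpg_sites("CG"), 0L)
  expect_error(find_cpg_sites("ACGU"), "non-DNA")
})

test_that("CpG scanner agrees with a regex oracle on random sequences", {
  set.seed(4)
  for (i in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 80, replace = TRUE,
                        prob = c(0.3, 0.25, 0.25, 0.15, 0.05)),
                 collapse = "")
    oracle <- as.integer(gregexpr("(?=CG)", seq, perl = TRUE)[[1L]]) - 1L
    oracle <- oracle[oracle >= 0L]
    expect_identical(find_cpg_sites(seq), oracle)
  }
})

test_that("primer rules enforce the 430-bp cap, 5-CpG floor and CpG-free primers", {
  # 6 CpGs, CpG-free ends, adjustable length
  base <- strrep("AT", 40)
  product <- function(len) {
    cpgs <- strrep(paste0("CGTTA"), 6)
    filler <- strrep("T", len - nchar(base) * 2 - nchar(cpgs))
    paste0(base, cpgs, filler, base)
  }
  v431 <- check_primer_pair("ATTGATT", "TGATTGA", product(431))
  expect_false(v431$size_rule)
  expect_true(v431$min_cpg_rule)
  expect_true(v431$primer_cpg_rule)
  expect_false(v431$pass)

  v430 <- check_primer_pair("ATTGATT", "TGATTGA", product(430))
  expect_true(v430$size_rule)
  expect_false(v430$optimal)

  v300 <- check_primer_pair("ATTGATT", "TGATTGA", product(300))
  expect_true(v300$pass)
  expect_true(v300$optimal)

  # 4 CpGs only
  few <- paste0(base, strrep("CGTTA", 4), strrep("T", 50), base)
  expect_false(check_primer_pair("ATTGATT", "TGATTGA", few)$min_cpg_rule)

  expect_false(check_primer_pair("ATTCGATT", "TGATTGA", product(300))$primer_cpg_rule)
  expect_error(check_primer_pair("", "TGA", product(300)), "non-empty")
})

test_that("primer verdict equals brute-force rule evaluation", {
  set.seed(9)
  for (i in 1:20) {
    len <- sample(250:450, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    fwd <- substr(seq, 1, 20)
    rev <- revcomp(substr(seq, len - 19, len))
    v <- check_primer_pair(fwd, rev, seq)
    n_cpg <- lengths(regmatches(seq, gregexpr("(?=CG)", seq, perl = TRUE)))
    expect_equal(v$pass,
                 len <= 430 && n_cpg >= 5 &&
                   !grepl("CG", fwd) && !grepl("CG", rev))
  }
})

test_that("bisulfite conversion follows strand and methylation mode", {
  expect_identical(bisulfite_reference("ACGT", "cpg_methylated", "top"), "ACGT")
  expect_identical(bisulfite_reference("CCGG", "all_unmethylated", "top"), "TTGG")
  expect_identical(bisulfite_reference("ACGT", "all_unmethylated", "bottom"), "ACAT")
  expect_identical(bisulfite_reference("CCGG", "cpg_methylated", "top"), "TCGG")
  # bottom strand, CpG methylated: the CpG's G (bottom-strand C) is kept
  expect_identical(bisulfite_reference("ACGT", "cpg_methylated", "bottom"), "ACGT")
})

test_that("conversion is idempotent and preserves/destroys CpGs as stated", {
  set.seed(11)
  for (i in 1:15) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    for (mode in c("cpg_methylated", "all_unmethylated")) {
      for (strand in c("top", "bottom")) {
        conv <- bisulfite_reference(seq, mode, strand)
        expect_identical(bisulfite_reference(conv, mode, strand), conv)
      }
    }
    expect_length(find_cpg_sites(bisulfite_reference(seq, "cpg_methylated", "top")),
                  length(find_cpg_sites(seq)))
    expect_false(grepl("C", bisulfite_reference(seq, "all_unmethylated", "top")))
  }
})

test_that("SNP usability excludes conversion-masked pairs, symmetric in alleles", {
  mk <- function(a, b) tibble::tibble(offset = 3L, allele_a = a, allele_b = b,
                                      label_a = "BL6", label_b = "CAST")
  expect_false(filter_snps(mk("C", "T"), "top")$usable)
  expect_false(filter_snps(mk("G", "A"), "bottom")$usable)
  expect_true(filter_snps(mk("A", "G"), "top")$usable)
  expect_true(filter_snps(mk("C", "T"), "bottom")$usable)
  expect_true(filter_snps(mk("C", "A"), "bottom")$usable)
  expect_true(filter_snps(mk("C", "A"), "top")$usable)
  expect_false(filter_snps(mk("A", "G"), "bottom")$usable)

  # allele order never matters
  for (strand in c("top", "bottom")) {
    for (pair in list(c("A", "G"), c("C", "T"), c("C", "A"), c("G", "T"))) {
      expect_identical(filter_snps(mk(pair[1], pair[2]), strand)$usable,
                       filter_snps(mk(pair[2], pair[1]), strand)$usable)
    }
  }
  expect_error(filter_snps(mk("A", "A"), "top"), "differ")
})

test_that("panel files round-trip and loading enforces the invariants", {
  panel <- fixture_panel()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "panel.fa")
  tsv <- file.path(dir, "panel.tsv")
  snp <- file.path(dir, "panel_snps.tsv")
  write_panel(panel, fa, tsv, snp)
  reloaded <- load_panel(fa, tsv, snp)
  expect_identical(reloaded$name, panel$name)
  expect_identical(reloaded$ref_seq, panel$ref_seq)
  expect_identical(reloaded$cpg_offsets, panel$cpg_offsets)
  expect_equal(as.data.frame(reloaded$snps[[1]]), as.data.frame(panel$snps[[1]]))

  # annotation row without FASTA record
  ann <- readr::read_tsv(tsv, show_col_types = FALSE)
  ann$name[1] <- "MISSING"
  tsv2 <- file.path(dir, "bad.tsv")
  readr::write_tsv(ann, tsv2)
  expect_error(load_panel(fa, tsv2, NULL), "MISSING")

  # amplicon with no CpG is rejected by name
  writeLines(c(">NOCPG", strrep("AT", 60)), file.path(dir, "nocpg.fa"))
  ann3 <- tibble::tibble(name = "NOCPG", chrom = "chr1", start = 0L,
                         end = 120L, strand = "top", class = "other",
                         fwd_primer = "ATAT", rev_primer = "ATAT")
  readr::write_tsv(ann3, file.path(dir, "nocpg.tsv"))
  expect_error(load_panel(file.path(dir, "nocpg.fa"),
                          file.path(dir, "nocpg.tsv")), "NOCPG")

  expect_error(validate_panel(dplyr::bind_rows(panel, panel[1, ])),
               "Duplicate")
})
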