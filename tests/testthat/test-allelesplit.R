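mk_read <- function(id, snp_obs, amplicon = "ICR1") {
  tibble::tibble(id = id, umi = "AAAAAAAA", amplicon = amplicon, start = 0L,
                 cpg_calls = list(rep(1L, 12)), snp_obs = list(snp_obs),
                 mismatches = 0L, unconverted_noncpg = 0L, noncpg_total = 5L,
                 obs_target = list(NA_character_))
}

test_that("single-SNP votes assign reads; conflicts and no-SNP reads do not", {
  panel <- fixture_panel()
  amp <- panel[1, ]   # A/G SNP at offset 120, BL6 = A, CAST = G
  g_obs <- tibble::tibble(offset = 120L, base = "G")
  a_obs <- tibble::tibble(offset = 120L, base = "A")
  none <- tibble::tibble(offset = integer(0), base = character(0))

  expect_identical(genotype_read(mk_read("r1", g_obs), amp)$label, "CAST")
  expect_identical(genotype_read(mk_read("r2", a_obs), amp)$label, "BL6")
  g1 <- genotype_read(mk_read("r3", none), amp)
  expect_identical(g1$label, "unassigned")
  expect_false(g1$conflict)
  expect_identical(g1$n_informative, 0L)

  # a sequencing error producing a base matching neither allele: uninformative
  t_obs <- tibble::tibble(offset = 120L, base = "T")
  expect_identical(genotype_read(mk_read("r4", t_obs), amp)$label, "unassigned")

  # two SNPs voting for different strains conflict
  amp2 <- amp
  amp2$snps <- list(tibble::tibble(
    offset = c(120L, 60L), allele_a = c("A", "T"), allele_b = c("G", "G"),
    label_a = "BL6", label_b = "CAST", usable = TRUE))
  conf <- tibble::tibble(offset = c(120L, 60L), base = c("G", "T"))
  g2 <- genotype_read(mk_read("r5", conf), amp2)
  expect_identical(g2$label, "unassigned")
  expect_true(g2$conflict)
  expect_identical(g2$n_informative, 2L)
})

test_that("conversion-aware matching tolerates converted allele cytosines", {
  panel <- fixture_panel()
  # top strand, C/A SNP: observed T must vote for the C allele
  amp <- panel[1, ]
  amp$snps <- list(filter_snps(tibble::tibble(
    offset = 120L, allele_a = "C", allele_b = "A",
    label_a = "BL6", label_b = "CAST"), "top"))
  expect_true(amp$snps[[1]]$usable)
  t_obs <- tibble::tibble(offset = 120L, base = "T")
  expect_identical(genotype_read(mk_read("r1", t_obs), amp)$label, "BL6")

  # bottom strand, G/T SNP: observed A votes for the G allele
  ampb <- panel[4, ]
  ampb$snps <- list(filter_snps(tibble::tibble(
    offset = 117L, allele_a = "G", allele_b = "T",
    label_a = "BL6", label_b = "CAST"), "bottom"))
  expect_true(ampb$snps[[1]]$usable)
  a_obs <- tibble::tibble(offset = 117L, base = "A")
  expect_identical(genotype_read(mk_read("rb", a_obs, "ICR2B"), ampb)$label,
                   "BL6")
})

test_that("split percentages sum to 100 and degenerate panels are handled", {
  panel <- fixture_panel()
  reads <- dplyr::bind_rows(
    mk_read("r1", tibble::tibble(offset = 120L, base = "A")),
    mk_read("r2", tibble::tibble(offset = 120L, base = "A")),
    mk_read("r3", tibble::tibble(offset = 120L, base = "G")),
    mk_read("r4", tibble::tibble(offset = integer(0), base = character(0))))
  sc <- split_counts(genotype_reads(reads, panel))
  expect_equal(sc$pct_a + sc$pct_b + sc$pct_unassigned, 100)
  expect_equal(sc$pct_a, 50)   # BL6
  expect_equal(sc$pct_b, 25)   # CAST
  expect_equal(sc$pct_unassigned, 25)

  all_one <- split_counts(genotype_reads(reads[1:2, ], panel))
  expect_equal(all_one$pct_a, 100)
  expect_equal(all_one$pct_b, 0)

  # amplicon without usable SNPs: everything unassigned
  no_snp <- mk_read("n1", tibble::tibble(offset = integer(0),
                                         base = character(0)),
                    amplicon = "CTRL_METH")
  sc2 <- split_counts(genotype_reads(no_snp, panel))
  expect_equal(sc2$pct_unassigned, 100)
  expect_error(split_counts(genotype_reads(reads[0, ], panel)), "No assignments")
})

test_that("error-free hybrid reads are assigned with 100% accuracy", {
  panel <- fixture_panel()
  sim <- clean_sim()
  res <- clean_result()
  truth <- sim$truth
  for (amp_name in c("ICR1", "ICR2B")) {
    asg <- res$assignments[res$assignments$amplicon == amp_name, ]
    expect_gt(nrow(asg), 0)
    mol <- match(read_molecule_id(asg$id), truth$molecule_id)
    expect_identical(asg$label, truth$strain[mol])
    expect_false(any(asg$conflict))
  }
  split <- res$allele_split
  expect_equal(split$pct_unassigned[split$amplicon %in% c("ICR1", "ICR2B")],
               c(0, 0))
})

test_that("swapping parental strains mirrors the per-allele tables", {
  panel <- fixture_panel()[1, ]
  fwd_spec <- allele_spec("ICR1", 0.9, 0.1,
                          maternal_label = "BL6", paternal_label = "CAST")
  rev_spec <- allele_spec("ICR1", 0.9, 0.1,
                          maternal_label = "CAST", paternal_label = "BL6")
  run_one <- function(spec) {
    sim <- simulate_reads(panel, spec, 80, chemistry = clean_chemistry(),
                          seed = 77, umi_mode = "unique", copies = 1L)
    run_pipeline(sim$reads, panel)
  }
  cross_f <- run_one(fwd_spec)
  cross_r <- run_one(rev_spec)
  tab_f <- cross_f$cpg_table
  tab_r <- cross_r$cpg_table
  # same RNG stream: the maternal molecules are identical, only labelled
  # with the opposite strain, so per-strain tables swap exactly
  expect_identical(tab_f[tab_f$allele == "BL6", c("meth", "unmeth")],
                   tab_r[tab_r$allele == "CAST", c("meth", "unmeth")])
  expect_identical(tab_f[tab_f$allele == "CAST", c("meth", "unmeth")],
                   tab_r[tab_r$allele == "BL6", c("meth", "unmeth")])
})
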