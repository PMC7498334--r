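mk_calls_read <- function(id, calls, amplicon = "ICR1") {
  tibble::tibble(id = id, umi = sprintf("%08d", abs(sum(utf8ToInt(id)))),
                 amplicon = amplicon, start = 0L, cpg_calls = list(calls),
                 mismatches = 0L, unconverted_noncpg = 0L, noncpg_total = 5L,
                 obs_target = list(NA_character_))
}

test_that("per-CpG counts aggregate calls and skip unknowns", {
  panel <- fixture_panel()
  # 7 methylated + 3 unmethylated at CpG 1; CpG 2 only unknown calls
  reads <- dplyr::bind_rows(lapply(1:10, function(i) {
    calls <- rep(NA_integer_, 12)
    calls[1] <- if (i <= 7) 1L else 0L
    mk_calls_read(sprintf("r%02d", i), calls)
  }))
  tab <- build_table(reads, panel)
  row1 <- tab[tab$amplicon == "ICR1" & tab$offset == panel$cpg_offsets[[1]][1], ]
  expect_identical(row1$meth, 7L)
  expect_identical(row1$unmeth, 3L)
  expect_equal(row1$methylation_pct, 70)
  row2 <- tab[tab$amplicon == "ICR1" & tab$offset == panel$cpg_offsets[[1]][2], ]
  expect_identical(row2$meth + row2$unmeth, 0L)
  expect_true(is.na(row2$methylation_pct))
})

test_that("zero-error 50:50 imprint recovers the truth-table counts exactly", {
  sim <- clean_sim()
  res <- clean_result()
  truth_counts <- lapply(split(sim$truth$meth_vector, sim$truth$amplicon),
                         function(v) colSums(do.call(rbind, v)))
  tab <- res$cpg_table[res$cpg_table$allele == "all", ]
  for (amp in names(truth_counts)) {
    sub <- tab[tab$amplicon == amp, ]
    expect_identical(sub$meth, as.integer(truth_counts[[amp]]))
  }
})

test_that("read classification uses strict cutoffs and a called-CpG minimum", {
  thr <- quant_thresholds()
  expect_identical(classify_read(rep(1L, 10), thr), "methylated")
  expect_identical(classify_read(rep(0L, 10), thr), "unmethylated")
  expect_identical(classify_read(c(rep(1L, 9), 0L), thr), "intermediate")  # 90.0%
  expect_identical(classify_read(c(rep(1L, 5), rep(0L, 5)), thr), "intermediate")
  expect_identical(classify_read(c(1L, 1L, rep(NA_integer_, 10)), thr),
                   "uncallable")
  expect_identical(classify_read(c(1L, 1L, 1L), thr), "methylated")

  reads <- dplyr::bind_rows(
    mk_calls_read("a", rep(1L, 12)),
    mk_calls_read("b", rep(0L, 12)),
    mk_calls_read("c", c(rep(1L, 6), rep(0L, 6))))
  cls <- classify_reads(reads, thr)
  expect_identical(cls$read_class, c("methylated", "unmethylated",
                                     "intermediate"))
  expect_equal(cls$read_pct, c(100, 0, 50))
})

test_that("coverage filter is strictly greater-than-100", {
  panel <- fixture_panel()[1, ]
  mk_n <- function(n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      mk_calls_read(sprintf("r%04d", i), rep(1L, 12))
    }))
  }
  rep100 <- region_summary(mk_n(100), panel)
  expect_identical(rep100$status, "low_coverage")
  rep101 <- region_summary(mk_n(101), panel)
  expect_false(rep101$status == "low_coverage")
  expect_identical(rep101$n_reads, 101L)
  empty <- region_summary(mk_n(1)[0, ], panel)
  expect_identical(empty$status, "low_coverage")
})

test_that("region status maps mean methylation and class to the field rules", {
  thr <- quant_thresholds()
  expect_identical(call_region_status(50, "imprinted_icr", thr), "normal_imprint")
  expect_identical(call_region_status(40, "imprinted_icr", thr), "normal_imprint")
  expect_identical(call_region_status(60, "imprinted_icr", thr), "normal_imprint")
  expect_identical(call_region_status(39.9, "imprinted_icr", thr), "hypomethylated")
  expect_identical(call_region_status(0, "imprinted_icr", thr), "hypomethylated")
  expect_identical(call_region_status(60.1, "imprinted_icr", thr), "hypermethylated")
  expect_identical(call_region_status(5, "control_unmethylated", thr), "control_pass")
  expect_identical(call_region_status(15, "control_unmethylated", thr), "control_fail")
  expect_identical(call_region_status(95, "control_methylated", thr), "control_pass")
  expect_identical(call_region_status(85, "control_methylated", thr), "control_fail")
  expect_error(call_region_status(50, "mystery", thr), "region class")
})

test_that("conversion efficiency is the converted non-CpG cytosine fraction", {
  mk_conv <- function(id, unconv, total, amplicon = "ICR1") {
    r <- mk_calls_read(id, rep(1L, 12), amplicon)
    r$unconverted_noncpg <- unconv
    r$noncpg_total <- total
    r
  }
  reads <- dplyr::bind_rows(
    mk_conv("a", 0L, 30L),
    mk_conv("b", 3L, 30L),
    mk_conv("c", 0L, 0L, amplicon = "CTRL_METH"))
  eff <- conversion_efficiency(reads)
  expect_equal(eff$efficiency_pct[eff$amplicon == "ICR1"], 100 * 57 / 60)
  expect_true(is.na(eff$efficiency_pct[eff$amplicon == "CTRL_METH"]))
  expect_equal(eff$efficiency_pct[eff$amplicon == "_all_"], 95)
})

test_that("pipeline conversion efficiency tracks the chemistry setting", {
  res_clean <- clean_result()
  eff <- res_clean$conversion
  expect_equal(eff$efficiency_pct[eff$amplicon == "_all_"], 100)

  panel <- fixture_panel()[1, ]
  chem <- chemistry_params(conversion_rate = 0.99,
                           inappropriate_conversion = 0,
                           seq_error_rate = 0, mean_pcr_copies = 1)
  sim <- simulate_reads(panel, imprint_spec(), 300, chemistry = chem,
                        seed = 41)
  res <- run_pipeline(sim$reads, panel)
  got <- res$conversion$efficiency_pct[res$conversion$amplicon == "_all_"]
  # 300 molecules x 34 non-CpG Cs: binomial(10200, 0.99) 99.9% interval
  expect_lt(abs(got - 99), 0.35)
})

test_that("recovered methylation lies in the binomial interval of the truth", {
  panel <- fixture_panel()[1, ]
  set.seed(53)
  for (p in c(0.1, 0.5, 0.9)) {
    spec <- allele_spec("ICR1", p, p)
    sim <- simulate_reads(panel, spec, 300, seed = floor(1000 * p) + 7)
    res <- run_pipeline(sim$reads, panel, by_allele = FALSE)
    truth_bits <- unlist(sim$truth$meth_vector)
    truth_frac <- mean(truth_bits)
    got <- res$regions$mean_pct / 100
    # conversion chemistry shifts the expectation slightly:
    # E[called meth] = q*(1-0.005) + (1-q)*0.005 for realized truth q
    expected <- truth_frac * 0.995 + (1 - truth_frac) * 0.005
    ci <- stats::binom.test(round(expected * 3600), 3600,
                            conf.level = 0.99)$conf.int
    expect_gt(got, ci[1] - 0.01)
    expect_lt(got, ci[2] + 0.01)
  }
})
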