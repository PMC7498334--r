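# End-to-end pipeline over an in-memory read set, plus broom-style
# accessors for the fitted result.

#' Run the full amplicon methylation pipeline
#'
#' UMI extraction, trimming, amplicon assignment and CpG calling, UMI
#' deduplication, optional allele splitting, quantification and region
#' status calls — over a paired read tibble (from [read_fastq_pairs()] or
#' [simulate_reads()]).
#'
#' @param reads Read tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param panel Amplicon panel.
#' @param thresholds [quant_thresholds()].
#' @param by_allele Split reads by parental allele via panel SNPs?
#' @param quality_cutoff Phred cutoff for 3' trimming.
#' @param umi_mismatch Passed to [deduplicate()].
#' @return An `ampmeth_result` object: a list with the stage outputs
#'   (`aligned`, `unique_reads`, `dedup_stats`, `assignments`,
#'   `allele_split`, `cpg_table`, `regions`, `conversion`, `shift`) and a
#'   read-accounting tibble `accounting` in which every input pair appears
#'   exactly once (rejected at UMI extraction, discarded at trimming,
#'   unassigned, duplicate, or unique).
#' @examples
#' panel <- synthetic_panel()
#' sim <- simulate_reads(panel[1, ], allele_spec("ICR1"), 30, seed = 7)
#' res <- run_pipeline(sim$reads, panel)
#' glance(res)
#' @export
run_pipeline <- function(reads, panel, thresholds = quant_thresholds(),
                         by_allele = TRUE, quality_cutoff = 20L,
                         umi_mismatch = 0L) {
  n_input <- nrow(reads)
  um <- extract_umi(reads)
  tr <- trim_pairs(um$reads, quality_cutoff = quality_cutoff)
  al <- align_reads(tr$reads, panel)
  dd <- deduplicate(al$aligned, umi_mismatch = umi_mismatch)
  n_unique <- nrow(dd$unique)
  n_dup <- nrow(al$aligned) - n_unique

  assignments <- NULL
  allele_split <- NULL
  has_snps <- any(vapply(panel$snps, function(s) any(s$usable %in% TRUE),
                         logical(1)))
  if (by_allele && has_snps && n_unique > 0L) {
    assignments <- genotype_reads(dd$unique, panel)
    allele_split <- split_counts(assignments)
  }
  cpg_table <- build_table(dd$unique, panel,
                           by_allele = !is.null(assignments),
                           assignments = assignments)
  regions <- region_summary(dd$unique, panel, thresholds, dd$stats)
  shift <- if (setequal(unique(al$aligned$amplicon),
                        unique(dd$unique$amplicon)) &&
               nrow(dd$unique) > 0L) {
    methylation_shift_check(al$aligned, dd$unique, panel)
  }
  accounting <- tibble(
    category = c("input", "rejected_umi", "discarded_trim", "unassigned",
                 "duplicate", "unique"),
    n = c(n_input, um$n_rejected, tr$n_discarded, al$n_unassigned,
          n_dup, n_unique))
  structure(list(
    panel = panel, thresholds = thresholds,
    aligned = al$aligned, unique_reads = dd$unique, dedup_stats = dd$stats,
    assignments = assignments, allele_split = allele_split,
    cpg_table = cpg_table, regions = regions,
    conversion = conversion_efficiency(dd$unique),
    shift = shift, trim_report = tr$report, accounting = accounting),
    class = "ampmeth_result")
}

#' @export
print.ampmeth_result <- function(x, ...) {
  acc <- setNames(x$accounting$n, x$accounting$category)
  cat(sprintf("<ampmeth_result> %d read pairs: %d unique, %d duplicate, %d unassigned\n",
              acc["input"], acc["unique"], acc["duplicate"], acc["unassigned"]))
  print(x$regions)
  invisible(x)
}

#' Tidy a pipeline result into the per-CpG methylation table
#'
#' @param x An `ampmeth_result`.
#' @param ... Unused.
#' @return The per-CpG tibble (`amplicon`, `offset`, `allele`, `meth`,
#'   `unmeth`, `methylation_pct`).
#' @method tidy ampmeth_result
#' @export
tidy.ampmeth_result <- function(x, ...) x$cpg_table

#' One-row summary of a pipeline result
#'
#' @param x An `ampmeth_result`.
#' @param ... Unused.
#' @return One-row tibble: read counts, global duplication rate, global
#'   conversion efficiency, and the number of regions passing/failing.
#' @method glance ampmeth_result
#' @export
glance.ampmeth_result <- function(x, ...) {
  acc <- setNames(x$accounting$n, x$accounting$category)
  glob_dup <- x$dedup_stats$duplication_pct[x$dedup_stats$amplicon == "_all_"]
  glob_conv <- x$conversion$efficiency_pct[x$conversion$amplicon == "_all_"]
  tibble(n_input = acc[["input"]], n_unique = acc[["unique"]],
         n_unassigned = acc[["unassigned"]],
         duplication_pct = glob_dup, conversion_efficiency_pct = glob_conv,
         n_regions = nrow(x$regions),
         n_low_coverage = sum(x$regions$status == "low_coverage"),
         n_normal_imprint = sum(x$regions$status == "normal_imprint"))
}
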