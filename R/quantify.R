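# Quantify module: per-CpG, per-read and per-region methylation summaries,
# the coverage filter, and imprinting-fidelity status calls.

#' Quantification thresholds
#'
#' The classification thresholds, hardened from the assay's approximate
#' rules into strict numeric ones: a region needs strictly more than
#' `min_region_reads` deduplicated reads; a read is fully methylated above
#' `read_meth_hi` percent and fully unmethylated below `read_meth_lo`; an
#' imprinted region is normal inside `normal_band`; read classification
#' requires at least `min_cpgs_called_per_read` called CpGs.
#'
#' @param min_region_reads Coverage threshold (strictly greater required).
#' @param read_meth_hi,read_meth_lo Per-read class cutoffs, percent.
#' @param normal_band Length-2 numeric, percent, the normal imprint band.
#' @param min_cpgs_called_per_read Minimum called CpGs for a read class.
#' @return A list of class `ampmeth_thresholds`.
#' @export
quant_thresholds <- function(min_region_reads = 100L,
                             read_meth_hi = 90,
                             read_meth_lo = 10,
                             normal_band = c(40, 60),
                             min_cpgs_called_per_read = 3L) {
  if (read_meth_lo >= read_meth_hi) abort("read_meth_lo must be < read_meth_hi.")
  if (length(normal_band) != 2L || any(normal_band < 0) ||
      any(normal_band > 100) || normal_band[1] > normal_band[2]) {
    abort("normal_band must be an increasing pair within [0, 100].")
  }
  structure(list(min_region_reads = as.integer(min_region_reads),
                 read_meth_hi = read_meth_hi, read_meth_lo = read_meth_lo,
                 normal_band = normal_band,
                 min_cpgs_called_per_read = as.integer(min_cpgs_called_per_read)),
            class = "ampmeth_thresholds")
}

#' Per-CpG methylation table
#'
#' Aggregates per-read CpG calls into methylated/unmethylated counts and a
#' methylation percentage per CpG. Unknown calls contribute to neither
#' count; a CpG with no called reads reports `NA` percent. With
#' `by_allele = TRUE`, additional per-allele tables are built from reads
#' assigned to a strain (conflict and unassigned reads are excluded from
#' allele tables but remain in the overall table).
#'
#' @param unique_reads Deduplicated aligned read tibble.
#' @param panel Amplicon panel.
#' @param by_allele Build per-allele tables as well?
#' @param assignments [genotype_reads()] output; required if `by_allele`.
#' @return Tibble: `amplicon`, `offset` (0-based, top-strand C), `allele`
#'   (`"all"` or a strain label), `meth`, `unmeth`, `methylation_pct`.
#' @export
build_table <- function(unique_reads, panel, by_allele = FALSE,
                        assignments = NULL) {
  one_table <- function(reads, allele_label) {
    purrr::map_dfr(seq_len(nrow(panel)), function(j) {
      amp <- panel[j, ]
      offs <- amp$cpg_offsets[[1L]]
      sub <- reads[reads$amplicon == amp$name, , drop = FALSE]
      if (nrow(sub) > 0L) {
        mat <- do.call(rbind, sub$cpg_calls)
        meth <- colSums(mat == 1L, na.rm = TRUE)
        unmeth <- colSums(mat == 0L, na.rm = TRUE)
      } else {
        meth <- unmeth <- rep(0L, length(offs))
      }
      tibble(amplicon = amp$name, offset = as.integer(offs),
             allele = allele_label,
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             methylation_pct = ifelse(meth + unmeth > 0,
                                      100 * meth / (meth + unmeth), NA_real_))
    })
  }
  out <- one_table(unique_reads, "all")
  if (by_allele) {
    if (is.null(assignments)) {
      abort("`assignments` is required when by_allele = TRUE.")
    }
    labs <- setdiff(unique(assignments$label), "unassigned")
    for (lab in sort(labs)) {
      ids <- assignments$id[assignments$label == lab]
      out <- bind_rows(out, one_table(
        unique_reads[unique_reads$id %in% ids, , drop = FALSE], lab))
    }
  }
  out
}

read_meth_pct <- function(cpg_calls) {
  called <- sum(!is.na(cpg_calls))
  if (called == 0L) return(NA_real_)
  100 * sum(cpg_calls == 1L, na.rm = TRUE) / called
}

#' Classify reads as fully methylated, unmethylated or intermediate
#'
#' Read-level methylation is the percentage of methylated calls over called
#' CpGs; strictly above the high cutoff is `methylated`, strictly below the
#' low cutoff `unmethylated`, anything else `intermediate` (so a read at
#' exactly 90% is intermediate). Reads with fewer called CpGs than the
#' minimum are `uncallable`.
#'
#' @param aligned Aligned read tibble.
#' @param thresholds [quant_thresholds()].
#' @return The tibble with added `read_pct` and `read_class` columns.
#' @export
classify_reads <- function(aligned, thresholds = quant_thresholds()) {
  pct <- vapply(aligned$cpg_calls, read_meth_pct, numeric(1))
  called <- vapply(aligned$cpg_calls, function(v) sum(!is.na(v)), integer(1))
  cls <- ifelse(called < thresholds$min_cpgs_called_per_read, "uncallable",
         ifelse(pct > thresholds$read_meth_hi, "methylated",
         ifelse(pct < thresholds$read_meth_lo, "unmethylated",
                "intermediate")))
  mutate(aligned, read_pct = pct, read_class = cls)
}

#' Classify a single read's call vector
#'
#' @param cpg_calls Integer vector of 1/0/`NA` calls.
#' @param thresholds [quant_thresholds()].
#' @return One of `"methylated"`, `"unmethylated"`, `"intermediate"`,
#'   `"uncallable"`.
#' @export
classify_read <- function(cpg_calls, thresholds = quant_thresholds()) {
  called <- sum(!is.na(cpg_calls))
  if (called < thresholds$min_cpgs_called_per_read) return("uncallable")
  pct <- read_meth_pct(cpg_calls)
  if (pct > thresholds$read_meth_hi) return("methylated")
  if (pct < thresholds$read_meth_lo) return("unmethylated")
  "intermediate"
}

#' Call region status from mean methylation and region class
#'
#' Imprinted control regions are `normal_imprint` inside the 40-60% band,
#' `hypomethylated` below and `hypermethylated` above; unmethylated controls
#' pass strictly below 10%, methylated controls strictly above 90%.
#'
#' @param mean_pct Region mean per-CpG methylation percent.
#' @param region_class One of the panel region classes.
#' @param thresholds [quant_thresholds()].
#' @return Status string.
#' @export
call_region_status <- function(mean_pct, region_class,
                               thresholds = quant_thresholds()) {
  if (is.na(mean_pct)) return("low_coverage")
  band <- thresholds$normal_band
  switch(region_class,
    imprinted_icr =
      if (mean_pct < band[1]) "hypomethylated"
      else if (mean_pct > band[2]) "hypermethylated"
      else "normal_imprint",
    control_unmethylated =
      if (mean_pct < thresholds$read_meth_lo) "control_pass"
      else "control_fail",
    control_methylated =
      if (mean_pct > thresholds$read_meth_hi) "control_pass"
      else "control_fail",
    other = "not_classified",
    abort(sprintf("Unknown region class '%s'.", region_class)))
}

#' Apply the post-deduplication coverage filter
#'
#' Regions with `n_reads` at or below the threshold (strictly more than 100
#' reads are required by default) are set to `low_coverage` and excluded
#' from downstream status interpretation.
#'
#' @param report Region report tibble (from [region_summary()]).
#' @param thresholds [quant_thresholds()].
#' @return The report with `status` overwritten where coverage fails.
#' @export
apply_coverage_filter <- function(report, thresholds = quant_thresholds()) {
  mutate(report, status = ifelse(
    .data$n_reads <= thresholds$min_region_reads, "low_coverage",
    .data$status))
}

#' Bisulfite conversion efficiency
#'
#' Percentage of non-CpG cytosine observations that were converted
#' (read as T), globally and per amplicon. Amplicons with no observed
#' non-CpG cytosines report `NA`.
#'
#' @param aligned Aligned read tibble (deduplicated or not).
#' @return Tibble: `amplicon` (including a `"_all_"` row), `converted`,
#'   `total`, `efficiency_pct`.
#' @export
conversion_efficiency <- function(aligned) {
  per <- aligned %>%
    group_by(amplicon = .data$amplicon) %>%
    summarise(converted = sum(.data$noncpg_total - .data$unconverted_noncpg),
              total = sum(.data$noncpg_total), .groups = "drop")
  out <- bind_rows(per, tibble(amplicon = "_all_",
                               converted = sum(per$converted),
                               total = sum(per$total)))
  mutate(out, efficiency_pct = ifelse(.data$total > 0,
                                      100 * .data$converted / .data$total,
                                      NA_real_))
}

#' Per-region summary with read classes, duplication and status
#'
#' The region mean is the unweighted mean over per-CpG methylation
#' percentages (CpGs without calls are dropped), matching per-CpG
#' quantification; read-class fractions are over classifiable reads only.
#'
#' @param unique_reads Deduplicated aligned read tibble.
#' @param panel Amplicon panel.
#' @param thresholds [quant_thresholds()].
#' @param dedup_stats Optional `$stats` from [deduplicate()] (for
#'   duplication percentages).
#' @return Tibble per amplicon: `amplicon`, `region_class`, `n_reads`,
#'   `mean_pct`, `frac_methylated`, `frac_unmethylated`, `frac_intermediate`,
#'   `duplication_pct`, `status`.
#' @export
region_summary <- function(unique_reads, panel,
                           thresholds = quant_thresholds(),
                           dedup_stats = NULL) {
  tab <- build_table(unique_reads, panel)
  classified <- classify_reads(unique_reads, thresholds)
  out <- purrr::map_dfr(seq_len(nrow(panel)), function(j) {
    amp <- panel[j, ]
    sub <- classified[classified$amplicon == amp$name, , drop = FALSE]
    cl <- sub$read_class[sub$read_class != "uncallable"]
    n_cl <- length(cl)
    pcts <- tab$methylation_pct[tab$amplicon == amp$name]
    mean_pct <- if (all(is.na(pcts))) NA_real_ else mean(pcts, na.rm = TRUE)
    dup <- if (!is.null(dedup_stats)) {
      d <- dedup_stats$duplication_pct[dedup_stats$amplicon == amp$name]
      if (length(d)) d else NA_real_
    } else NA_real_
    tibble(amplicon = amp$name, region_class = amp$region_class,
           n_reads = nrow(sub), mean_pct = mean_pct,
           frac_methylated = if (n_cl) sum(cl == "methylated") / n_cl else NA_real_,
           frac_unmethylated = if (n_cl) sum(cl == "unmethylated") / n_cl else NA_real_,
           frac_intermediate = if (n_cl) sum(cl == "intermediate") / n_cl else NA_real_,
           duplication_pct = dup,
           status = call_region_status(mean_pct, amp$region_class, thresholds))
  })
  apply_coverage_filter(out, thresholds)
}

#' Export quantification results as text files
#'
#' Writes the per-CpG table as TSV (1-based positions), a bedGraph
#' (0-based half-open, score = methylation %), and the per-read call matrix
#' (rows = reads, columns = CpGs, values 1/0/.) that underlies per-read
#' epiallele ("lollipop") displays.
#'
#' @param cpg_table [build_table()] output.
#' @param aligned Aligned (deduplicated) reads, for the read matrix.
#' @param panel Amplicon panel.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_quantification <- function(cpg_table, aligned, panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coords <- panel %>% select("name", "chrom", "start") %>%
    rename(amplicon = "name", amp_start = "start")
  tab <- left_join(cpg_table, coords, by = "amplicon") %>%
    mutate(pos1 = .data$amp_start + .data$offset + 1L)

  tsv_path <- file.path(dir, "cpg_methylation.tsv")
  readr::write_tsv(select(tab, "amplicon", "chrom", "pos1", "allele",
                          "meth", "unmeth", "methylation_pct"), tsv_path)

  bg <- tab %>% filter(.data$allele == "all", !is.na(.data$methylation_pct)) %>%
    mutate(bg_start = .data$pos1 - 1L, bg_end = .data$pos1 + 1L)
  bg_path <- file.path(dir, "cpg_methylation.bedGraph")
  readr::write_tsv(select(bg, "chrom", "bg_start", "bg_end",
                          "methylation_pct"), bg_path, col_names = FALSE)

  mat_path <- file.path(dir, "read_call_matrix.tsv")
  calls <- vapply(aligned$cpg_calls, function(v) {
    paste(ifelse(is.na(v), ".", as.character(v)), collapse = "\t")
  }, character(1))
  header <- paste("id", "amplicon", "umi", "calls", sep = "\t")
  writeLines(c(header, paste(aligned$id, aligned$amplicon, aligned$umi,
                             calls, sep = "\t")), mat_path)
  invisible(c(tsv_path, bg_path, mat_path))
}
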