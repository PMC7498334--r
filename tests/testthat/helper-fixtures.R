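# Shared fixtures: the synthetic four-amplicon panel, canonical allele
# specs, and cached simulations (built once per test run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

fixture_panel <- function() cached("panel", synthetic_panel())

# Error-free chemistry: complete conversion, no inappropriate conversion,
# no sequencing error, exactly one PCR copy per molecule.
clean_chemistry <- function(mean_pcr_copies = 1) {
  chemistry_params(conversion_rate = 1, inappropriate_conversion = 0,
                   seq_error_rate = 0, mean_pcr_copies = mean_pcr_copies)
}

imprint_spec <- function(amplicon = "ICR1") {
  allele_spec(amplicon, maternal_meth_p = 0.98, paternal_meth_p = 0.02)
}

full_panel_specs <- function() {
  dplyr::bind_rows(
    imprint_spec("ICR1"),
    allele_spec("CTRL_UNMETH", 0.02, 0.02),
    allele_spec("CTRL_METH", 0.98, 0.98),
    imprint_spec("ICR2B"))
}

# Clean-chemistry simulation over the whole panel, single copies, distinct
# UMIs: the exactness-limit fixture.
clean_sim <- function() {
  cached("clean_sim", simulate_reads(
    fixture_panel(), full_panel_specs(), n_molecules = 60,
    chemistry = clean_chemistry(), seed = 101, umi_mode = "unique",
    copies = 1L))
}

clean_result <- function() {
  cached("clean_result", run_pipeline(clean_sim()$reads, fixture_panel()))
}

# Truth molecule index parsed back out of a simulated read id
# (SIM001:1:<amplicon>:<molecule>:<copy>[:UMI]).
read_molecule_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)
  vapply(parts, function(p) sprintf("%s_m%06d", p[3], as.integer(p[4])),
         character(1))
}

# Independent brute-force deduplication oracle: enumerate (amplicon, start,
# UMI) groups with base R and keep the alphabetically first id per group.
brute_dedup_ids <- function(aligned) {
  key <- paste(aligned$amplicon, aligned$start, aligned$umi, sep = "|")
  unname(vapply(split(aligned$id, key), function(ids) sort(ids)[1],
                character(1)))
}
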