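# YAML run configuration: chemistry + thresholds + per-amplicon allele
# specs, mirrored into R objects. The config is echoed into the output
# directory on every run for provenance.

#' Read a pipeline configuration file
#'
#' YAML with optional blocks `chemistry` (fields of [chemistry_params()]),
#' `thresholds` (fields of [quant_thresholds()]) and `alleles` (a list of
#' [allele_spec()] field sets, one per amplicon). Missing fields take the
#' package defaults.
#'
#' @param path YAML file path; `NULL` gives an all-defaults config.
#' @return List with `chemistry`, `thresholds`, `alleles` (tibble or NULL),
#'   and `seed` (integer or NULL).
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  chem <- do.call(chemistry_params, raw$chemistry %||na% list())
  thr <- do.call(quant_thresholds, raw$thresholds %||na% list())
  alleles <- if (!is.null(raw$alleles)) {
    purrr::map_dfr(raw$alleles, function(a) do.call(allele_spec, a))
  }
  list(chemistry = chem, thresholds = thr, alleles = alleles,
       seed = raw$seed)
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Echo a configuration into an output directory
#'
#' @param config List from [read_config()].
#' @param outdir Directory to write `config_used.yaml` into.
#' @return The path written, invisibly.
#' @export
write_config_echo <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    chemistry = unclass(config$chemistry),
    thresholds = unclass(config$thresholds),
    seed = config$seed)
  if (!is.null(config$alleles)) {
    out$alleles <- purrr::map(seq_len(nrow(config$alleles)), function(i) {
      a <- config$alleles[i, ]
      list(amplicon = a$amplicon,
           maternal_meth_p = a$maternal_meth_p[[1L]],
           paternal_meth_p = a$paternal_meth_p[[1L]],
           maternal_label = a$maternal_label,
           paternal_label = a$paternal_label,
           maternal_fraction = a$maternal_fraction,
           allele_deleted = a$allele_deleted)
    })
  }
  path <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(out, path)
  invisible(path)
}
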