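#' Pipeline run configuration
#'
#' @param genes,ncrnas annotation files (GFF3/BED6/TSV; format guessed from
#'   extension unless overridden).
#' @param gene_counts,ncrna_counts count matrix TSVs.
#' @param samples sample sheet TSV (`sample_id`, `condition`).
#' @param out_dir output directory.
#' @param fdr_threshold gene-level FDR cutoff in (0, 1] (default 0.25).
#' @param genes_format,ncrnas_format annotation dialects (see
#'   [read_features()]).
#' @param require_ncrna_significant also require ncRNA significance in the
#'   pair selection (default FALSE).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(genes, ncrnas, gene_counts, ncrna_counts, samples,
                       out_dir, fdr_threshold = 0.25,
                       genes_format = "auto", ncrnas_format = "auto",
                       require_ncrna_significant = FALSE) {
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1) {
    stop("fdr_threshold must lie in (0, 1]")
  }
  cfg <- list(genes = genes, ncrnas = ncrnas, gene_counts = gene_counts,
              ncrna_counts = ncrna_counts, samples = samples,
              out_dir = out_dir, fdr_threshold = fdr_threshold,
              genes_format = genes_format, ncrnas_format = ncrnas_format,
              require_ncrna_significant = require_ncrna_significant)
  inputs <- c(genes, ncrnas, gene_counts, ncrna_counts, samples)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "RunConfig")
}

#' Load a RunConfig from a flat YAML file
#'
#' Recognized keys are the arguments of [run_config()]. Entries in
#' `overrides` (e.g. parsed command-line flags) replace the file's values.
#'
#' @param path YAML file.
#' @param overrides named list of values taking precedence over the file.
#' @return a [run_config()].
#' @export
load_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  for (k in names(overrides)) {
    if (!is.null(overrides[[k]])) raw[[k]] <- overrides[[k]]
  }
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

drop_unannotated <- function(cm, features, what) {
  known <- rownames(cm$counts) %in% features$feature_id
  n_drop <- sum(!known)
  if (n_drop > 0) {
    message(n_drop, " ", what, " count row(s) dropped: id absent from the ",
            "annotation (", sum(known), " kept)")
    cm <- count_matrix(cm$counts[known, , drop = FALSE], cm$condition)
  }
  cm
}

#' Run the full sense/antisense correlation analysis
#'
#' Reads annotations and counts, builds the pair catalog (overlap join ->
#' opposite-strand filter -> longest ncRNA per gene), computes NB Wald
#' differential expression for genes and ncRNAs, selects pairs significant at
#' the gene-level FDR threshold, and computes the Pearson correlation of
#' sense and antisense log2 fold-changes. Writes `pair_catalog.tsv`,
#' `de_genes.tsv`, `de_ncrnas.tsv`, `pair_table.tsv` and `summary.json` to
#' the output directory. The run is deterministic given identical inputs.
#'
#' @param config a [run_config()] (or path handled by [load_run_config()]).
#' @return (invisibly) the run summary: a list with `schema_version`,
#'   stage counts, `n_pairs`, `r`, `pvalue`, `fdr_threshold` and output file
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genes <- read_features(config$genes, config$genes_format,
                         kind_default = "gene", label = "genes")
  ncrnas <- read_features(config$ncrnas, config$ncrnas_format,
                          kind_default = "ncRNA_other", label = "ncRNAs")
  gene_cm <- read_count_matrix(config$gene_counts, config$samples)
  ncrna_cm <- read_count_matrix(config$ncrna_counts, config$samples)
  gene_cm <- drop_unannotated(gene_cm, genes, "gene")
  ncrna_cm <- drop_unannotated(ncrna_cm, ncrnas, "ncRNA")

  catalog <- build_pair_catalog(genes, ncrnas)
  if (nrow(catalog) == 0) {
    stop(structure(class = c("empty_catalog_error", "error", "condition"),
                   list(message = "no opposite-strand overlapping pairs found",
                        call = sys.call())))
  }
  de_genes <- nb_wald_test(gene_cm)
  de_ncrnas <- nb_wald_test(ncrna_cm)
  corr <- correlate_pairs(catalog, de_genes, de_ncrnas,
                          fdr_threshold = config$fdr_threshold,
                          require_ncrna_significant = config$require_ncrna_significant)

  p <- function(f) file.path(config$out_dir, f)
  write_pair_catalog(catalog, p("pair_catalog.tsv"))
  write_de_results(de_genes, p("de_genes.tsv"))
  write_de_results(de_ncrnas, p("de_ncrnas.tsv"))
  utils::write.table(corr$table, p("pair_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- c(
    list(schema_version = 1L, fdr_threshold = config$fdr_threshold),
    attr(catalog, "summary"),
    list(n_genes_tested = nrow(de_genes), n_ncrnas_tested = nrow(de_ncrnas),
         n_pairs = corr$n_pairs, r = corr$r, pvalue = corr$pvalue,
         status = corr$status,
         files = list(pair_catalog = p("pair_catalog.tsv"),
                      de_genes = p("de_genes.tsv"),
                      de_ncrnas = p("de_ncrnas.tsv"),
                      pair_table = p("pair_table.tsv"),
                      summary = p("summary.json")))
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(summary)
}
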