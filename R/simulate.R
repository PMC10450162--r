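#' Simulation configuration
#'
#' Parameters of the synthetic study: a yeast-like genome of non-overlapping
#' genes, a fraction of which carry an opposite-strand overlapping ncRNA, and
#' two-condition negative-binomial counts in which the true log2 fold-changes
#' of paired sense/antisense features share a planted Pearson correlation
#' `rho`.
#'
#' Defaults describe the study conditions used throughout the test suite:
#' 1500 genes all carrying an antisense partner, unit-SD true effects,
#' dispersion 0.01, deep coverage (baseline means LogNormal with median 1500,
#' so nearly all features average >= 500 counts), 6 control vs 6 treatment
#' replicates and library-size factors in [0.7, 1.3].
#'
#' @param n_genes number of genes.
#' @param antisense_fraction fraction of genes given an opposite-strand
#'   overlapping ncRNA, in [0, 1].
#' @param rho planted correlation of true sense/antisense log2FCs, in [-1, 1].
#' @param effect_sd SD of true gene log2 fold-changes (log2 units).
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2); 0 gives
#'   Poisson counts.
#' @param mean_log_mu,sd_log_mu log-normal (natural-log) parameters of
#'   baseline expression means.
#' @param n_control,n_treatment replicate counts (>= 2 each).
#' @param size_factor_range interval for uniform true library-size factors.
#' @param decoy_fraction fraction of genes matched by each decoy class
#'   (intergenic and same-strand overlapping); 0 disables decoys.
#' @param seed master seed; every stage derives its own stream from it.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 1500, antisense_fraction = 1, rho = 0.9,
                       effect_sd = 1, dispersion = 0.01,
                       mean_log_mu = log(1500), sd_log_mu = 0.4,
                       n_control = 6, n_treatment = 6,
                       size_factor_range = c(0.7, 1.3),
                       decoy_fraction = 0.05, seed = 1) {
  stopifnot(n_genes >= 0,
            antisense_fraction >= 0, antisense_fraction <= 1,
            abs(rho) <= 1, effect_sd >= 0, dispersion >= 0,
            n_control >= 2, n_treatment >= 2,
            length(size_factor_range) == 2,
            size_factor_range[1] > 0,
            size_factor_range[2] >= size_factor_range[1],
            decoy_fraction >= 0)
  structure(list(
    n_genes = as.integer(n_genes), antisense_fraction = antisense_fraction,
    rho = rho, effect_sd = effect_sd, dispersion = dispersion,
    mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
    n_control = as.integer(n_control), n_treatment = as.integer(n_treatment),
    size_factor_range = as.numeric(size_factor_range),
    decoy_fraction = decoy_fraction, seed = as.integer(seed)
  ), class = "SimConfig")
}

# Independent per-stage streams derived from one master seed, so annotation
# and counts can be regenerated separately. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage)) * 7919L
  (as.integer(seed) %% 1000003L) * 2011L + offset
}

#' Simulate gene and antisense ncRNA annotations
#'
#' Places non-overlapping genes (lengths U[500, 3000], intergenic gaps
#' U[200, 1000]) on toy chromosomes of at most 500 genes each, with strands
#' alternating along each chromosome. A `round(antisense_fraction * n_genes)`
#' subset of genes each receives one opposite-strand ncRNA (target length
#' U[200, 1500]) that overlaps the gene's 3' half by at least 100 bases; the
#' ncRNA starts inside the gene and any 3' extension is clipped at the
#' neighbouring gap so it never reaches another gene — each planted ncRNA
#' overlaps exactly its own gene. Two decoy classes are added: intergenic
#' ncRNAs overlapping nothing, and same-strand ncRNAs contained in a gene
#' (removed by the opposite-strand filter).
#'
#' @param config a [sim_config()].
#' @param seed master seed (default `config$seed`).
#' @return list with `genes` and `ncrnas` ([feature_set()]s) and `pairs`, the
#'   planted gene_id/ncrna_id truth mapping.
#' @export
simulate_annotation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(stage_seed(seed, "annotation"))
  n <- config$n_genes
  per_chrom <- 500L
  chrom_of <- paste0("chr_sim", ((seq_len(n) - 1L) %/% per_chrom) + 1L)
  pos_in_chrom <- ((seq_len(n) - 1L) %% per_chrom) + 1L

  gap_before <- round(stats::runif(n, 200, 1000))
  gap_after <- round(stats::runif(n, 200, 1000))
  glen <- round(stats::runif(n, 500, 3000))
  gstart <- integer(n); gend <- integer(n)
  cursor <- 0L
  for (i in seq_len(n)) {
    if (pos_in_chrom[i] == 1L) cursor <- 0L
    gstart[i] <- cursor + gap_before[i] + 1L
    gend[i] <- gstart[i] + glen[i] - 1L
    # the gap between gene i and i+1 is gap_after[i] (gap_before of the next
    # gene is only used when it opens a chromosome)
    cursor <- gend[i] + gap_after[i]
    if (i < n && pos_in_chrom[i + 1L] != 1L) gap_before[i + 1L] <- gap_after[i]
  }
  strand <- ifelse(pos_in_chrom %% 2L == 1L, "+", "-")
  gene_id <- sprintf("gene%05d", seq_len(n))
  genes <- feature_set(data.frame(
    feature_id = gene_id, chrom = chrom_of, start = gstart, end = gend,
    strand = strand, kind = "gene", stringsAsFactors = FALSE
  ), label = "genes")

  nc <- list()
  pairs <- data.frame(gene_id = character(0), ncrna_id = character(0),
                      stringsAsFactors = FALSE)
  n_as <- round(config$antisense_fraction * n)
  if (n_as > 0) {
    chosen <- sort(sample.int(n, n_as))
    L <- round(stats::runif(n_as, 200, 1500))
    ovl <- round(stats::runif(n_as, 100, pmin(L, glen[chosen])))
    ext <- L - ovl
    plus <- strand[chosen] == "+"
    # clip the extension so the ncRNA never enters the neighbouring gap's gene
    ext <- pmin(ext, ifelse(plus, gap_after[chosen], gap_before[chosen]) - 1L)
    ext <- pmax(ext, 0L)
    ns <- ifelse(plus, gend[chosen] - ovl + 1L, gstart[chosen] - ext)
    ne <- ifelse(plus, gend[chosen] + ext, gstart[chosen] + ovl - 1L)
    as_id <- paste0("as_", gene_id[chosen])
    nc[["antisense"]] <- data.frame(
      feature_id = as_id, chrom = chrom_of[chosen],
      start = as.integer(ns), end = as.integer(ne),
      strand = ifelse(plus, "-", "+"),
      kind = sample(c("CUT", "SUT", "XUT"), n_as, replace = TRUE),
      stringsAsFactors = FALSE
    )
    pairs <- data.frame(gene_id = gene_id[chosen], ncrna_id = as_id,
                        stringsAsFactors = FALSE)
  }
  n_dec <- ceiling(config$decoy_fraction * n)
  if (n_dec > 0 && n > 0) {
    host <- sample.int(n, n_dec, replace = TRUE)
    dlen <- pmin(round(stats::runif(n_dec, 100, 800)), gap_after[host] - 2L)
    dlen <- pmax(dlen, 50L)
    offs <- floor(stats::runif(n_dec) *
                    (gap_after[host] - dlen - 1L + 1L))
    ds <- gend[host] + 1L + as.integer(offs)
    nc[["intergenic"]] <- data.frame(
      feature_id = sprintf("idec%04d", seq_len(n_dec)),
      chrom = chrom_of[host], start = ds, end = ds + as.integer(dlen) - 1L,
      strand = sample(c("+", "-"), n_dec, replace = TRUE),
      kind = sample(c("CUT", "SUT", "XUT"), n_dec, replace = TRUE),
      stringsAsFactors = FALSE
    )
    host2 <- sample.int(n, n_dec, replace = TRUE)
    slen <- pmin(round(stats::runif(n_dec, 200, 1500)), glen[host2])
    offs2 <- floor(stats::runif(n_dec) * (glen[host2] - slen + 1L))
    ss <- gstart[host2] + as.integer(offs2)
    nc[["samestrand"]] <- data.frame(
      feature_id = sprintf("sdec%04d", seq_len(n_dec)),
      chrom = chrom_of[host2], start = ss, end = ss + as.integer(slen) - 1L,
      strand = strand[host2],
      kind = sample(c("CUT", "SUT", "XUT"), n_dec, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  nc_df <- if (length(nc) > 0) do.call(rbind, nc) else data.frame(
    feature_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), kind = character(0),
    stringsAsFactors = FALSE
  )
  rownames(nc_df) <- NULL
  ncrnas <- feature_set(nc_df, label = "ncRNAs", kind_default = "ncRNA_other")
  list(genes = genes, ncrnas = ncrnas, pairs = pairs)
}

#' Simulate two-condition NB counts with a planted effect correlation
#'
#' True gene log2 fold-changes are `g_i ~ N(0, effect_sd^2)`. Each paired
#' ncRNA gets `a_i = rho * g_i + sqrt(1 - rho^2) * e_i` with
#' `e_i ~ N(0, effect_sd^2)`, so `Corr(g, a) = rho` exactly in expectation;
#' unpaired ncRNAs get independent effects. Baseline means are log-normal.
#' Sample `j` of feature `i` is drawn NB with mean
#' `s_j * mu_i * 2^(lfc_i * [j in treatment])` and dispersion alpha
#' (Poisson when alpha = 0). Gene and ncRNA matrices share the same samples
#' and true size factors.
#'
#' @param genes,ncrnas [feature_set()]s (from [simulate_annotation()]).
#' @param pairs planted gene/ncRNA mapping (from [simulate_annotation()]).
#' @param config a [sim_config()].
#' @param seed master seed (default `config$seed`).
#' @return list with `gene_counts` and `ncrna_counts` ([count_matrix()]s) and
#'   `truth`: list of `gene_lfc`, `ncrna_lfc` (named numeric), `size_factors`
#'   (named), and the `pairs` mapping.
#' @export
simulate_counts <- function(genes, ncrnas, pairs, config,
                            seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(stage_seed(seed, "counts"))
  nC <- config$n_control; nT <- config$n_treatment
  sample_id <- c(sprintf("ctrl_%d", seq_len(nC)),
                 sprintf("trt_%d", seq_len(nT)))
  condition <- stats::setNames(rep(c("control", "treatment"), c(nC, nT)),
                               sample_id)
  sf <- stats::setNames(
    stats::runif(nC + nT, config$size_factor_range[1],
                 config$size_factor_range[2]), sample_id)

  gene_lfc <- stats::setNames(
    stats::rnorm(nrow(genes), 0, config$effect_sd), genes$feature_id)
  ncrna_lfc <- stats::setNames(
    stats::rnorm(nrow(ncrnas), 0, config$effect_sd), ncrnas$feature_id)
  if (nrow(pairs) > 0) {
    eps <- stats::rnorm(nrow(pairs), 0, config$effect_sd)
    ncrna_lfc[pairs$ncrna_id] <- config$rho * gene_lfc[pairs$gene_id] +
      sqrt(1 - config$rho^2) * eps
  }

  draw <- function(ids, lfc) {
    mu0 <- stats::rlnorm(length(ids), config$mean_log_mu, config$sd_log_mu)
    is_trt <- condition == "treatment"
    m <- outer(mu0, sf) * 2^(lfc %o% as.numeric(is_trt))
    counts <- if (config$dispersion == 0) {
      matrix(stats::rpois(length(m), lambda = m), nrow = length(ids))
    } else {
      matrix(stats::rnbinom(length(m), mu = m, size = 1 / config$dispersion),
             nrow = length(ids))
    }
    dimnames(counts) <- list(ids, sample_id)
    count_matrix(counts, condition)
  }
  gene_counts <- draw(genes$feature_id, gene_lfc)
  ncrna_counts <- draw(ncrnas$feature_id, ncrna_lfc)
  list(gene_counts = gene_counts, ncrna_counts = ncrna_counts,
       truth = list(gene_lfc = gene_lfc, ncrna_lfc = ncrna_lfc,
                    size_factors = sf, pairs = pairs))
}

#' Simulate a complete on-disk dataset
#'
#' Runs [simulate_annotation()] and [simulate_counts()] and writes all
#' artifacts to a directory: BED6 + TSV annotations, count matrix TSVs, a
#' sample sheet, the truth table of planted effects, and a JSON manifest
#' recording the configuration, seed and per-file MD5 hashes.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the simulated objects and a `files` vector
#'   of written paths.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory not writable: ", out_dir)
  }
  ann <- simulate_annotation(config)
  cnt <- simulate_counts(ann$genes, ann$ncrnas, ann$pairs, config)
  p <- function(f) file.path(out_dir, f)

  write_features_bed(ann$genes, p("genes.bed"))
  write_features_bed(ann$ncrnas, p("ncrnas.bed"))
  write_features_tsv(ann$genes, p("genes.tsv"))
  write_features_tsv(ann$ncrnas, p("ncrnas.tsv"))
  write_counts_tsv(cnt$gene_counts, p("gene_counts.tsv"))
  write_counts_tsv(cnt$ncrna_counts, p("ncrna_counts.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cnt$gene_counts$condition),
               condition = unname(cnt$gene_counts$condition)),
    p("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- rbind(
    data.frame(feature_id = names(cnt$truth$gene_lfc), set = "gene",
               true_log2fc = unname(cnt$truth$gene_lfc)),
    data.frame(feature_id = names(cnt$truth$ncrna_lfc), set = "ncrna",
               true_log2fc = unname(cnt$truth$ncrna_lfc))
  )
  utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cnt$truth$pairs, p("true_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c("genes.bed", "ncrnas.bed", "genes.tsv", "ncrnas.tsv",
             "gene_counts.tsv", "ncrna_counts.tsv", "samples.tsv",
             "truth.tsv", "true_pairs.tsv")
  manifest <- list(
    schema_version = 1L,
    config = unclass(config),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genes = ann$genes, ncrnas = ann$ncrnas, pairs = ann$pairs,
                 gene_counts = cnt$gene_counts,
                 ncrna_counts = cnt$ncrna_counts, truth = cnt$truth,
                 files = file.path(out_dir, c(files, "manifest.json"))))
}

#' Write a CountMatrix to TSV (feature_id + one column per sample)
#'
#' @param x a `CountMatrix`.
#' @param path output file.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "CountMatrix"))
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
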