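#' Overlap join of genes against non-coding transcripts
#'
#' Finds every (gene, ncRNA) pair sharing at least one base on the same
#' chromosome, regardless of strand, and records the intersection interval
#' `[max(starts), min(ends)]`. Abutting intervals (gene end + 1 == ncRNA
#' start) do not overlap. The join runs on GenomicRanges interval trees;
#' output is ordered by (gene input order, ncRNA input order).
#'
#' @param genes `FeatureSet` of genes.
#' @param ncrnas `FeatureSet` of non-coding transcripts.
#' @return data.frame of candidate pairs with columns `gene_id`, `ncrna_id`,
#'   `chrom`, `gene_strand`, `ncrna_strand`, `overlap_start`, `overlap_end`,
#'   `overlap_length`, `ncrna_start`, `ncrna_length`.
#' @export
overlap_join <- function(genes, ncrnas) {
  stopifnot(inherits(genes, "FeatureSet"), inherits(ncrnas, "FeatureSet"))
  chroms <- unique(c(genes$chrom, ncrnas$chrom))
  gr_g <- as_granges(genes, seqlevels = chroms)
  gr_n <- as_granges(ncrnas, seqlevels = chroms)
  hits <- GenomicRanges::findOverlaps(gr_g, gr_n, minoverlap = 1L,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  o <- order(qi, si)
  qi <- qi[o]; si <- si[o]
  ovl_start <- pmax(genes$start[qi], ncrnas$start[si])
  ovl_end <- pmin(genes$end[qi], ncrnas$end[si])
  data.frame(
    gene_id        = genes$feature_id[qi],
    ncrna_id       = ncrnas$feature_id[si],
    chrom          = genes$chrom[qi],
    gene_strand    = genes$strand[qi],
    ncrna_strand   = ncrnas$strand[si],
    overlap_start  = ovl_start,
    overlap_end    = ovl_end,
    overlap_length = ovl_end - ovl_start + 1L,
    ncrna_start    = ncrnas$start[si],
    ncrna_length   = ncrnas$end[si] - ncrnas$start[si] + 1L,
    stringsAsFactors = FALSE
  )
}

#' Keep only opposite-strand (antisense) pairs
#'
#' @param pairs data.frame from [overlap_join()].
#' @return the subset whose gene and ncRNA strands differ; order preserved.
#' @export
filter_opposite_strand <- function(pairs) {
  pairs[pairs$gene_strand != pairs$ncrna_strand, , drop = FALSE]
}

#' Resolve each gene to its longest antisense ncRNA
#'
#' For each gene keeps the single pair whose ncRNA has maximal full annotated
#' length (not overlap length). Ties are broken by smaller ncRNA start, then
#' lexicographically smaller ncRNA id, so the result is deterministic and
#' independent of input order. A ncRNA may still appear under several genes;
#' the resolution is per gene only.
#'
#' @param pairs opposite-strand filtered pairs.
#' @return a `PairCatalog`: one row per gene, in gene first-appearance order.
#' @export
select_longest_per_gene <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(structure(pairs, class = c("PairCatalog", "data.frame")))
  }
  ord <- order(-pairs$ncrna_length, pairs$ncrna_start, pairs$ncrna_id,
               method = "radix")
  best <- ord[!duplicated(pairs$gene_id[ord])]
  # restore gene input order
  best <- best[order(match(pairs$gene_id[best], unique(pairs$gene_id)))]
  structure(pairs[best, , drop = FALSE],
            class = c("PairCatalog", "data.frame"))
}

#' Build the sense/antisense pair catalog
#'
#' Composes the three cataloging rules: overlap join, opposite-strand filter,
#' longest-ncRNA-per-gene resolution. The returned catalog carries a
#' `summary` attribute with the intermediate counts: candidate (strand-blind)
#' pairs, opposite-strand pairs, distinct ncRNAs and distinct genes after the
#' strand filter, and final pairs.
#'
#' @param genes `FeatureSet` of genes.
#' @param ncrnas `FeatureSet` of non-coding transcripts.
#' @return a `PairCatalog` with attribute `summary` (named list of counts).
#' @export
build_pair_catalog <- function(genes, ncrnas) {
  candidates <- overlap_join(genes, ncrnas)
  opposite <- filter_opposite_strand(candidates)
  catalog <- select_longest_per_gene(opposite)
  attr(catalog, "summary") <- list(
    n_candidate_pairs = nrow(candidates),
    n_opposite_pairs  = nrow(opposite),
    n_distinct_ncrnas = length(unique(opposite$ncrna_id)),
    n_distinct_genes  = length(unique(opposite$gene_id)),
    n_catalog_pairs   = nrow(catalog)
  )
  catalog
}

#' @export
print.PairCatalog <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("PairCatalog: %d sense/antisense pairs\n", nrow(x)))
  if (!is.null(s)) {
    cat(sprintf("  candidates %d | opposite-strand %d (%d ncRNAs x %d genes)\n",
                s$n_candidate_pairs, s$n_opposite_pairs,
                s$n_distinct_ncrnas, s$n_distinct_genes))
  }
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write a pair catalog to TSV
#'
#' Columns: gene_id, ncrna_id, chrom, gene_strand, ncrna_strand,
#' overlap_start, overlap_end, overlap_length, ncrna_length.
#'
#' @param catalog a `PairCatalog`.
#' @param path output file.
#' @export
write_pair_catalog <- function(catalog, path) {
  cols <- c("gene_id", "ncrna_id", "chrom", "gene_strand", "ncrna_strand",
            "overlap_start", "overlap_end", "overlap_length", "ncrna_length")
  utils::write.table(as.data.frame(catalog)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a pair catalog written by [write_pair_catalog()]
#'
#' @param path TSV file.
#' @return a `PairCatalog` data.frame (no summary attribute).
#' @export
read_pair_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  structure(df, class = c("PairCatalog", "data.frame"))
}
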