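# Naive O(n*m) reference for the pair catalog, independent of the package's
# interval-tree join: enumerate every gene x ncRNA combination, apply the
# three cataloging rules directly, and resolve ties by the documented rule.
brute_force_catalog <- function(genes, ncrnas) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    best <- NULL
    for (j in seq_len(nrow(ncrnas))) {
      if (genes$chrom[i] != ncrnas$chrom[j]) next
      os <- max(genes$start[i], ncrnas$start[j])
      oe <- min(genes$end[i], ncrnas$end[j])
      if (os > oe) next
      if (genes$strand[i] == ncrnas$strand[j]) next
      cand <- list(ncrna_id = ncrnas$feature_id[j],
                   nlen = ncrnas$end[j] - ncrnas$start[j] + 1L,
                   nstart = ncrnas$start[j], os = os, oe = oe)
      if (is.null(best) ||
          cand$nlen > best$nlen ||
          (cand$nlen == best$nlen && cand$nstart < best$nstart) ||
          (cand$nlen == best$nlen && cand$nstart == best$nstart &&
           cand$ncrna_id < best$ncrna_id)) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$feature_id[i], ncrna_id = best$ncrna_id,
        overlap_start = best$os, overlap_end = best$oe,
        ncrna_length = best$nlen, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), ncrna_id = character(0),
                      overlap_start = integer(0), overlap_end = integer(0),
                      ncrna_length = integer(0)))
  }
  do.call(rbind, rows)
}

# Vectorized variant of the same all-pairs enumeration, for large random
# instances: full cross join, then the three rules.
brute_force_catalog_fast <- function(genes, ncrnas) {
  gi <- rep(seq_len(nrow(genes)), each = nrow(ncrnas))
  ni <- rep(seq_len(nrow(ncrnas)), times = nrow(genes))
  keep <- genes$chrom[gi] == ncrnas$chrom[ni] &
    genes$strand[gi] != ncrnas$strand[ni] &
    pmax(genes$start[gi], ncrnas$start[ni]) <=
      pmin(genes$end[gi], ncrnas$end[ni])
  gi <- gi[keep]; ni <- ni[keep]
  if (length(gi) == 0) {
    return(data.frame(gene_id = character(0), ncrna_id = character(0),
                      overlap_start = integer(0), overlap_end = integer(0),
                      ncrna_length = integer(0)))
  }
  nlen <- ncrnas$end[ni] - ncrnas$start[ni] + 1L
  ord <- order(gi, -nlen, ncrnas$start[ni], ncrnas$feature_id[ni],
               method = "radix")
  gi <- gi[ord]; ni <- ni[ord]
  first <- !duplicated(gi)
  gi <- gi[first]; ni <- ni[first]
  data.frame(
    gene_id = genes$feature_id[gi], ncrna_id = ncrnas$feature_id[ni],
    overlap_start = pmax(genes$start[gi], ncrnas$start[ni]),
    overlap_end = pmin(genes$end[gi], ncrnas$end[ni]),
    ncrna_length = ncrnas$end[ni] - ncrnas$start[ni] + 1L,
    stringsAsFactors = FALSE)
}

# Random feature sets over a few toy chromosomes.
random_instance <- function(n_genes, n_ncrnas, n_chroms = 3,
                            span = 50000L) {
  mk <- function(n, prefix, kind) {
    if (n == 0) {
      return(feature_set(data.frame(
        feature_id = character(0), chrom = character(0), start = integer(0),
        end = integer(0), strand = character(0), kind = character(0),
        stringsAsFactors = FALSE), kind_default = kind))
    }
    start <- sample.int(span, n, replace = TRUE)
    len <- sample.int(500L, n, replace = TRUE)
    feature_set(data.frame(
      feature_id = paste0(prefix, seq_len(n)),
      chrom = paste0("chr", sample.int(n_chroms, n, replace = TRUE)),
      start = start, end = start + len - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      kind = kind, stringsAsFactors = FALSE), kind_default = kind)
  }
  list(genes = mk(n_genes, "g", "gene"),
       ncrnas = mk(n_ncrnas, "n", "ncRNA_other"))
}

# Sort a catalog-shaped data.frame into a canonical order for comparison.
canonical_pairs <- function(df) {
  df <- as.data.frame(df)[, c("gene_id", "ncrna_id",
                              "overlap_start", "overlap_end")]
  out <- df[order(df$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Small deterministic NB count fixture with condition labels.
toy_count_matrix <- function(n_feat = 50, nC = 3, nT = 3, mu = 200,
                             alpha = 0.05, lfc = 0, seed = 42) {
  set.seed(seed)
  ids <- sprintf("f%03d", seq_len(n_feat))
  samples <- c(sprintf("c%d", seq_len(nC)), sprintf("t%d", seq_len(nT)))
  cond <- setNames(rep(c("control", "treatment"), c(nC, nT)), samples)
  m <- sapply(seq_along(samples), function(j) {
    mean_j <- mu * 2^(lfc * (cond[j] == "treatment"))
    if (alpha == 0) rpois(n_feat, mean_j)
    else rnbinom(n_feat, mu = mean_j, size = 1 / alpha)
  })
  dimnames(m) <- list(ids, samples)
  count_matrix(m, cond)
}
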