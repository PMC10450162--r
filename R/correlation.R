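#' Select catalog pairs significant at a gene-level FDR threshold
#'
#' Retains pairs whose sense gene has BH q-value strictly below
#' `fdr_threshold`; by default the antisense ncRNA's q-value plays no role in
#' selection. Catalog genes missing from the DE table are dropped (the count
#' of dropped pairs is reported in the `n_dropped_missing` attribute and via
#' a message).
#'
#' @param catalog a `PairCatalog`.
#' @param de_genes `DEResult` for genes.
#' @param fdr_threshold significance cutoff in (0, 1]; pairs with
#'   `qvalue < fdr_threshold` are kept (strict inequality).
#' @param de_ncrnas optional `DEResult` for ncRNAs, consulted only when
#'   `require_ncrna_significant = TRUE`.
#' @param require_ncrna_significant also require the ncRNA q-value below the
#'   threshold (sensitivity analysis; default FALSE).
#' @return the retained catalog rows with a `gene_qvalue` column appended.
#' @export
filter_significant <- function(catalog, de_genes, fdr_threshold,
                               de_ncrnas = NULL,
                               require_ncrna_significant = FALSE) {
  if (!is.numeric(fdr_threshold) || length(fdr_threshold) != 1 ||
      is.na(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1) {
    stop("fdr_threshold must be a single number in (0, 1]")
  }
  idx <- match(catalog$gene_id, de_genes$feature_id)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    message(n_missing, " catalog pair(s) dropped: gene absent from DE results")
  }
  keep <- !is.na(idx)
  out <- catalog[keep, , drop = FALSE]
  out$gene_qvalue <- de_genes$qvalue[idx[keep]]
  sig <- out$gene_qvalue < fdr_threshold
  if (require_ncrna_significant) {
    if (is.null(de_ncrnas)) {
      stop("require_ncrna_significant = TRUE needs de_ncrnas")
    }
    nq <- de_ncrnas$qvalue[match(out$ncrna_id, de_ncrnas$feature_id)]
    sig <- sig & !is.na(nq) & nq < fdr_threshold
  }
  out <- out[sig, , drop = FALSE]
  attr(out, "n_dropped_missing") <- n_missing
  out
}

#' Pearson product-moment correlation with t-based significance
#'
#' Two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both non-constant.
#' @return list with elements `r` and `pvalue`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations for a correlation")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), pvalue = ct$p.value)
}

#' Correlate sense and antisense log2 fold-changes over a pair catalog
#'
#' Joins gene and ncRNA log2 fold-changes by catalog pair, applies the
#' gene-level FDR selection, and computes the Pearson correlation of the two
#' fold-change vectors. This is the statistic summarizing whether antisense
#' transcription tracks sense transcription between two conditions.
#'
#' @param catalog a `PairCatalog`.
#' @param de_genes,de_ncrnas `DEResult` tables computed on the same contrast
#'   orientation (treatment over control).
#' @param fdr_threshold gene-level FDR cutoff (default 0.25).
#' @param require_ncrna_significant see [filter_significant()].
#' @return object of class `PairCorrelationResult`: list with `n_pairs`, `r`,
#'   `pvalue`, `fdr_threshold`, `status` (`"ok"` or `"undefined"`), and
#'   `table` (per-pair data.frame with `gene_id`, `ncrna_id`, `gene_log2fc`,
#'   `ncrna_log2fc`, `gene_qvalue`). `r` is `NA` with a warning when fewer
#'   than 3 pairs survive or a fold-change vector is constant.
#' @export
correlate_pairs <- function(catalog, de_genes, de_ncrnas,
                            fdr_threshold = 0.25,
                            require_ncrna_significant = FALSE) {
  retained <- filter_significant(catalog, de_genes, fdr_threshold,
                                 de_ncrnas = de_ncrnas,
                                 require_ncrna_significant = require_ncrna_significant)
  gidx <- match(retained$gene_id, de_genes$feature_id)
  nidx <- match(retained$ncrna_id, de_ncrnas$feature_id)
  keep <- !is.na(nidx)
  n_missing_nc <- sum(!keep)
  if (n_missing_nc > 0) {
    message(n_missing_nc, " pair(s) dropped: ncRNA absent from DE results")
  }
  tab <- data.frame(
    gene_id      = retained$gene_id[keep],
    ncrna_id     = retained$ncrna_id[keep],
    gene_log2fc  = de_genes$log2fc[gidx[keep]],
    ncrna_log2fc = de_ncrnas$log2fc[nidx[keep]],
    gene_qvalue  = retained$gene_qvalue[keep],
    stringsAsFactors = FALSE
  )
  res <- list(n_pairs = nrow(tab), r = NA_real_, pvalue = NA_real_,
              fdr_threshold = fdr_threshold, status = "undefined",
              table = tab)
  if (nrow(tab) >= 3 &&
      stats::sd(tab$gene_log2fc) > 0 && stats::sd(tab$ncrna_log2fc) > 0) {
    pr <- pearson(tab$gene_log2fc, tab$ncrna_log2fc)
    res$r <- pr$r
    res$pvalue <- pr$pvalue
    res$status <- "ok"
  } else {
    warning("correlation undefined: fewer than 3 retained pairs ",
            "or constant fold-change vector")
  }
  class(res) <- "PairCorrelationResult"
  res
}

#' @export
print.PairCorrelationResult <- function(x, ...) {
  cat(sprintf("Sense/antisense log2FC correlation (gene FDR < %g)\n",
              x$fdr_threshold))
  cat(sprintf("  pairs retained: %d\n", x$n_pairs))
  if (x$status == "ok") {
    cat(sprintf("  Pearson r = %.3f, p = %.3g\n", x$r, x$pvalue))
  } else {
    cat("  r undefined (too few pairs or constant vector)\n")
  }
  invisible(x)
}
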