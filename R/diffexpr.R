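#' Two-condition count matrix
#'
#' Container for non-negative integer counts (features x samples) with a
#' control/treatment label per sample.
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param condition character vector (or named vector keyed by sample id)
#'   with values `"control"` / `"treatment"`, one per sample.
#' @return object of class `CountMatrix`: list with elements `counts`
#'   (integer matrix) and `condition` (named character).
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (any(is.na(counts))) stop("counts contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (!is.null(names(condition))) {
    missing <- setdiff(colnames(counts), names(condition))
    if (length(missing) > 0) {
      stop("no condition label for sample(s): ", paste(missing, collapse = ", "))
    }
    condition <- condition[colnames(counts)]
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop("need one condition label per sample")
  }
  if (!all(condition %in% c("control", "treatment"))) {
    stop("condition labels must be 'control' or 'treatment'")
  }
  names(condition) <- colnames(counts)
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  structure(list(counts = counts, condition = condition),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("CountMatrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: each count is divided by its
#' feature's geometric mean across samples, and the size factor is the
#' per-sample median of those ratios over features whose geometric mean is
#' positive (i.e. features with no zero count). Factors are not renormalized
#' afterward.
#'
#' @param x a `CountMatrix` or plain count matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "CountMatrix")) x$counts else as.matrix(x)
  log_geomean <- rowMeans(log(counts))
  use <- is.finite(log_geomean)
  if (!any(use)) {
    stop("no feature has all-positive counts across samples; ",
         "filter low-count features or add a pseudocount before normalizing")
  }
  apply(counts[use, , drop = FALSE], 2, function(cj) {
    stats::median(cj / exp(log_geomean[use]))
  })
}

#' Per-feature method-of-moments dispersion
#'
#' Negative-binomial dispersion alpha in the Var = mu + alpha * mu^2
#' parameterization, estimated on normalized counts with condition means
#' removed: `alpha_i = max(alpha_floor, (v_i - m_i) / m_i^2)` where `m_i` is
#' the grand mean of normalized counts and `v_i` the pooled within-condition
#' variance (df = n - 2). Features with `m_i = 0` get the floor and are
#' flagged untestable (attribute `untestable`).
#'
#' @param x a `CountMatrix`.
#' @param sf size factors (default [size_factors()]).
#' @param alpha_floor lower bound on the estimate (default 1e-8).
#' @return numeric vector of dispersions, named by feature, with logical
#'   attribute `untestable`.
#' @export
estimate_dispersion <- function(x, sf = NULL, alpha_floor = 1e-8) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(sf)) sf <- size_factors(x)
  check_two_group_design(x)
  norm <- sweep(x$counts, 2, sf, "/")
  m <- rowMeans(norm)
  groups <- split(seq_along(x$condition), x$condition)
  ss <- 0
  df <- ncol(norm) - length(groups)
  for (idx in groups) {
    sub <- norm[, idx, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- ss / df
  untestable <- m == 0
  alpha <- ifelse(untestable, alpha_floor,
                  pmax(alpha_floor, (v - m) / m^2))
  names(alpha) <- rownames(x$counts)
  attr(alpha, "untestable") <- untestable
  alpha
}

check_two_group_design <- function(x) {
  tab <- table(factor(x$condition, levels = c("control", "treatment")))
  if (any(tab < 2)) {
    stop("need >= 2 samples in each of control and treatment (have ",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  }
  invisible(tab)
}

#' Negative-binomial Wald test for differential expression
#'
#' Tests treatment versus control per feature. With normalized condition
#' means `muT`, `muC` and pseudocount `c0`:
#' \deqn{log2FC = log2((muT + c0) / (muC + c0))}
#' The sampling variance of each condition mean is the NB model variance
#' `(mu + alpha mu^2) / n_c`; the standard error of the log2 fold-change
#' follows by the delta method,
#' `se = (1/ln 2) * sqrt(Var(muT)/(muT+c0)^2 + Var(muC)/(muC+c0)^2)`,
#' and `z = log2FC / se` is referred to the standard normal (two-sided).
#' Untestable features (zero counts everywhere) get p = 1. Q-values are
#' Benjamini-Hochberg over all reported p-values.
#'
#' @param x a `CountMatrix` with >= 2 samples per condition.
#' @param sf size factors (default [size_factors()]).
#' @param dispersions per-feature alpha (default [estimate_dispersion()]).
#' @param pseudocount `c0` added to both condition means (default 0.5).
#' @return data.frame of class `DEResult` with columns `feature_id`,
#'   `base_mean`, `log2fc`, `se`, `wald_z`, `pvalue`, `qvalue`, `untestable`.
#' @export
nb_wald_test <- function(x, sf = NULL, dispersions = NULL, pseudocount = 0.5) {
  stopifnot(inherits(x, "CountMatrix"))
  check_two_group_design(x)
  if (is.null(sf)) sf <- size_factors(x)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(x, sf)
  untestable <- attr(dispersions, "untestable")
  if (is.null(untestable)) untestable <- rep(FALSE, nrow(x$counts))
  norm <- sweep(x$counts, 2, sf, "/")
  muC <- rowMeans(norm[, x$condition == "control", drop = FALSE])
  muT <- rowMeans(norm[, x$condition == "treatment", drop = FALSE])
  nC <- sum(x$condition == "control")
  nT <- sum(x$condition == "treatment")
  alpha <- as.numeric(dispersions)
  log2fc <- log2((muT + pseudocount) / (muC + pseudocount))
  var_muC <- (muC + alpha * muC^2) / nC
  var_muT <- (muT + alpha * muT^2) / nT
  se <- (1 / log(2)) * sqrt(var_muT / (muT + pseudocount)^2 +
                            var_muC / (muC + pseudocount)^2)
  wald_z <- ifelse(log2fc == 0, 0, log2fc / se)
  pvalue <- ifelse(untestable, 1, 2 * stats::pnorm(-abs(wald_z)))
  res <- data.frame(
    feature_id = rownames(x$counts),
    base_mean  = rowMeans(norm),
    log2fc     = log2fc,
    se         = se,
    wald_z     = wald_z,
    pvalue     = pvalue,
    qvalue     = bh_adjust(pvalue),
    untestable = untestable,
    row.names  = NULL,
    stringsAsFactors = FALSE
  )
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, aligned to input
#' order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a count matrix and sample sheet from TSV
#'
#' Count TSV: header row, first column `feature_id`, one column per sample.
#' Sample sheet TSV: columns `sample_id`, `condition`.
#'
#' @param counts_path count matrix TSV.
#' @param samples_path sample sheet TSV.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") {
    stop("first column of ", counts_path, " must be 'feature_id'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  sheet <- read_sample_sheet(samples_path)
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing) > 0) {
    stop("sample sheet lacks sample(s): ", paste(missing, collapse = ", "))
  }
  cond <- stats::setNames(sheet$condition, sheet$sample_id)
  count_matrix(m, cond[colnames(m)])
}

#' Read a sample sheet TSV (`sample_id`, `condition`)
#'
#' @param path TSV file.
#' @return data.frame with columns `sample_id`, `condition`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(sheet))) {
    stop("sample sheet ", path, " must have columns sample_id, condition")
  }
  if (!all(sheet$condition %in% c("control", "treatment"))) {
    stop("sample sheet conditions must be 'control' or 'treatment'")
  }
  sheet
}

#' Write DE results to TSV
#'
#' @param res a `DEResult`.
#' @param path output file.
#' @export
write_de_results <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read DE results written by [write_de_results()]
#'
#' @param path TSV file.
#' @return a `DEResult` data.frame.
#' @export
read_de_results <- function(path) {
  res <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  class(res) <- c("DEResult", "data.frame")
  res
}
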