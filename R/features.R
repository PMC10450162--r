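#' Genomic feature sets
#'
#' A `FeatureSet` is an ordered table of single-interval, stranded genomic
#' annotations (genes or non-coding transcripts such as CUTs, SUTs and XUTs).
#' Coordinates are stored 1-based inclusive (the GFF convention); all
#' conversions from other conventions happen at the I/O boundary.
#'
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end`, `strand` and optionally `kind`.
#' @param label short label for the set (e.g. `"genes"`, `"ncRNAs"`).
#' @param kind_default kind assigned to rows lacking a `kind` column.
#'
#' @return An object of class `FeatureSet` (a validated data.frame with
#'   columns `feature_id`, `chrom`, `start`, `end`, `strand`, `kind`).
#' @export
feature_set <- function(features, label = "features", kind_default = "gene") {
  stopifnot(is.data.frame(features))
  required <- c("feature_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"kind" %in% names(features)) features$kind <- kind_default
  df <- data.frame(
    feature_id = as.character(features$feature_id),
    chrom      = as.character(features$chrom),
    start      = as.integer(features$start),
    end        = as.integer(features$end),
    strand     = as.character(features$strand),
    kind       = as.character(features$kind),
    stringsAsFactors = FALSE
  )
  validate_features(df)
  structure(df, class = c("FeatureSet", "data.frame"), label = label)
}

valid_kinds <- c("gene", "CUT", "SUT", "XUT", "ncRNA_other")

validate_features <- function(df) {
  # strand must be declared: unstranded annotations cannot enter an
  # opposite-strand analysis
  bad_strand <- !(df$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("invalid strand (must be '+' or '-') for feature(s): ",
         paste(utils::head(df$feature_id[bad_strand], 5), collapse = ", "))
  }
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("non-integer start/end coordinate(s)")
  }
  if (any(df$start < 1L)) stop("start coordinates must be >= 1 (1-based)")
  if (any(df$end < df$start)) {
    stop("end < start for feature(s): ",
         paste(utils::head(df$feature_id[df$end < df$start], 5), collapse = ", "))
  }
  if (any(df$feature_id == "" | is.na(df$feature_id))) {
    stop("empty feature_id")
  }
  dup <- duplicated(df$feature_id)
  if (any(dup)) {
    stop("duplicate feature_id(s): ",
         paste(unique(utils::head(df$feature_id[dup], 5)), collapse = ", "))
  }
  bad_kind <- !(df$kind %in% valid_kinds)
  if (any(bad_kind)) {
    stop("unknown feature kind(s): ",
         paste(unique(df$kind[bad_kind]), collapse = ", "),
         " (allowed: ", paste(valid_kinds, collapse = ", "), ")")
  }
  invisible(df)
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat(sprintf("FeatureSet '%s': %d features on %d sequence(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Feature lengths in bases
#'
#' @param x a `FeatureSet`.
#' @return integer vector, `end - start + 1` per feature.
#' @export
feature_lengths <- function(x) {
  stopifnot(inherits(x, "FeatureSet"))
  x$end - x$start + 1L
}

#' Read genomic features from GFF3, BED6 or TSV
#'
#' Normalizes the three supported dialects into the internal 1-based
#' inclusive representation:
#' \itemize{
#'   \item \strong{bed6}: 0-based half-open; starts are incremented by 1 on
#'     read. Columns chrom, start, end, name, score, strand.
#'   \item \strong{gff3}: 1-based inclusive, read as-is. Only records whose
#'     `type` is in `gff_types` are kept; the `ID` attribute (fallback `Name`,
#'     then a generated `<type>_<record number>`) becomes the feature id.
#'   \item \strong{tsv}: 1-based inclusive; header columns `id`, `chrom`,
#'     `start`, `end`, `strand`, optional `kind`.
#' }
#' Chromosome names are compared verbatim downstream (no "chr" aliasing), so
#' gene and ncRNA inputs must use the same naming scheme.
#'
#' @param path input file.
#' @param format one of `"gff3"`, `"bed6"`, `"tsv"`. Default guesses from the
#'   file extension (`.gff`/`.gff3` -> gff3, `.bed` -> bed6, otherwise tsv).
#' @param kind_default kind assigned when the input carries none.
#' @param label label for the returned set.
#' @param gff_types GFF3 `type` values to keep (default `"gene"`).
#' @return a [feature_set()].
#' @export
read_features <- function(path, format = c("auto", "gff3", "bed6", "tsv"),
                          kind_default = "gene", label = NULL,
                          gff_types = "gene") {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed6", "tsv")
  }
  if (is.null(label)) label <- basename(path)
  df <- switch(format,
    bed6 = read_bed6(path),
    tsv  = read_feature_tsv(path),
    gff3 = read_gff3_features(path, gff_types)
  )
  feature_set(df, label = label, kind_default = kind_default)
}

read_bed6 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop(sprintf("BED6 parse error at line %d of %s: expected >= 6 tab-separated fields, got %d",
                 idx[which(nf < 6)[1]], path, nf[nf < 6][1]))
  }
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0   <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0) {
    stop(sprintf("BED6 parse error at line %d of %s: non-numeric coordinates",
                 idx[bad[1]], path))
  }
  data.frame(
    feature_id = vapply(fields, `[`, "", 4L),
    chrom      = vapply(fields, `[`, "", 1L),
    start      = start0 + 1L,  # 0-based half-open -> 1-based inclusive
    end        = end0,
    strand     = vapply(fields, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
}

read_feature_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "#")
  required <- c("id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("TSV feature table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    # +1 for the header line
    stop(sprintf("TSV parse error at line %d of %s: non-numeric coordinates",
                 bad[1] + 1L, path))
  }
  out <- data.frame(feature_id = df$id, chrom = df$chrom, start = start,
                    end = end, strand = df$strand, stringsAsFactors = FALSE)
  if ("kind" %in% names(df)) out$kind <- df$kind
  out
}

read_gff3_features <- function(path, gff_types) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  keep <- g$type %in% gff_types
  if (!any(keep)) {
    stop("no records of type ", paste(gff_types, collapse = "/"),
         " found in ", path)
  }
  record_no <- which(keep)
  g <- g[keep, , drop = FALSE]
  id <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  nm <- if ("Name" %in% names(g)) as.character(g$Name) else rep(NA_character_, nrow(g))
  id <- ifelse(is.na(id) | id == "", nm, id)
  fallback <- paste0(as.character(g$type), "_", record_no)
  id <- ifelse(is.na(id) | id == "", fallback, id)
  data.frame(
    feature_id = id,
    chrom      = as.character(g$seqid),
    start      = g$start,
    end        = g$end,
    strand     = as.character(g$strand),
    stringsAsFactors = FALSE
  )
}

#' Write a FeatureSet to BED6
#'
#' Starts are decremented by 1 on write (1-based inclusive -> 0-based
#' half-open), so a write/read round trip is exact.
#'
#' @param x a `FeatureSet`.
#' @param path output file.
#' @export
write_features_bed <- function(x, path) {
  stopifnot(inherits(x, "FeatureSet"))
  bed <- data.frame(x$chrom, x$start - 1L, x$end, x$feature_id, 0L, x$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a FeatureSet to TSV (1-based inclusive, with header)
#'
#' @param x a `FeatureSet`.
#' @param path output file.
#' @export
write_features_tsv <- function(x, path) {
  stopifnot(inherits(x, "FeatureSet"))
  out <- data.frame(id = x$feature_id, chrom = x$chrom, start = x$start,
                    end = x$end, strand = x$strand, kind = x$kind)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# FeatureSet -> GRanges (strand preserved); internal. A shared seqlevels
# universe keeps cross-set operations quiet when chromosome sets differ.
as_granges <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = x$strand,
    feature_id = x$feature_id
  )
}
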