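#' Abundance matrices
#'
#' An abundance matrix is a numeric matrix with features as rows and samples
#' as columns, carrying a `normalization` attribute that is either
#' `"raw_lengthnorm"` (read counts divided by gene length in bp) or
#' `"relative"` (each sample column rescaled to sum to 1 within its feature
#' universe).
#'
#' @param values numeric matrix, features x samples, non-negative, with
#'   row and column names.
#' @param normalization `"raw_lengthnorm"` or `"relative"`.
#' @return the matrix with class `abundance_matrix` and the tag attached.
#' @export
abundance_matrix <- function(values, normalization = c("raw_lengthnorm", "relative")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values))
    stop("abundance values must be a numeric matrix")
  if (any(values < 0)) stop("abundance values must be non-negative")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("abundance matrix needs feature (row) and sample (column) names")
  structure(values, normalization = normalization,
            class = c("abundance_matrix", class(values)))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d features x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "normalization")))
  print(utils::head(unclass(x), 5L))
  invisible(x)
}

#' Drop genes with too few mapped reads
#'
#' Retains exactly the genes whose total mapped reads, summed over all
#' samples, reach `min_total_reads` (default 2, i.e. genes with at least two
#' mapped reads are kept). The sample set is unchanged; an empty result is
#' allowed.
#'
#' @param counts integer matrix of mapped reads, genes x samples.
#' @param min_total_reads minimum summed reads for a gene to be retained.
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, min_total_reads = 2) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0)) stop("read counts must be non-negative")
  keep <- rowSums(counts) >= min_total_reads
  counts[keep, , drop = FALSE]
}

#' Gene-length-normalized abundance
#'
#' Gene abundance is the mapped-read count divided by the gene length in bp:
#' `value(g, s) = count(g, s) / length_bp(g)`. No per-kilobase rescaling is
#' applied; downstream statistics use only relative comparisons.
#'
#' @param counts integer matrix, genes x samples, with gene row names.
#' @param catalog data.frame with columns `gene_id` and `length_bp`.
#' @return an [abundance_matrix()] tagged `raw_lengthnorm`.
#' @export
gene_abundance <- function(counts, catalog) {
  stopifnot(is.matrix(counts), is.data.frame(catalog),
            all(c("gene_id", "length_bp") %in% names(catalog)))
  if (anyDuplicated(catalog$gene_id)) stop("gene ids in catalog must be unique")
  if (any(catalog$length_bp < 1)) stop("gene lengths must be >= 1 bp")
  len <- stats::setNames(catalog$length_bp, catalog$gene_id)
  missing <- setdiff(rownames(counts), catalog$gene_id)
  if (length(missing))
    stop("no catalog length for gene(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  vals <- counts / len[rownames(counts)]
  abundance_matrix(vals, "raw_lengthnorm")
}

#' Aggregate gene abundance into feature abundance
#'
#' The abundance of a feature (KEGG ortholog, module, enzyme family or genus)
#' is the sum of the abundances of the genes assigned to it. Genes without an
#' assignment are ignored; a gene may appear under several features (a KO can
#' belong to several modules), in which case its abundance contributes to each.
#'
#' @param abund an [abundance_matrix()] with genes as rows.
#' @param assignment either a named character vector (names = gene ids,
#'   values = feature ids) or a two-column data.frame `(gene_id, feature_id)`;
#'   repeated gene ids express many-to-many membership.
#' @return an [abundance_matrix()] with features as rows, same normalization
#'   tag as the input.
#' @export
aggregate_to_features <- function(abund, assignment) {
  if (is.data.frame(assignment)) {
    stopifnot(ncol(assignment) >= 2)
    gene_id <- as.character(assignment[[1L]])
    feature_id <- as.character(assignment[[2L]])
  } else {
    gene_id <- names(assignment)
    feature_id <- as.character(assignment)
  }
  keep <- gene_id %in% rownames(abund) & !is.na(feature_id)
  gene_id <- gene_id[keep]; feature_id <- feature_id[keep]
  if (!length(gene_id)) {
    out <- matrix(0, 0L, ncol(abund), dimnames = list(character(), colnames(abund)))
    return(abundance_matrix(out, attr(abund, "normalization") %||% "raw_lengthnorm"))
  }
  m <- unclass(abund)[gene_id, , drop = FALSE]
  out <- rowsum(m, group = feature_id, reorder = TRUE)
  abundance_matrix(out, attr(abund, "normalization") %||% "raw_lengthnorm")
}

#' Per-sample relative abundance
#'
#' Divides each sample column by its column sum so that every column sums to
#' one within the feature universe of the matrix; all-zero columns are left
#' at zero.
#'
#' @param abund an [abundance_matrix()].
#' @return an [abundance_matrix()] tagged `relative`.
#' @export
to_relative <- function(abund) {
  m <- unclass(abund)
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, cs[nz], "/")
  abundance_matrix(m, "relative")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
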