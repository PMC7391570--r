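#' BLAST/DIAMOND tabular hit sets
#'
#' Alignment hits follow the 12 standard BLAST `outfmt 6` columns plus the
#' query length (`qlen`) as column 13, which is required to compute query
#' coverage for the enzyme-gene assignment.
#'
#' @name alignment_hits
NULL

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qlen")

#' Validate a table of alignment hits
#'
#' @param hits data.frame with the columns in `outfmt 6` order plus `qlen`.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  miss <- setdiff(setdiff(HIT_COLUMNS, "qlen"), names(hits))
  if (length(miss)) stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(hits$evalue < 0)) stop("e-values must be non-negative")
  if (any(hits$pident < 0 | hits$pident > 100)) stop("percent identity must lie in [0, 100]")
  if (any(hits$length < 1)) stop("alignment length must be >= 1")
  hits
}

#' Read / write BLAST tabular hits
#'
#' `read_hits()` reads a headerless `outfmt 6` TSV with `qlen` appended as
#' column 13; `write_hits()` writes the same layout.
#'
#' @param path file path.
#' @param hits data.frame of hits.
#' @return `read_hits()` returns a data.frame with named columns.
#' @export
read_hits <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(dt) == 12L) dt$qlen <- NA_integer_
  if (ncol(dt) != 13L) stop("expected 12 or 13 columns in ", path, ", got ", ncol(dt))
  names(dt) <- HIT_COLUMNS
  validate_hits(dt)
}

#' @rdname read_hits
#' @export
write_hits <- function(hits, path) {
  validate_hits(hits)
  data.table::fwrite(hits[, intersect(HIT_COLUMNS, names(hits))], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Feature maps linking reference proteins to functional labels
#'
#' @param protein_to_ko data.frame `(protein_id, ko)`.
#' @param ko_to_module data.frame `(ko, module)`; many-to-many.
#' @param protein_to_enzyme data.frame `(protein_id, enzyme_family)` with
#'   families restricted to CutC, CntA, GrdH, TorA.
#' @param protein_to_taxon optional data.frame `(protein_id, node_id)` mapping
#'   taxonomy-reference proteins to taxonomy nodes.
#' @return a list of class `feature_maps`.
#' @export
feature_maps <- function(protein_to_ko, ko_to_module, protein_to_enzyme,
                         protein_to_taxon = NULL) {
  fam <- unique(protein_to_enzyme$enzyme_family)
  bad <- setdiff(fam, ENZYME_FAMILIES)
  if (length(bad))
    stop("unknown enzyme family label(s): ", paste(bad, collapse = ", "))
  structure(list(protein_to_ko = protein_to_ko,
                 ko_to_module = ko_to_module,
                 protein_to_enzyme = protein_to_enzyme,
                 protein_to_taxon = protein_to_taxon),
            class = "feature_maps")
}

#' The four TMA-synthesis enzyme families
#' @export
ENZYME_FAMILIES <- c("CutC", "CntA", "GrdH", "TorA")

# order hits so the first row per gene is the best: highest bit score,
# then smaller e-value, then lexicographically smallest subject id
best_hit_order <- function(h) {
  order(h$qseqid, -h$bitscore, h$evalue, h$sseqid, method = "radix")
}

#' Assign catalog genes to KEGG orthologs and modules
#'
#' A gene is assigned the KO of its highest-scoring hit among hits whose
#' subject carries a KO label and whose score exceeds `min_hsp_score`
#' (strict `>`, default 60, the conventional high-scoring segment pair
#' cutoff). Ties on score are broken by smaller e-value, then by subject id.
#' The gene's module set is every module containing the assigned KO. Genes
#' with no qualifying hit are left unannotated (absent from the result).
#'
#' @param hits alignment hit data.frame (see [read_hits()]).
#' @param maps a [feature_maps()] object.
#' @param min_hsp_score score threshold; hits must score strictly above it.
#' @return data.frame `(gene_id, ko, modules, subject_id, bit_score, e_value)`,
#'   one row per annotated gene, `modules` semicolon-joined.
#' @export
assign_kegg <- function(hits, maps, min_hsp_score = 60) {
  validate_hits(hits)
  p2k <- stats::setNames(maps$protein_to_ko$ko, maps$protein_to_ko$protein_id)
  h <- hits[hits$bitscore > min_hsp_score & hits$sseqid %in% names(p2k), , drop = FALSE]
  if (!nrow(h))
    return(data.frame(gene_id = character(), ko = character(), modules = character(),
                      subject_id = character(), bit_score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  h <- h[best_hit_order(h), , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  ko <- unname(p2k[h$sseqid])
  mod_by_ko <- split(maps$ko_to_module$module, maps$ko_to_module$ko)
  modules <- vapply(ko, function(k) {
    m <- mod_by_ko[[k]]
    if (is.null(m)) "" else paste(sort(unique(m)), collapse = ";")
  }, character(1L))
  data.frame(gene_id = h$qseqid, ko = ko, modules = unname(modules),
             subject_id = h$sseqid, bit_score = h$bitscore, e_value = h$evalue,
             stringsAsFactors = FALSE)
}

#' Assign catalog genes to TMA enzyme families
#'
#' Best-hit assignment against the enzyme-family reference: a hit qualifies
#' when its e-value is strictly below `max_evalue`, its percent identity
#' strictly above `min_identity`, and its query coverage
#' (`100 * alignment_length / query_length`) strictly above `min_coverage`.
#' Among qualifying hits the highest bit score wins (ties: smaller e-value,
#' then subject id).
#'
#' @param hits alignment hit data.frame; the `qlen` column must be present
#'   and non-missing for hits against enzyme reference proteins.
#' @param maps a [feature_maps()] object.
#' @param max_evalue,min_identity,min_coverage the three strict filters
#'   (defaults 1e-5, 50, 50).
#' @return data.frame `(gene_id, enzyme_family, subject_id, bit_score,
#'   e_value, identity, coverage)`, one row per assigned gene.
#' @export
assign_enzyme <- function(hits, maps, max_evalue = 1e-5,
                          min_identity = 50, min_coverage = 50) {
  validate_hits(hits)
  p2e <- stats::setNames(maps$protein_to_enzyme$enzyme_family,
                         maps$protein_to_enzyme$protein_id)
  h <- hits[hits$sseqid %in% names(p2e), , drop = FALSE]
  if (nrow(h)) {
    bad <- is.na(h$qlen) | h$qlen <= 0
    if (any(bad))
      stop("missing query length for hit ", h$qseqid[which(bad)[1L]], " -> ",
           h$sseqid[which(bad)[1L]], "; coverage cannot be computed")
  }
  cov <- 100 * h$length / h$qlen
  h <- h[h$evalue < max_evalue & h$pident > min_identity & cov > min_coverage, ,
         drop = FALSE]
  if (!nrow(h))
    return(data.frame(gene_id = character(), enzyme_family = character(),
                      subject_id = character(), bit_score = numeric(),
                      e_value = numeric(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  h <- h[best_hit_order(h), , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  data.frame(gene_id = h$qseqid, enzyme_family = unname(p2e[h$sseqid]),
             subject_id = h$sseqid, bit_score = h$bitscore, e_value = h$evalue,
             identity = h$pident, coverage = 100 * h$length / h$qlen,
             stringsAsFactors = FALSE)
}
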