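# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# odds ratio transliterated sum-by-sum from the definition
or_brute <- function(m, is_ctr, feature, af_numerator = TRUE) {
  k <- which(rownames(m) == feature)
  s_ctr <- 0; c_ctr <- 0; s_af <- 0; c_af <- 0
  for (s in seq_len(ncol(m))) {
    for (i in seq_len(nrow(m))) {
      v <- m[i, s]
      if (is_ctr[s]) {
        if (i == k) s_ctr <- s_ctr + v else c_ctr <- c_ctr + v
      } else {
        if (i == k) s_af <- s_af + v else c_af <- c_af + v
      }
    }
  }
  r <- (s_ctr / c_ctr) / (s_af / c_af)
  if (af_numerator) 1 / r else r
}

# LCA as intersection of root paths, deepest common element
lca_brute <- function(ids, tree) {
  paths <- lapply(ids, function(id) ancestor_path(tree, id))
  common <- Reduce(intersect, paths)
  common[[1L]]  # paths are ordered node -> root, first common is deepest
}

# random rooted tree as a node table: node i attaches to a random earlier node
random_tree_nodes <- function(n) {
  parent <- c("n1", sprintf("n%d", vapply(2:n, function(i)
    sample.int(i - 1L, 1L), integer(1L))))
  data.frame(node_id = sprintf("n%d", 1:n), parent_id = parent,
             rank = c("root", rep("clade", n - 1L)),
             name = sprintf("n%d", 1:n), stringsAsFactors = FALSE)
}

# best-hit annotation oracles: filter, then argmax by score with
# tie-breaks (smaller e-value, then lexicographic subject id)
kegg_brute <- function(hits, maps, min_score = 60) {
  p2k <- setNames(maps$protein_to_ko$ko, maps$protein_to_ko$protein_id)
  out <- list()
  for (g in sort(unique(hits$qseqid))) {
    h <- hits[hits$qseqid == g & hits$bitscore > min_score &
                hits$sseqid %in% names(p2k), , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    out[[g]] <- unname(p2k[h$sseqid[1L]])
  }
  unlist(out)
}

enzyme_brute <- function(hits, maps, max_e = 1e-5, min_id = 50, min_cov = 50) {
  p2e <- setNames(maps$protein_to_enzyme$enzyme_family,
                  maps$protein_to_enzyme$protein_id)
  out <- list()
  for (g in sort(unique(hits$qseqid))) {
    h <- hits[hits$qseqid == g & hits$sseqid %in% names(p2e), , drop = FALSE]
    h <- h[h$evalue < max_e & h$pident > min_id &
             100 * h$length / h$qlen > min_cov, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    out[[g]] <- unname(p2e[h$sseqid[1L]])
  }
  unlist(out)
}

# Spearman as rank-then-Pearson
spearman_brute <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# random hit table over a small gene / protein universe
random_hits <- function(n_hits, genes, proteins, qlen = 900L) {
  data.frame(
    qseqid = sample(genes, n_hits, replace = TRUE),
    sseqid = sample(proteins, n_hits, replace = TRUE),
    pident = round(runif(n_hits, 20, 100), 1),
    length = sample.int(qlen, n_hits, replace = TRUE),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L,
    evalue = signif(10^runif(n_hits, -30, -2), 3),
    bitscore = round(runif(n_hits, 30, 120), 1),
    qlen = qlen, stringsAsFactors = FALSE)
}

# a single synthetic hit row with sensible defaults
one_hit <- function(gene = "gA", subject = "P1", score = 61, evalue = 1e-10,
                    pident = 80, alen = 500L, qlen = 900L) {
  data.frame(qseqid = gene, sseqid = subject, pident = pident, length = alen,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = alen,
             sstart = 1L, send = alen, evalue = evalue, bitscore = score,
             qlen = qlen, stringsAsFactors = FALSE)
}

toy_maps <- function() {
  feature_maps(
    protein_to_ko = data.frame(protein_id = paste0("P", 1:6),
                               ko = paste0("K0000", 1:6)),
    ko_to_module = data.frame(ko = c("K00001", "K00001", "K00002"),
                              module = c("M0001", "M0002", "M0001")),
    protein_to_enzyme = data.frame(protein_id = paste0("E", 1:4),
                                   enzyme_family = ENZYME_FAMILIES))
}

# small deterministic taxonomy: root -> 2 phyla -> 4 families -> 8 genera
toy_taxonomy <- function() {
  taxonomy_tree(data.frame(
    node_id = c("root", "p1", "p2", "f1", "f2", "f3", "f4",
                paste0("g", 1:8)),
    parent_id = c("root", "root", "root", "p1", "p1", "p2", "p2",
                  c("f1", "f1", "f2", "f2", "f3", "f3", "f4", "f4")),
    rank = c("root", "phylum", "phylum", rep("family", 4), rep("genus", 8)),
    name = c("root", "p1", "p2", "f1", "f2", "f3", "f4", paste0("g", 1:8)),
    stringsAsFactors = FALSE))
}

rel_abund <- function(m) abundance_matrix(m, "relative")
raw_abund <- function(m) abundance_matrix(m, "raw_lengthnorm")

named_matrix <- function(vals, nr, nc, prefix = c("f", "s")) {
  matrix(vals, nr, nc, dimnames = list(sprintf("%s%d", prefix[1L], seq_len(nr)),
                                       sprintf("%s%d", prefix[2L], seq_len(nc))))
}

meta_ctr_af <- function(n_ctr, n_af, ids = NULL) {
  if (is.null(ids)) ids <- c(sprintf("s%d", seq_len(n_ctr + n_af)))
  sample_metadata(ids, c(rep("CTR", n_ctr), rep("AF", n_af)))
}
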