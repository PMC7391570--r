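#' Rooted, rank-labelled taxonomy tree
#'
#' Builds a taxonomy from a node table `(node_id, parent_id, rank, name)`.
#' The single root is the node whose parent is itself (or `NA`). Every other
#' node must reach the root through its parent chain; cycles are rejected.
#'
#' @param nodes data.frame with columns `node_id`, `parent_id`, `rank`,
#'   `name`.
#' @return an object of class `taxonomy_tree` with precomputed parent
#'   indices and depths (root depth 0).
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("node_id", "parent_id", "rank", "name") %in% names(nodes)))
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$node_id)) stop("node ids must be unique")
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$node_id)
  is_root <- is.na(nodes$parent_id) | nodes$parent_id == nodes$node_id
  if (sum(is_root) != 1L)
    stop("taxonomy must have exactly one root, found ", sum(is_root))
  unknown <- setdiff(nodes$parent_id[!is_root], nodes$node_id)
  if (length(unknown))
    stop("parent id(s) not present as nodes: ", paste(unknown, collapse = ", "))
  parent_idx <- unname(idx[nodes$parent_id])
  parent_idx[is_root] <- NA_integer_
  # depths by pointer-chasing; a chain longer than the node count is a cycle
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[is_root] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    chain <- i; j <- i
    while (is.na(depth[j])) {
      j <- parent_idx[j]
      chain <- c(chain, j)
      if (length(chain) > n + 1L) stop("cycle detected in taxonomy parent chain")
    }
    depth[chain] <- depth[j] + rev(seq_along(chain)) - 1L
  }
  structure(list(nodes = nodes, index = idx, parent_idx = parent_idx,
                 depth = depth, root = nodes$node_id[is_root]),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root '%s', ranks: %s\n",
              nrow(x$nodes), x$root,
              paste(unique(x$nodes$rank), collapse = " > ")))
  invisible(x)
}

node_index <- function(tree, ids) {
  i <- tree$index[as.character(ids)]
  if (anyNA(i))
    stop("unknown taxonomy node id: ", as.character(ids)[which(is.na(i))[1L]])
  unname(i)
}

#' Root path of a node
#'
#' @param tree a [taxonomy_tree()].
#' @param node_id a single node id.
#' @return character vector of node ids from the node up to the root.
#' @export
ancestor_path <- function(tree, node_id) {
  i <- node_index(tree, node_id)
  path <- i
  while (!is.na(tree$parent_idx[i])) {
    i <- tree$parent_idx[i]
    path <- c(path, i)
  }
  tree$nodes$node_id[path]
}

#' Lowest common ancestor of a node set
#'
#' Returns the deepest node that is an ancestor-or-self of every input node.
#' The LCA of a single node is that node; the result is invariant to input
#' order and to adding the LCA itself to the set.
#'
#' @param node_ids non-empty vector of node ids.
#' @param tree a [taxonomy_tree()].
#' @return a single node id.
#' @export
lca <- function(node_ids, tree) {
  ids <- unique(as.character(node_ids))
  if (!length(ids)) stop("lca needs at least one node")
  i <- node_index(tree, ids[1L])
  for (id in ids[-1L]) {
    j <- node_index(tree, id)
    while (tree$depth[i] > tree$depth[j]) i <- tree$parent_idx[i]
    while (tree$depth[j] > tree$depth[i]) j <- tree$parent_idx[j]
    while (i != j) { i <- tree$parent_idx[i]; j <- tree$parent_idx[j] }
  }
  tree$nodes$node_id[i]
}

#' Valid matches within the e-value window of the top hit
#'
#' Keeps the hits whose e-value is at most `factor` times the smallest
#' e-value of the set; the top hit is always kept. A top e-value of exactly 0
#' is handled exactly: only other zero-e-value hits qualify (10 x 0 = 0).
#'
#' @param hits_for_gene data.frame of alignment hits for one gene.
#' @param factor window width relative to the top e-value (default 10).
#' @return the qualifying subset of the input rows (empty in, empty out).
#' @export
valid_matches <- function(hits_for_gene, factor = 10) {
  if (!nrow(hits_for_gene)) return(hits_for_gene)
  e0 <- min(hits_for_gene$evalue)
  hits_for_gene[hits_for_gene$evalue <= max(factor * e0, e0), , drop = FALSE]
}

#' LCA-based taxonomic assignment of genes
#'
#' For each gene, takes the valid matches (e-value within `factor` times the
#' top hit), maps their subjects to taxonomy nodes, and assigns the lowest
#' common ancestor of those nodes. Hits whose subject has no taxon mapping
#' are skipped (a single warning reports how many). Genes whose every hit is
#' unmapped receive no assignment.
#'
#' @param hits alignment hit data.frame against the taxonomy-labelled
#'   reference.
#' @param tree a [taxonomy_tree()].
#' @param subject_taxon named character vector or data.frame
#'   `(protein_id, node_id)` mapping subjects to taxonomy nodes.
#' @param factor valid-match e-value window (default 10).
#' @return data.frame `(gene_id, node_id, rank, n_valid_matches)`; `node_id`
#'   is `NA` for unassignable genes.
#' @export
assign_taxa <- function(hits, tree, subject_taxon, factor = 10) {
  validate_hits(hits)
  if (is.data.frame(subject_taxon))
    subject_taxon <- stats::setNames(as.character(subject_taxon[[2L]]),
                                     as.character(subject_taxon[[1L]]))
  n_unmapped <- sum(!hits$sseqid %in% names(subject_taxon))
  if (n_unmapped > 0L)
    warning(n_unmapped, " hit(s) skipped: subject has no taxon mapping")
  rank_of <- stats::setNames(tree$nodes$rank, tree$nodes$node_id)
  by_gene <- split(hits, hits$qseqid)
  rows <- lapply(names(by_gene), function(g) {
    vm <- valid_matches(by_gene[[g]], factor = factor)
    taxa <- unique(unname(subject_taxon[vm$sseqid]))
    taxa <- taxa[!is.na(taxa)]
    if (!length(taxa))
      return(data.frame(gene_id = g, node_id = NA_character_,
                        rank = NA_character_, n_valid_matches = nrow(vm),
                        stringsAsFactors = FALSE))
    node <- lca(taxa, tree)
    data.frame(gene_id = g, node_id = node, rank = unname(rank_of[node]),
               n_valid_matches = nrow(vm), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genus-level abundance from taxonomic assignments
#'
#' Sums gene abundance per genus and sample. Genes assigned above genus
#' level (conflicting valid matches) and unassigned genes are excluded, so
#' total genus mass never exceeds the assigned genes' total mass.
#'
#' @param assignments output of [assign_taxa()].
#' @param gene_abund an [abundance_matrix()] with genes as rows.
#' @param tree a [taxonomy_tree()].
#' @return an [abundance_matrix()] with genus node ids as rows.
#' @export
genus_abundance <- function(assignments, gene_abund, tree) {
  gen <- assignments[!is.na(assignments$node_id) & assignments$rank == "genus", ,
                     drop = FALSE]
  aggregate_to_features(gene_abund,
                        data.frame(gene_id = gen$gene_id, feature_id = gen$node_id,
                                   stringsAsFactors = FALSE))
}
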