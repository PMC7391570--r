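#' Spearman correlation block between two abundance matrices
#'
#' Rank-based (midrank ties) correlation of every feature of `x` against
#' every feature of `y` across the shared samples, with two-sided p-values
#' from the t approximation on `n - 2` degrees of freedom. Constant features
#' have undefined rank correlation and are recorded as rho = 0 with p = 1.
#'
#' @param x,y [abundance_matrix()] objects with identical sample sets in
#'   identical order.
#' @return list with matrices `rho` and `p` (rows = features of `x`,
#'   columns = features of `y`) and the sample count `n`.
#' @export
spearman_matrix <- function(x, y) {
  if (!identical(colnames(x), colnames(y))) {
    diff <- union(setdiff(colnames(x), colnames(y)), setdiff(colnames(y), colnames(x)))
    stop("sample sets differ or are ordered differently; mismatch: ",
         if (length(diff)) paste(utils::head(diff, 5L), collapse = ", ")
         else "same set, different order")
  }
  n <- ncol(x)
  if (n < 3L) stop("Spearman correlation needs >= 3 samples")
  rho <- suppressWarnings(stats::cor(t(unclass(x)), t(unclass(y)),
                                     method = "spearman"))
  rho[is.na(rho)] <- 0
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[rho == 0] <- 1
  p <- pmin(p, 1)
  dimnames(p) <- dimnames(rho)
  list(rho = rho, p = p, n = n)
}

#' Threshold a correlation block into network edges
#'
#' Benjamini-Hochberg correction is applied over all tested pairs of the
#' block; an edge is kept when its q-value is below `alpha` and its absolute
#' correlation strictly exceeds `r_min`. Edges with `|rho| > r_strong` are
#' flagged strong; the `tier` column distinguishes q < 0.01 from q < 0.05.
#'
#' @param correlations output of [spearman_matrix()].
#' @param alpha FDR level (default 0.05).
#' @param r_min minimum absolute correlation, strict (default 0.4).
#' @param r_strong strong-edge threshold, strict (default 0.6).
#' @return data.frame `(source, target, rho, p_value, q_value, sign, strong,
#'   tier)` sorted by decreasing `|rho|`.
#' @export
select_edges <- function(correlations, alpha = 0.05, r_min = 0.4, r_strong = 0.6) {
  rho <- correlations$rho; p <- correlations$p
  q <- matrix(stats::p.adjust(as.vector(p), method = "BH"),
              nrow(p), ncol(p), dimnames = dimnames(p))
  keep <- which(q < alpha & abs(rho) > r_min, arr.ind = TRUE)
  if (!nrow(keep))
    return(data.frame(source = character(), target = character(),
                      rho = numeric(), p_value = numeric(), q_value = numeric(),
                      sign = character(), strong = logical(), tier = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(source = rownames(rho)[keep[, 1L]],
                    target = colnames(rho)[keep[, 2L]],
                    rho = rho[keep], p_value = p[keep], q_value = q[keep],
                    stringsAsFactors = FALSE)
  out$sign <- ifelse(out$rho >= 0, "positive", "negative")
  out$strong <- abs(out$rho) > r_strong
  out$tier <- ifelse(out$q_value < 0.01, "q<0.01", "q<0.05")
  out[order(-abs(out$rho), out$source, out$target), , drop = FALSE]
}

#' Assemble the genus - enzyme - function tripartite network
#'
#' Layers are ordered genera, enzyme genes, functions. The network keeps
#' only genera with at least one edge to an enzyme, all enzymes appearing in
#' either edge list, and functions with at least one edge to an enzyme;
#' edges connect adjacent layers only. Node ordering is stable: by layer,
#' then descending edge count, then id.
#'
#' @param genus_edges edge data.frame from [select_edges()] with genera as
#'   sources and enzyme families as targets.
#' @param function_edges edge data.frame with enzyme families as sources and
#'   functional features (KOs or modules) as targets.
#' @return object of class `tripartite_network` with elements `layers`,
#'   `nodes` (node_id, layer, degree) and `edges` (with a `layer_pair`
#'   column).
#' @export
build_tripartite <- function(genus_edges, function_edges) {
  ge <- genus_edges; fe <- function_edges
  ge$layer_pair <- if (nrow(ge)) "genus-enzyme" else character(0)
  fe$layer_pair <- if (nrow(fe)) "enzyme-function" else character(0)
  edges <- rbind(ge, fe)
  layer_nodes <- list(
    genera = unique(ge$source),
    enzyme_genes = unique(c(ge$target, fe$source)),
    functions = unique(fe$target))
  deg <- table(c(edges$source, edges$target))
  nodes <- do.call(rbind, lapply(names(layer_nodes), function(ly) {
    ids <- layer_nodes[[ly]]
    if (!length(ids)) return(NULL)
    d <- as.integer(deg[ids]); d[is.na(d)] <- 0L
    df <- data.frame(node_id = ids, layer = ly, degree = d,
                     stringsAsFactors = FALSE)
    df[order(-df$degree, df$node_id), , drop = FALSE]
  }))
  if (is.null(nodes))
    nodes <- data.frame(node_id = character(), layer = character(),
                        degree = integer(), stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(layers = c("genera", "enzyme_genes", "functions"),
                 nodes = nodes, edges = edges),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  counts <- table(factor(x$nodes$layer, levels = x$layers))
  cat(sprintf("tripartite_network: %s | %d edges\n",
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Export a tripartite network
#'
#' `write_network_json()` writes a Sankey-ready node-link JSON document
#' (layers, nodes with layer and degree, links weighted by `|rho|`);
#' `write_edges_tsv()` writes the flat edge table.
#'
#' @param net a [build_tripartite()] network.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_network_json <- function(net, path) {
  links <- net$edges
  doc <- list(
    layers = net$layers,
    nodes = net$nodes,
    links = data.frame(source = links$source, target = links$target,
                       weight = abs(links$rho), sign = links$sign,
                       strong = links$strong, tier = links$tier,
                       stringsAsFactors = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @param edges an edge data.frame from [select_edges()].
#' @export
write_edges_tsv <- function(edges, path) {
  data.table::fwrite(edges, path, sep = "\t")
  invisible(path)
}
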