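#' Pipeline configuration
#'
#' Bundles every stage threshold with its default: the printed values of the
#' methods the pipeline implements (gene inclusion at 2 total mapped reads,
#' KEGG score cutoff 60, enzyme filters 1e-5 / 50% / 50%, LCA e-value window
#' factor 10, OR classification at 2 and 0.5, FDR level 0.05, correlation
#' thresholds 0.4 and 0.6).
#'
#' @param min_total_reads gene inclusion filter (default 2).
#' @param min_hsp_score KEGG score cutoff, strict (default 60).
#' @param max_evalue,min_identity,min_coverage enzyme-assignment filters,
#'   strict (defaults 1e-5, 50, 50).
#' @param lca_factor valid-match e-value window (default 10).
#' @param or_high,or_low OR classification thresholds (defaults 2 and 0.5).
#' @param or_orientation `"af_numerator"` (OR > 2 means AF-enriched, the
#'   default) or `"ctr_numerator"` (the reciprocal ratio, with the control
#'   share in the numerator).
#' @param zero_handling `"pseudo"` or `"exact"`, see [or_values()].
#' @param alpha FDR level for tests and network edges (default 0.05).
#' @param r_min,r_strong correlation thresholds (defaults 0.4, 0.6).
#' @param function_universe `"module"` (default) or `"ko"`: which functional
#'   layer the enzyme genes are correlated against in the network.
#' @param contrasts contrast names to test (see [contrast_arms()]); arms
#'   with fewer than 2 samples are skipped with a message.
#' @param output_dir optional directory; when given, every stage output is
#'   written there along with a JSON run manifest.
#' @param seed integer seed recorded in the manifest.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_total_reads = 2, min_hsp_score = 60,
                            max_evalue = 1e-5, min_identity = 50,
                            min_coverage = 50, lca_factor = 10,
                            or_high = 2, or_low = 0.5,
                            or_orientation = c("af_numerator", "ctr_numerator"),
                            zero_handling = c("pseudo", "exact"),
                            alpha = 0.05, r_min = 0.4, r_strong = 0.6,
                            function_universe = c("module", "ko"),
                            contrasts = c("CTR_vs_AF", "PAF_vs_psAF",
                                          "PersLt12m_vs_PersGt12m"),
                            output_dir = NULL, seed = 1) {
  cfg <- list(min_total_reads = min_total_reads, min_hsp_score = min_hsp_score,
              max_evalue = max_evalue, min_identity = min_identity,
              min_coverage = min_coverage, lca_factor = lca_factor,
              or_high = or_high, or_low = or_low,
              or_orientation = match.arg(or_orientation),
              zero_handling = match.arg(zero_handling),
              alpha = alpha, r_min = r_min, r_strong = r_strong,
              function_universe = match.arg(function_universe),
              contrasts = contrasts, output_dir = output_dir,
              seed = as.integer(seed))
  num <- c("min_total_reads", "min_hsp_score", "max_evalue", "min_identity",
           "min_coverage", "lca_factor", "or_high", "or_low", "alpha",
           "r_min", "r_strong")
  bad <- num[vapply(cfg[num], function(v) !is.numeric(v) || v <= 0, logical(1L))]
  if (length(bad)) stop("threshold(s) must be positive: ", paste(bad, collapse = ", "))
  if (cfg$or_low >= cfg$or_high)
    stop("or_low (", cfg$or_low, ") must be < or_high (", cfg$or_high, ")")
  if (cfg$r_min >= cfg$r_strong)
    stop("r_min must be < r_strong")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys are
#'   [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

write_stage_table <- function(df, path, params) {
  hdr <- sprintf("# %s = %s", names(params),
                 vapply(params, function(p) paste(format(p), collapse = ","),
                        character(1L)))
  writeLines(hdr, path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  path
}

#' Read a stage output table
#'
#' Stage tables written by [run_pipeline()] start with `#`-prefixed
#' parameter lines; this reads the table and attaches those parameters as
#' the `"params"` attribute.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_stage_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  df <- data.table::fread(text = lines[setdiff(seq_along(lines), hdr)],
                          data.table = FALSE)
  attr(df, "params") <- sub("^# ", "", lines[hdr])
  df
}

abund_df <- function(abund) {
  data.table::as.data.table(unclass(abund), keep.rownames = "feature_id")
}

#' Run the full mining pipeline on a study bundle
#'
#' Executes the stages in order: gene inclusion filter, gene-length
#' normalization, KEGG/enzyme annotation, feature aggregation into the four
#' universes (KEGG orthologs, modules, enzyme families, genera via LCA
#' taxonomic assignment of the enzyme genes), per-universe relative
#' abundance, odds-ratio + Wilcoxon/BH enrichment tables per universe and
#' contrast, Spearman correlation edges (genera vs enzyme families, enzyme
#' families vs functions) and the tripartite network. Correlations are
#' computed on relative abundances across all samples pooled.
#'
#' @param bundle a [simulate_study()] result, a [read_fixture_bundle()]
#'   list, or a directory path containing a written bundle.
#' @param config a [pipeline_config()].
#' @return list of class `tma_pipeline_result` with elements
#'   `counts_filtered`, `gene_abund`, `annotations` (kegg + enzyme),
#'   `taxa` (assignments), `abundance` (per-universe relative matrices),
#'   `enrichment` (per universe x contrast), `edges` (genus + function),
#'   `network`, `manifest`, `log` (stage record counts).
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(bundle)) bundle <- read_fixture_bundle(bundle)
  b <- bundle
  if (!nrow(b$metadata)) stop("empty sample set: sample_metadata has no rows")
  log <- list()
  note <- function(stage, n_in, n_out)
    log[[stage]] <<- list(n_in = n_in, n_out = n_out)

  counts <- filter_genes(b$counts, config$min_total_reads)
  note("filter_genes", nrow(b$counts), nrow(counts))

  gene_ab <- gene_abundance(counts, b$catalog)

  kegg <- assign_kegg(b$hits_functional, b$maps, config$min_hsp_score)
  enz <- assign_enzyme(b$hits_functional, b$maps, config$max_evalue,
                       config$min_identity, config$min_coverage)
  note("assign_kegg", length(unique(b$hits_functional$qseqid)), nrow(kegg))
  note("assign_enzyme", length(unique(b$hits_functional$qseqid)), nrow(enz))

  tree <- taxonomy_tree(b$taxonomy)
  tax_hits <- b$hits_taxonomy[b$hits_taxonomy$qseqid %in% enz$gene_id, ,
                              drop = FALSE]
  taxa <- if (nrow(tax_hits))
    assign_taxa(tax_hits, tree, b$maps$protein_to_taxon, config$lca_factor)
  else data.frame(gene_id = character(), node_id = character(),
                  rank = character(), n_valid_matches = integer())
  note("assign_taxa", nrow(enz), sum(!is.na(taxa$node_id) & taxa$rank == "genus"))

  ko_map <- data.frame(gene_id = kegg$gene_id, feature_id = kegg$ko)
  mod_pairs <- do.call(rbind, lapply(which(nzchar(kegg$modules)), function(i)
    data.frame(gene_id = kegg$gene_id[i],
               feature_id = strsplit(kegg$modules[i], ";", fixed = TRUE)[[1L]])))
  if (is.null(mod_pairs))
    mod_pairs <- data.frame(gene_id = character(), feature_id = character())
  enz_map <- data.frame(gene_id = enz$gene_id, feature_id = enz$enzyme_family)

  abundance <- list(
    ko = to_relative(aggregate_to_features(gene_ab, ko_map)),
    module = to_relative(aggregate_to_features(gene_ab, mod_pairs)),
    enzyme = to_relative(aggregate_to_features(gene_ab, enz_map)),
    genus = to_relative(genus_abundance(taxa, gene_ab, tree)))

  enrichment <- list()
  for (ct in config$contrasts) {
    arms <- contrast_arms(b$metadata, ct)
    if (length(arms$a) < 2L || length(arms$b) < 2L)
      stop("contrast '", ct, "' has an empty or degenerate arm (",
           length(arms$a), " vs ", length(arms$b), " samples)")
    for (u in names(abundance)) {
      if (!nrow(abundance[[u]])) next
      enrichment[[paste(u, ct, sep = ".")]] <-
        enrichment_table(abundance[[u]], b$metadata, ct,
                         or_high = config$or_high, or_low = config$or_low,
                         orientation = config$or_orientation,
                         zero_handling = config$zero_handling)
    }
  }

  fun_ab <- abundance[[config$function_universe]]
  edges <- list(
    genus = if (nrow(abundance$genus) && nrow(abundance$enzyme))
      select_edges(spearman_matrix(abundance$genus, abundance$enzyme),
                   config$alpha, config$r_min, config$r_strong)
    else NULL,
    fun = if (nrow(abundance$enzyme) && nrow(fun_ab))
      select_edges(spearman_matrix(abundance$enzyme, fun_ab),
                   config$alpha, config$r_min, config$r_strong)
    else NULL)
  empty_edges <- data.frame(source = character(), target = character(),
                            rho = numeric(), p_value = numeric(),
                            q_value = numeric(), sign = character(),
                            strong = logical(), tier = character())
  if (is.null(edges$genus)) edges$genus <- empty_edges
  if (is.null(edges$fun)) edges$fun <- empty_edges
  network <- build_tripartite(edges$genus, edges$fun)
  note("network", nrow(edges$genus) + nrow(edges$fun), nrow(network$nodes))

  result <- structure(
    list(counts_filtered = counts, gene_abund = gene_ab,
         annotations = list(kegg = kegg, enzyme = enz), taxa = taxa,
         abundance = abundance, enrichment = enrichment, edges = edges,
         network = network, manifest = NULL, log = log),
    class = "tma_pipeline_result")

  if (!is.null(config$output_dir))
    result$manifest <- write_pipeline_outputs(result, b, config)
  result
}

write_pipeline_outputs <- function(result, bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(config$output_dir, f)
  pl <- unclass(config)
  pl$output_dir <- NULL
  written <- character()
  w <- function(df, name, params) {
    write_stage_table(df, fp(name), params)
    written <<- c(written, name)
  }
  w(abund_df(result$counts_filtered), "counts_filtered.tsv",
    list(stage = "filter_genes", min_total_reads = config$min_total_reads))
  ann <- result$annotations$kegg
  w(ann, "annotations_kegg.tsv",
    list(stage = "assign_kegg", min_hsp_score = config$min_hsp_score))
  w(result$annotations$enzyme, "annotations_enzyme.tsv",
    list(stage = "assign_enzyme", max_evalue = config$max_evalue,
         min_identity = config$min_identity, min_coverage = config$min_coverage))
  w(result$taxa, "taxon_assignments.tsv",
    list(stage = "assign_taxa", lca_factor = config$lca_factor))
  for (u in names(result$abundance))
    w(abund_df(result$abundance[[u]]), sprintf("abundance_%s.tsv", u),
      list(stage = "abundance", universe = u, normalization = "relative"))
  for (nm in names(result$enrichment)) {
    z <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    w(result$enrichment[[nm]], sprintf("enrichment_%s_%s.tsv", z[1L], z[2L]),
      list(stage = "enrichment", universe = z[1L], contrast = z[2L],
           or_high = config$or_high, or_low = config$or_low,
           alpha = config$alpha, or_orientation = config$or_orientation))
  }
  w(result$edges$genus, "edges_genus_enzyme.tsv",
    list(stage = "select_edges", alpha = config$alpha, r_min = config$r_min,
         r_strong = config$r_strong))
  w(result$edges$fun, "edges_enzyme_function.tsv",
    list(stage = "select_edges", alpha = config$alpha, r_min = config$r_min,
         r_strong = config$r_strong, function_universe = config$function_universe))
  write_network_json(result$network, fp("network.json"))
  written <- c(written, "network.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("tmanet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = pl,
    log = result$log,
    files = data.frame(file = written,
                       md5 = unname(tools::md5sum(fp(written))),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, fp("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.tma_pipeline_result <- function(x, ...) {
  cat("tma_pipeline_result\n")
  for (s in names(x$log))
    cat(sprintf("  %-14s in=%d out=%d\n", s, x$log[[s]]$n_in, x$log[[s]]$n_out))
  cat(sprintf("  universes: %s\n",
              paste(sprintf("%s=%d", names(x$abundance),
                            vapply(x$abundance, nrow, 1L)), collapse = ", ")))
  invisible(x)
}
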