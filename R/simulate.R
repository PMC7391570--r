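#' Configuration for a synthetic metagenomic case-control study
#'
#' The generator emulates a shotgun-metagenome gene-catalog study of a
#' control vs atrial-fibrillation cohort. Defaults mirror the cohort design
#' of the motivating setting: 50 controls and 50 AF patients, the AF group
#' split 30/12/8 into paroxysmal AF and persistent AF of under / over 12
#' months' duration. Mapped-read counts follow an overdispersed model: a
#' per-gene log-normal baseline, a per-sample log-normal depth multiplier
#' (sdlog 0.15, matching a sequencing-depth coefficient of variation of
#' about 16%), and negative-binomial observation noise.
#'
#' Planted effects multiply the expected counts of the affected genes in AF
#' samples by `fold_change`: `planted_features` targets KEGG orthologs (ids
#' `K00001 ...`) or modules (`M0001 ...`, applied to every KO of the
#' module); `planted_taxa` plants enzyme-family genes inside a genus.
#'
#' @param n_ctr,n_af sample counts per group (default 50 + 50).
#' @param af_subtype_split proportions of PAF / PersLt12m / PersGt12m among
#'   AF samples; must sum to 1.
#' @param n_genes catalog size (default 2000).
#' @param gene_length_range gene length interval in bp.
#' @param n_kos,n_modules,n_genera sizes of the feature universes.
#' @param annotated_fraction fraction of genes carrying a KO label.
#' @param enzyme_genes_per_family background enzyme genes per family placed
#'   in random genera with no planted effect.
#' @param genes_per_planted_taxon enzyme genes created for each
#'   `planted_taxa` row.
#' @param planted_features data.frame `(feature_id, fold_change)` or NULL.
#' @param planted_taxa data.frame `(genus, enzyme_family, fold_change)` or
#'   NULL.
#' @param decoy_hit_rate fraction of spurious alignment hits added on top of
#'   the true hits (default 0.2).
#' @param dispersion negative-binomial overdispersion (NB size = 1 /
#'   dispersion; default 0.2).
#' @param baseline_meanlog,baseline_sdlog log-normal per-gene baseline of
#'   expected reads.
#' @param depth_sdlog log-normal sdlog of the per-sample depth factor.
#' @param seed integer random seed; a fixed seed makes the whole bundle
#'   byte-identical across runs.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_ctr = 50, n_af = 50,
                              af_subtype_split = c(PAF = 0.6, PersLt12m = 0.24,
                                                   PersGt12m = 0.16),
                              n_genes = 2000, gene_length_range = c(300, 3000),
                              n_kos = 150, n_modules = 25, n_genera = 30,
                              annotated_fraction = 0.7,
                              enzyme_genes_per_family = 6,
                              genes_per_planted_taxon = 5,
                              planted_features = NULL, planted_taxa = NULL,
                              decoy_hit_rate = 0.2, dispersion = 0.2,
                              baseline_meanlog = log(20), baseline_sdlog = 1,
                              depth_sdlog = 0.15, seed = 1) {
  cfg <- list(n_ctr = as.integer(n_ctr), n_af = as.integer(n_af),
              af_subtype_split = af_subtype_split,
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_kos = as.integer(n_kos), n_modules = as.integer(n_modules),
              n_genera = as.integer(n_genera),
              annotated_fraction = annotated_fraction,
              enzyme_genes_per_family = as.integer(enzyme_genes_per_family),
              genes_per_planted_taxon = as.integer(genes_per_planted_taxon),
              planted_features = planted_features, planted_taxa = planted_taxa,
              decoy_hit_rate = decoy_hit_rate, dispersion = dispersion,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, depth_sdlog = depth_sdlog,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_ctr > 0, n_af > 0, n_genes > 0, n_kos > 0, n_modules > 0,
              n_genera > 0, dispersion > 0, decoy_hit_rate >= 0,
              annotated_fraction > 0, annotated_fraction <= 1,
              gene_length_range[1L] >= 1,
              gene_length_range[2L] >= gene_length_range[1L])
    if (abs(sum(af_subtype_split) - 1) > 1e-9)
      stop("af_subtype_split must sum to 1")
  })
  ko_ids <- sprintf("K%05d", seq_len(cfg$n_kos))
  mod_ids <- sprintf("M%04d", seq_len(cfg$n_modules))
  genus_ids <- sprintf("Genus%03d", seq_len(cfg$n_genera))
  if (!is.null(cfg$planted_features)) {
    stopifnot(all(c("feature_id", "fold_change") %in% names(cfg$planted_features)))
    if (any(cfg$planted_features$fold_change <= 0))
      stop("planted fold changes must be > 0")
    bad <- setdiff(cfg$planted_features$feature_id, c(ko_ids, mod_ids))
    if (length(bad))
      stop("planted feature(s) outside the feature universe: ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$planted_taxa)) {
    stopifnot(all(c("genus", "enzyme_family", "fold_change") %in%
                    names(cfg$planted_taxa)))
    if (any(cfg$planted_taxa$fold_change <= 0))
      stop("planted fold changes must be > 0")
    bad <- setdiff(cfg$planted_taxa$genus, genus_ids)
    if (length(bad))
      stop("planted genus outside the taxonomy: ", paste(bad, collapse = ", "))
    stopifnot(all(cfg$planted_taxa$enzyme_family %in% ENZYME_FAMILIES))
  }
  cfg$ko_ids <- ko_ids; cfg$module_ids <- mod_ids; cfg$genus_ids <- genus_ids
  structure(cfg, class = "simulation_config")
}

rlog_unif <- function(n, lo, hi) 10^stats::runif(n, lo, hi)

# one outfmt6(+qlen) hit row with plausible filler coordinates
hit_rows <- function(qseqid, sseqid, pident, alen, evalue, bitscore, qlen) {
  n <- length(qseqid)
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = round(pident, 1),
             length = as.integer(alen), mismatch = as.integer(round(alen * (100 - pident) / 100)),
             gapopen = 0L, qstart = 1L, qend = as.integer(alen),
             sstart = 1L, send = as.integer(alen),
             evalue = signif(evalue, 3), bitscore = round(bitscore, 1),
             qlen = as.integer(qlen), stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study bundle
#'
#' Generates, in one seeded stream and a fixed draw order (gene lengths,
#' genus weights and assignments, KO labels, module membership, enzyme-gene
#' placement, baselines and depths, counts, functional hits and decoys,
#' taxonomy hits and decoys): a gene catalog, a mapped-read count matrix,
#' sample metadata, functional and taxonomic alignment-hit tables, a
#' taxonomy tree, feature maps, and the ground truth of every planted
#' effect.
#'
#' True functional hits always pass the downstream annotation filters; decoy
#' hits (added at `decoy_hit_rate`) each fail at least one filter (score,
#' e-value, identity, coverage, or an unmapped subject). True taxonomy hits
#' fall inside the 10x e-value window of the gene's top hit and point to the
#' gene's true genus; taxonomy decoys point to a wrong genus at an e-value
#' 100-10000x the top hit, outside the window.
#'
#' @param config a [simulation_config()].
#' @return list of class `tma_simulation` with elements `catalog`, `counts`,
#'   `metadata`, `hits_functional`, `hits_taxonomy`, `taxonomy`, `maps`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)

  gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  lengths <- as.integer(round(stats::runif(cfg$n_genes, cfg$gene_length_range[1L],
                                           cfg$gene_length_range[2L])))
  catalog <- data.frame(gene_id = gene_ids, length_bp = lengths,
                        stringsAsFactors = FALSE)

  # uneven genus sizes, as in real communities
  genus_w <- stats::rexp(cfg$n_genera)
  gene_genus <- sample(cfg$genus_ids, cfg$n_genes, replace = TRUE,
                       prob = genus_w / sum(genus_w))

  n_annot <- round(cfg$annotated_fraction * cfg$n_genes)
  annot_idx <- sort(sample.int(cfg$n_genes, n_annot))
  gene_ko <- rep(NA_character_, cfg$n_genes)
  gene_ko[annot_idx] <- sample(cfg$ko_ids, n_annot, replace = TRUE)

  # a planted KO (direct or via a planted module) must have member genes,
  # otherwise the plant would be vacuous: top up from unannotated genes
  if (!is.null(cfg$planted_features) && nrow(cfg$planted_features)) {
    direct_kos <- grep("^K", cfg$planted_features$feature_id, value = TRUE)
    for (k in direct_kos) {
      short <- 2L - sum(gene_ko == k, na.rm = TRUE)
      if (short > 0L) {
        pool <- which(is.na(gene_ko))
        pick <- pool[sample.int(length(pool), short)]
        gene_ko[pick] <- k
      }
    }
  }

  n_mods_per_ko <- sample(1:2, cfg$n_kos, replace = TRUE)
  ko_to_module <- data.frame(
    ko = rep(cfg$ko_ids, n_mods_per_ko),
    module = unlist(lapply(n_mods_per_ko, function(k) sample(cfg$module_ids, k))),
    stringsAsFactors = FALSE)

  # enzyme genes: planted (genus forced, fold applied) then background
  gene_enzyme <- rep(NA_character_, cfg$n_genes)
  enzyme_fold <- rep(1, cfg$n_genes)
  free <- which(is.na(gene_enzyme))
  if (!is.null(cfg$planted_taxa) && nrow(cfg$planted_taxa)) {
    for (r in seq_len(nrow(cfg$planted_taxa))) {
      pick <- sample(free, cfg$genes_per_planted_taxon)
      free <- setdiff(free, pick)
      gene_enzyme[pick] <- cfg$planted_taxa$enzyme_family[r]
      gene_genus[pick] <- cfg$planted_taxa$genus[r]
      enzyme_fold[pick] <- cfg$planted_taxa$fold_change[r]
    }
  }
  for (fam in ENZYME_FAMILIES) {
    if (cfg$enzyme_genes_per_family <= 0) break
    pick <- sample(free, cfg$enzyme_genes_per_family)
    free <- setdiff(free, pick)
    gene_enzyme[pick] <- fam
  }

  lambda <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  n_samples <- cfg$n_ctr + cfg$n_af
  depth <- stats::rlnorm(n_samples, 0, cfg$depth_sdlog)

  sample_ids <- c(sprintf("CTR%03d", seq_len(cfg$n_ctr)),
                  sprintf("AF%03d", seq_len(cfg$n_af)))
  # largest-remainder apportionment of the AF subtypes, deterministic
  raw <- cfg$af_subtype_split * cfg$n_af
  n_sub <- floor(raw)
  rem <- cfg$n_af - sum(n_sub)
  if (rem > 0) {
    top <- order(raw - n_sub, decreasing = TRUE)[seq_len(rem)]
    n_sub[top] <- n_sub[top] + 1
  }
  subtype <- c(rep("none", cfg$n_ctr),
               rep(c("PAF", "PersLt12m", "PersGt12m"), times = n_sub))
  metadata <- sample_metadata(sample_ids,
                              c(rep("CTR", cfg$n_ctr), rep("AF", cfg$n_af)),
                              subtype)

  # per-gene AF fold from planted features (KO or module) and planted taxa
  feature_fold <- rep(1, cfg$n_genes)
  feature_effects <- numeric(0)
  if (!is.null(cfg$planted_features) && nrow(cfg$planted_features)) {
    feature_effects <- stats::setNames(cfg$planted_features$fold_change,
                                       cfg$planted_features$feature_id)
    for (r in seq_len(nrow(cfg$planted_features))) {
      fid <- cfg$planted_features$feature_id[r]
      fc <- cfg$planted_features$fold_change[r]
      kos <- if (startsWith(fid, "M"))
        ko_to_module$ko[ko_to_module$module == fid] else fid
      feature_fold[gene_ko %in% kos] <- feature_fold[gene_ko %in% kos] * fc
    }
  }
  af_fold <- feature_fold * enzyme_fold

  mu <- outer(lambda, depth)
  af_cols <- metadata$group == "AF"
  mu[, af_cols] <- mu[, af_cols] * af_fold
  counts <- matrix(as.integer(stats::rnbinom(length(mu), mu = mu,
                                             size = 1 / cfg$dispersion)),
                   cfg$n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))

  # --- functional reference and hits ---------------------------------------
  ko_proteins <- sprintf("RP_%s", cfg$ko_ids)
  protein_to_ko <- data.frame(protein_id = ko_proteins, ko = cfg$ko_ids,
                              stringsAsFactors = FALSE)
  enz_proteins <- data.frame(
    protein_id = as.vector(outer(ENZYME_FAMILIES, 1:3, function(f, i)
      sprintf("EP_%s_%d", f, i))),
    enzyme_family = rep(ENZYME_FAMILIES, 3),
    stringsAsFactors = FALSE)

  ko_genes <- which(!is.na(gene_ko))
  true_kegg <- hit_rows(
    qseqid = gene_ids[ko_genes],
    sseqid = sprintf("RP_%s", gene_ko[ko_genes]),
    pident = stats::runif(length(ko_genes), 60, 95),
    alen = pmax(30L, round(lengths[ko_genes] / 3 *
                             stats::runif(length(ko_genes), 0.55, 0.9))),
    evalue = rlog_unif(length(ko_genes), -60, -15),
    bitscore = stats::runif(length(ko_genes), 80, 300),
    qlen = lengths[ko_genes])

  enz_genes <- which(!is.na(gene_enzyme))
  enz_subject <- sprintf("EP_%s_%d", gene_enzyme[enz_genes],
                         sample(1:3, length(enz_genes), replace = TRUE))
  true_enz <- hit_rows(
    qseqid = gene_ids[enz_genes],
    sseqid = enz_subject,
    pident = stats::runif(length(enz_genes), 60, 95),
    alen = round(lengths[enz_genes] *
                   stats::runif(length(enz_genes), 0.6, 0.95)),
    evalue = rlog_unif(length(enz_genes), -40, -10),
    bitscore = stats::runif(length(enz_genes), 100, 300),
    qlen = lengths[enz_genes])

  n_decoy <- round(cfg$decoy_hit_rate * (nrow(true_kegg) + nrow(true_enz)))
  decoys <- NULL
  if (n_decoy > 0) {
    dg <- sample.int(cfg$n_genes, n_decoy, replace = TRUE)
    flavor <- sample(c("low_score", "unmapped", "enz_evalue", "enz_identity",
                       "enz_coverage"), n_decoy, replace = TRUE)
    decoys <- hit_rows(
      qseqid = gene_ids[dg],
      sseqid = "placeholder",
      pident = stats::runif(n_decoy, 55, 90),
      alen = pmax(30L, round(lengths[dg] * stats::runif(n_decoy, 0.55, 0.9))),
      evalue = rlog_unif(n_decoy, -30, -10),
      bitscore = stats::runif(n_decoy, 100, 250),
      qlen = lengths[dg])
    decoys$sseqid <- ifelse(
      flavor %in% c("low_score", "unmapped"),
      ifelse(flavor == "low_score", sample(ko_proteins, n_decoy, replace = TRUE),
             sprintf("DECOY_%03d", sample.int(999, n_decoy, replace = TRUE))),
      sample(enz_proteins$protein_id, n_decoy, replace = TRUE))
    decoys$bitscore[flavor == "low_score"] <-
      round(stats::runif(sum(flavor == "low_score"), 20, 59.5), 1)
    decoys$evalue[flavor == "enz_evalue"] <-
      signif(rlog_unif(sum(flavor == "enz_evalue"), -4.9, -1), 3)
    decoys$pident[flavor == "enz_identity"] <-
      round(stats::runif(sum(flavor == "enz_identity"), 20, 49.9), 1)
    cvi <- flavor == "enz_coverage"
    decoys$length[cvi] <- pmax(1L, as.integer(round(
      decoys$qlen[cvi] * stats::runif(sum(cvi), 0.1, 0.49))))
  }
  hits_functional <- rbind(true_kegg, true_enz, decoys)
  rownames(hits_functional) <- NULL

  # --- taxonomy tree, reference proteins, taxonomy hits --------------------
  n_phyla <- max(2L, ceiling(cfg$n_genera / 8))
  n_fam <- max(n_phyla, ceiling(cfg$n_genera / 3))
  phy_ids <- sprintf("p__Phylum%02d", seq_len(n_phyla))
  fam_ids <- sprintf("f__Family%02d", seq_len(n_fam))
  fam_phy <- sort(rep_len(seq_len(n_phyla), n_fam))
  gen_fam <- sort(rep_len(seq_len(n_fam), cfg$n_genera))
  taxonomy <- rbind(
    data.frame(node_id = "root", parent_id = "root", rank = "root",
               name = "root", stringsAsFactors = FALSE),
    data.frame(node_id = "d__Bacteria", parent_id = "root", rank = "domain",
               name = "Bacteria", stringsAsFactors = FALSE),
    data.frame(node_id = phy_ids, parent_id = "d__Bacteria", rank = "phylum",
               name = sub("p__", "", phy_ids), stringsAsFactors = FALSE),
    data.frame(node_id = fam_ids, parent_id = phy_ids[fam_phy], rank = "family",
               name = sub("f__", "", fam_ids), stringsAsFactors = FALSE),
    data.frame(node_id = cfg$genus_ids, parent_id = fam_ids[gen_fam],
               rank = "genus", name = cfg$genus_ids, stringsAsFactors = FALSE))

  protein_to_taxon <- data.frame(
    protein_id = as.vector(outer(cfg$genus_ids, 1:3, function(g, i)
      sprintf("NRP_%s_%d", g, i))),
    node_id = rep(cfg$genus_ids, 3),
    stringsAsFactors = FALSE)

  tax_rows <- lapply(enz_genes, function(gi) {
    g <- gene_ids[gi]; genus <- gene_genus[gi]
    k <- sample(2:4, 1L)
    e0 <- rlog_unif(1L, -40, -20)
    ev <- e0 * c(1, stats::runif(k - 1L, 1, 9))
    true_hits <- hit_rows(
      qseqid = g,
      sseqid = sprintf("NRP_%s_%d", genus, sample(1:3, k, replace = TRUE)),
      pident = stats::runif(k, 70, 98),
      alen = pmax(30L, round(lengths[gi] * stats::runif(k, 0.6, 0.95))),
      evalue = ev, bitscore = sort(stats::runif(k, 80, 250), decreasing = TRUE),
      qlen = lengths[gi])
    wrong <- sample(setdiff(cfg$genus_ids, genus), 1L)
    decoy <- hit_rows(
      qseqid = g, sseqid = sprintf("NRP_%s_%d", wrong, sample(1:3, 1L)),
      pident = stats::runif(1L, 50, 80),
      alen = pmax(30L, round(lengths[gi] * stats::runif(1L, 0.4, 0.8))),
      evalue = e0 * rlog_unif(1L, 2, 4),
      bitscore = stats::runif(1L, 50, 90), qlen = lengths[gi])
    rbind(true_hits, decoy)
  })
  hits_taxonomy <- do.call(rbind, tax_rows)
  if (is.null(hits_taxonomy))
    hits_taxonomy <- hit_rows(character(), character(), numeric(), integer(),
                              numeric(), numeric(), integer())
  rownames(hits_taxonomy) <- NULL

  maps <- feature_maps(protein_to_ko, ko_to_module, enz_proteins,
                       protein_to_taxon)
  truth <- list(
    feature_effects = feature_effects,
    gene_feature_map = data.frame(gene_id = gene_ids, ko = gene_ko,
                                  enzyme_family = gene_enzyme,
                                  stringsAsFactors = FALSE),
    gene_taxon_map = stats::setNames(gene_genus, gene_ids),
    enriched_taxa = if (is.null(cfg$planted_taxa)) character()
                    else unique(cfg$planted_taxa$genus),
    enzyme_gene_ids = gene_ids[enz_genes])

  structure(list(catalog = catalog, counts = counts, metadata = metadata,
                 hits_functional = hits_functional,
                 hits_taxonomy = hits_taxonomy,
                 taxonomy = taxonomy, maps = maps, truth = truth,
                 config = cfg),
            class = "tma_simulation")
}

#' @export
print.tma_simulation <- function(x, ...) {
  cat(sprintf(paste0("tma_simulation: %d genes x %d samples (%d CTR / %d AF), ",
                     "%d functional hits, %d taxonomy hits, seed %d\n"),
              nrow(x$counts), ncol(x$counts), x$config$n_ctr, x$config$n_af,
              nrow(x$hits_functional), nrow(x$hits_taxonomy), x$config$seed))
  invisible(x)
}

BUNDLE_FILES <- c(catalog = "gene_catalog.tsv", counts = "read_counts.tsv",
                  metadata = "sample_metadata.tsv",
                  hits_functional = "hits_functional.tsv",
                  hits_taxonomy = "hits_taxonomy.tsv",
                  taxonomy = "taxonomy.tsv", maps = "feature_maps.tsv")

#' Write a simulated study to a directory of plain-text tables
#'
#' Serializes the seven study tables (gene catalog, read counts, sample
#' metadata, functional hits, taxonomy hits, taxonomy tree, feature maps) as
#' TSV and returns a manifest of file names and MD5 checksums (also written
#' as `manifest.tsv`).
#'
#' @param sim a [simulate_study()] result.
#' @param directory output directory, created if absent.
#' @return data.frame `(file, md5)`, invisibly the manifest is also on disk.
#' @export
write_fixture_bundle <- function(sim, directory) {
  stopifnot(inherits(sim, "tma_simulation"))
  if (!nrow(sim$metadata))
    stop("empty sample set: sample_metadata has no rows")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(directory, f)
  data.table::fwrite(sim$catalog, fp(BUNDLE_FILES["catalog"]), sep = "\t")
  cnt <- data.table::as.data.table(sim$counts, keep.rownames = "gene_id")
  data.table::fwrite(cnt, fp(BUNDLE_FILES["counts"]), sep = "\t")
  data.table::fwrite(as.data.frame(sim$metadata), fp(BUNDLE_FILES["metadata"]),
                     sep = "\t")
  write_hits(sim$hits_functional, fp(BUNDLE_FILES["hits_functional"]))
  write_hits(sim$hits_taxonomy, fp(BUNDLE_FILES["hits_taxonomy"]))
  data.table::fwrite(sim$taxonomy, fp(BUNDLE_FILES["taxonomy"]), sep = "\t")
  m <- sim$maps
  maps_long <- rbind(
    data.frame(map_type = "protein_ko", key = m$protein_to_ko$protein_id,
               value = m$protein_to_ko$ko, stringsAsFactors = FALSE),
    data.frame(map_type = "ko_module", key = m$ko_to_module$ko,
               value = m$ko_to_module$module, stringsAsFactors = FALSE),
    data.frame(map_type = "protein_enzyme", key = m$protein_to_enzyme$protein_id,
               value = m$protein_to_enzyme$enzyme_family, stringsAsFactors = FALSE),
    if (!is.null(m$protein_to_taxon))
      data.frame(map_type = "protein_taxon", key = m$protein_to_taxon$protein_id,
                 value = m$protein_to_taxon$node_id, stringsAsFactors = FALSE))
  data.table::fwrite(maps_long, fp(BUNDLE_FILES["maps"]), sep = "\t")
  manifest <- data.frame(file = unname(BUNDLE_FILES),
                         md5 = unname(tools::md5sum(fp(BUNDLE_FILES))),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, fp("manifest.tsv"), sep = "\t")
  manifest
}

#' Read a study bundle written by [write_fixture_bundle()]
#'
#' @param directory bundle directory.
#' @return list with the same table elements as [simulate_study()] (without
#'   `truth` and `config`).
#' @export
read_fixture_bundle <- function(directory) {
  fp <- function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) stop("bundle file missing: ", p)
    p
  }
  catalog <- data.table::fread(fp(BUNDLE_FILES["catalog"]), data.table = FALSE)
  cnt <- data.table::fread(fp(BUNDLE_FILES["counts"]), data.table = FALSE)
  counts <- as.matrix(cnt[, -1L, drop = FALSE])
  rownames(counts) <- cnt[[1L]]
  md <- data.table::fread(fp(BUNDLE_FILES["metadata"]), data.table = FALSE)
  metadata <- sample_metadata(md$sample_id, md$group, md$subtype)
  taxonomy <- data.table::fread(fp(BUNDLE_FILES["taxonomy"]), data.table = FALSE)
  maps_long <- data.table::fread(fp(BUNDLE_FILES["maps"]), data.table = FALSE)
  pick <- function(type, nm) {
    d <- maps_long[maps_long$map_type == type, c("key", "value")]
    stats::setNames(d, nm)
  }
  maps <- feature_maps(pick("protein_ko", c("protein_id", "ko")),
                       pick("ko_module", c("ko", "module")),
                       pick("protein_enzyme", c("protein_id", "enzyme_family")),
                       pick("protein_taxon", c("protein_id", "node_id")))
  list(catalog = catalog, counts = counts, metadata = metadata,
       hits_functional = read_hits(fp(BUNDLE_FILES["hits_functional"])),
       hits_taxonomy = read_hits(fp(BUNDLE_FILES["hits_taxonomy"])),
       taxonomy = taxonomy, maps = maps)
}
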