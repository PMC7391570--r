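#' Sample metadata table
#'
#' @param sample_id character vector of sample ids.
#' @param group `"CTR"` or `"AF"` per sample.
#' @param subtype AF subtype: `"PAF"`, `"PersLt12m"`, `"PersGt12m"`, or
#'   `"none"` for controls.
#' @return validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, group, subtype = NULL) {
  if (is.null(subtype)) subtype <- ifelse(group == "AF", "PAF", "none")
  stopifnot(length(sample_id) == length(group), length(group) == length(subtype))
  if (!all(group %in% c("CTR", "AF"))) stop("group must be CTR or AF")
  if (!all(subtype %in% c("PAF", "PersLt12m", "PersGt12m", "none")))
    stop("unknown subtype label")
  if (any(subtype != "none" & group != "AF"))
    stop("subtype must be 'none' for CTR samples")
  structure(data.frame(sample_id = as.character(sample_id), group = group,
                       subtype = subtype, stringsAsFactors = FALSE),
            class = c("sample_metadata", "data.frame"))
}

group_columns <- function(abund, meta) {
  missing <- setdiff(colnames(abund), meta$sample_id)
  if (length(missing))
    stop("samples without metadata: ", paste(utils::head(missing, 5L), collapse = ", "))
  grp <- stats::setNames(meta$group, meta$sample_id)[colnames(abund)]
  list(ctr = which(grp == "CTR"), af = which(grp == "AF"))
}

or_sums_pseudo <- function(s) {
  # replace zero sums by half the smallest nonzero sum of the same kind
  if (all(s == 0)) return(s)
  s[s == 0] <- min(s[s > 0]) / 2
  s
}

#' Odds-ratio enrichment statistic for all features
#'
#' For feature k the statistic compares the abundance share of k between the
#' two groups:
#' \deqn{OR(k) = \frac{\sum_{s \in AF} A_{sk} / \sum_{s \in AF} \sum_{i \ne k} A_{si}}
#'                    {\sum_{s \in CTR} A_{sk} / \sum_{s \in CTR} \sum_{i \ne k} A_{si}}}
#' so that `OR > 2` marks AF enrichment and `OR < 0.5` CTR enrichment
#' (orientation `"af_numerator"`, the default). `orientation = "ctr_numerator"`
#' returns the exact reciprocal, i.e. the ratio with the control group's
#' share on top.
#'
#' Zero handling: with `zero_handling = "pseudo"` any zero among the four
#' sums is replaced by half the smallest nonzero value of its kind (feature
#' sums and complement sums separately), keeping every OR finite and
#' classifiable; `"exact"` performs plain division, yielding `Inf`, 0 or
#' `NaN` at the boundaries.
#'
#' @param abund an [abundance_matrix()] for one feature universe.
#' @param meta a [sample_metadata()] table covering all columns of `abund`.
#' @param orientation `"af_numerator"` (default) or `"ctr_numerator"`.
#' @param zero_handling `"pseudo"` (default) or `"exact"`.
#' @return named numeric vector of OR values, one per feature.
#' @export
or_values <- function(abund, meta, orientation = c("af_numerator", "ctr_numerator"),
                      zero_handling = c("pseudo", "exact")) {
  orientation <- match.arg(orientation)
  zero_handling <- match.arg(zero_handling)
  g <- group_columns(abund, meta)
  if (!length(g$ctr) || !length(g$af)) stop("both CTR and AF groups must be non-empty")
  m <- unclass(abund)
  if (all(m == 0)) stop("all-zero abundance matrix: odds ratios undefined")
  s_ctr <- rowSums(m[, g$ctr, drop = FALSE])
  s_af <- rowSums(m[, g$af, drop = FALSE])
  comp_ctr <- sum(s_ctr) - s_ctr
  comp_af <- sum(s_af) - s_af
  if (zero_handling == "pseudo") {
    feat <- or_sums_pseudo(c(s_ctr, s_af))
    comp <- or_sums_pseudo(c(comp_ctr, comp_af))
    n <- length(s_ctr)
    s_ctr <- feat[seq_len(n)]; s_af <- feat[n + seq_len(n)]
    comp_ctr <- comp[seq_len(n)]; comp_af <- comp[n + seq_len(n)]
  }
  or <- (s_af / comp_af) / (s_ctr / comp_ctr)
  if (orientation == "ctr_numerator") or <- 1 / or
  stats::setNames(or, rownames(m))
}

#' @rdname or_values
#' @param feature a single feature id (row of `abund`).
#' @export
odds_ratio <- function(abund, meta, feature,
                       orientation = c("af_numerator", "ctr_numerator"),
                       zero_handling = c("pseudo", "exact")) {
  if (!feature %in% rownames(abund)) stop("unknown feature: ", feature)
  or_values(abund, meta, orientation, zero_handling)[[feature]]
}

#' Classify features by odds ratio
#'
#' Strict thresholds: `AF_enriched` iff `OR > or_high` (default 2),
#' `CTR_enriched` iff `OR < or_low` (default 0.5), otherwise
#' `not_significant`; the boundary values themselves are not significant.
#' An infinite OR is AF-enriched; `NaN` (0/0 under exact zero handling) is
#' not significant.
#'
#' @param or_value numeric vector of odds ratios.
#' @param or_high,or_low classification thresholds.
#' @return character vector in
#'   `{"AF_enriched", "CTR_enriched", "not_significant"}`.
#' @export
classify_enrichment <- function(or_value, or_high = 2, or_low = 0.5) {
  out <- rep("not_significant", length(or_value))
  out[!is.nan(or_value) & or_value > or_high] <- "AF_enriched"
  out[!is.nan(or_value) & or_value < or_low] <- "CTR_enriched"
  stats::setNames(out, names(or_value))
}

#' Built-in group contrasts
#'
#' Returns the sample ids of the two arms of a named contrast:
#' `"CTR_vs_AF"` (controls vs all AF), `"PAF_vs_psAF"` (paroxysmal vs
#' persistent AF), `"PersLt12m_vs_PersGt12m"` (persistent AF split at 12
#' months' duration).
#'
#' @param meta a [sample_metadata()] table.
#' @param contrast one of the three contrast names.
#' @return list with elements `a`, `b` (sample id vectors) and `name`.
#' @export
contrast_arms <- function(meta, contrast = c("CTR_vs_AF", "PAF_vs_psAF",
                                             "PersLt12m_vs_PersGt12m")) {
  contrast <- match.arg(contrast)
  arms <- switch(contrast,
    CTR_vs_AF = list(a = meta$sample_id[meta$group == "CTR"],
                     b = meta$sample_id[meta$group == "AF"]),
    PAF_vs_psAF = list(a = meta$sample_id[meta$subtype == "PAF"],
                       b = meta$sample_id[meta$subtype %in% c("PersLt12m", "PersGt12m")]),
    PersLt12m_vs_PersGt12m = list(a = meta$sample_id[meta$subtype == "PersLt12m"],
                                  b = meta$sample_id[meta$subtype == "PersGt12m"]))
  arms$name <- contrast
  arms
}

wilcox_p <- function(x, y) {
  if (all(c(x, y) == c(x, y)[1L])) return(1)  # all-tie convention
  no_ties <- !anyDuplicated(c(x, y))
  use_exact <- no_ties && max(length(x), length(y)) <= 12L
  suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                      correct = !use_exact)$p.value)
}

#' Wilcoxon rank-sum differential abundance with BH correction
#'
#' Two-sided Wilcoxon rank-sum test per feature between the two arms of a
#' contrast (exact for small tie-free arms, tie-corrected normal
#' approximation otherwise; features constant across all samples get p = 1),
#' with Benjamini-Hochberg q-values computed within the feature universe
#' tested.
#'
#' @param abund an [abundance_matrix()].
#' @param meta a [sample_metadata()] table.
#' @param contrast a contrast name for [contrast_arms()], or a list with
#'   sample-id vectors `a` and `b`.
#' @return data.frame `(feature_id, p_value, q_value, median_a, median_b)`;
#'   the contrast name and arm sizes are attached as attributes.
#' @export
wilcoxon_bh <- function(abund, meta, contrast = "CTR_vs_AF") {
  arms <- if (is.list(contrast)) contrast else contrast_arms(meta, contrast)
  a <- intersect(arms$a, colnames(abund))
  b <- intersect(arms$b, colnames(abund))
  if (length(a) < 2L || length(b) < 2L)
    stop("contrast '", arms$name %||% "custom",
         "' needs >= 2 samples per arm (got ", length(a), " and ", length(b), ")")
  m <- unclass(abund)
  p <- vapply(seq_len(nrow(m)), function(i) wilcox_p(m[i, a], m[i, b]), numeric(1L))
  out <- data.frame(feature_id = rownames(m), p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    median_a = apply(m[, a, drop = FALSE], 1L, stats::median),
                    median_b = apply(m[, b, drop = FALSE], 1L, stats::median),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- arms$name %||% "custom"
  attr(out, "n_a") <- length(a); attr(out, "n_b") <- length(b)
  out
}

#' Combined enrichment table for one feature universe
#'
#' Joins the odds-ratio classification (computed for the CTR-vs-AF contrast
#' only, as the statistic is defined on the two clinical groups) with the
#' Wilcoxon/BH differential-abundance test for the requested contrast.
#'
#' @inheritParams wilcoxon_bh
#' @inheritParams or_values
#' @param or_high,or_low classification thresholds (defaults 2 and 0.5).
#' @return data.frame `(feature_id, or_value, class, p_value, q_value,
#'   median_a, median_b)`; `or_value`/`class` are `NA` for subtype contrasts.
#' @export
enrichment_table <- function(abund, meta, contrast = "CTR_vs_AF",
                             or_high = 2, or_low = 0.5,
                             orientation = "af_numerator",
                             zero_handling = "pseudo") {
  wx <- wilcoxon_bh(abund, meta, contrast)
  if (identical(contrast, "CTR_vs_AF")) {
    or <- or_values(abund, meta, orientation, zero_handling)
    cls <- classify_enrichment(or, or_high, or_low)
    wx$or_value <- unname(or[wx$feature_id])
    wx$class <- unname(cls[wx$feature_id])
  } else {
    wx$or_value <- NA_real_
    wx$class <- NA_character_
  }
  wx[, c("feature_id", "or_value", "class", "p_value", "q_value",
         "median_a", "median_b")]
}

#' Row-wise Z-score profiles
#'
#' Standardizes each feature row to mean 0 and (sample) standard deviation 1
#' across samples; zero-variance rows become all-zero rows.
#'
#' @param abund an [abundance_matrix()] with at least two samples.
#' @return plain numeric matrix of Z scores, same dimnames.
#' @export
zscore_profile <- function(abund) {
  m <- unclass(abund)
  if (ncol(m) < 2L) stop("Z-score profiles need >= 2 samples")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}
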