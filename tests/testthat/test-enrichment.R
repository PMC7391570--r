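test_that("odds ratio reproduces the hand-computed toy example", {
  # CTR sums: feature k = 1, complement = 9; AF sums: k = 4, complement = 6
  m <- rel_abund(named_matrix(c(0.5, 4.5, 0.5, 4.5, 2, 3, 2, 3), 2, 4))
  rownames(m) <- c("k", "other")
  meta <- meta_ctr_af(2, 2)
  expect_equal(odds_ratio(m, meta, "k"), (4 / 6) / (1 / 9))  # = 6
  expect_equal(unname(classify_enrichment(odds_ratio(m, meta, "k"))),
               "AF_enriched")
  # the control-numerator orientation is the exact reciprocal
  expect_equal(odds_ratio(m, meta, "k", orientation = "ctr_numerator"), 1 / 6)
})

test_that("odds ratio is 1 under symmetry and reciprocal under label swap", {
  set.seed(51)
  m <- rel_abund(named_matrix(rep(runif(6), 4), 6, 4))
  meta <- meta_ctr_af(2, 2)
  ors <- or_values(m, meta)
  expect_equal(unname(ors), rep(1, 6))
  expect_equal(unname(classify_enrichment(ors)), rep("not_significant", 6))

  m2 <- rel_abund(named_matrix(runif(24), 6, 4))
  swapped <- sample_metadata(meta$sample_id,
                             ifelse(meta$group == "CTR", "AF", "CTR"))
  expect_equal(or_values(m2, meta) * or_values(m2, swapped), rep(1, 6),
               ignore_attr = TRUE)
})

test_that("odds ratio matches the transliterated-formula oracle on random matrices", {
  set.seed(52)
  for (rep in 1:100) {
    nr <- sample(2:12, 1); nc <- sample(4:12, 1)
    m <- rel_abund(named_matrix(rexp(nr * nc) + 1e-3, nr, nc))
    n_ctr <- sample(2:(nc - 2), 1)
    meta <- meta_ctr_af(n_ctr, nc - n_ctr)
    is_ctr <- meta$group == "CTR"
    ors <- or_values(m, meta)
    for (f in rownames(m))
      expect_equal(ors[[f]], or_brute(unclass(m), is_ctr, f),
                   tolerance = 1e-12)
  }
})

test_that("classification thresholds are strict and infinite OR is AF-enriched", {
  expect_equal(unname(classify_enrichment(c(2.0, 0.5, 1))),
               rep("not_significant", 3))
  expect_equal(unname(classify_enrichment(0.49)), "CTR_enriched")
  expect_equal(unname(classify_enrichment(2.01)), "AF_enriched")
  expect_equal(unname(classify_enrichment(Inf)), "AF_enriched")
  expect_equal(unname(classify_enrichment(NaN)), "not_significant")
})

test_that("zero group sums are handled by the pseudo-sum rule or exactly", {
  m <- rel_abund(named_matrix(c(0, 1, 0, 1, 0.2, 0.8, 0.4, 0.6), 2, 4))
  meta <- meta_ctr_af(2, 2)
  expect_true(is.finite(odds_ratio(m, meta, "f1")))
  expect_equal(odds_ratio(m, meta, "f1", zero_handling = "exact"), Inf)
  zero <- rel_abund(named_matrix(0, 2, 4))
  expect_error(or_values(zero, meta), "all-zero")
})

test_that("Wilcoxon/BH table has the documented conventions", {
  set.seed(53)
  m <- named_matrix(rexp(20 * 12), 20, 12)
  m[1, ] <- 0.5  # constant across all samples -> p = 1
  meta <- meta_ctr_af(6, 6)
  tab <- wilcoxon_bh(rel_abund(m), meta, "CTR_vs_AF")
  expect_equal(tab$p_value[tab$feature_id == "f1"], 1)
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
  # q values equal a hand-coded BH step-up oracle:
  # q_(i) = min_{j >= i} m * p_(j) / j, e.g. (0.01,0.02,0.03,0.04) -> all 0.04
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    q <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(q, 1)[order(o)]
  }
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(tab$q_value, bh_oracle(tab$p_value))
  # q is monotone non-decreasing in p
  ord <- order(tab$p_value)
  expect_true(all(diff(tab$q_value[ord]) >= -1e-12))
  # degenerate arms are rejected
  tiny <- meta[c(1, 7, 8), ]
  expect_error(wilcoxon_bh(rel_abund(m[, c(1, 7, 8)]), tiny, "CTR_vs_AF"),
               ">= 2 samples")
})

test_that("subtype contrasts are selected correctly and skip the OR statistic", {
  md <- sample_metadata(sprintf("s%d", 1:10),
                        c(rep("CTR", 4), rep("AF", 6)),
                        c(rep("none", 4), rep("PAF", 3), "PersLt12m",
                          "PersLt12m", "PersGt12m"))
  arms <- contrast_arms(md, "PAF_vs_psAF")
  expect_setequal(arms$a, c("s5", "s6", "s7"))
  expect_setequal(arms$b, c("s8", "s9", "s10"))
  set.seed(54)
  ab <- rel_abund(named_matrix(rexp(5 * 10), 5, 10))
  et <- enrichment_table(ab, md, "PAF_vs_psAF")
  expect_true(all(is.na(et$or_value)))
  et2 <- enrichment_table(ab, md, "CTR_vs_AF")
  expect_false(anyNA(et2$or_value))
  expect_identical(et2$class,
                   unname(classify_enrichment(et2$or_value)))
})

test_that("Z-score rows are standardized and constant rows become zero", {
  ab <- raw_abund(named_matrix(c(1, 5, 2, 5, 3, 5), 2, 3))
  z <- zscore_profile(ab)
  expect_equal(unname(z[1, ]), c(-1, 0, 1))
  expect_equal(unname(z[2, ]), c(0, 0, 0))
  set.seed(55)
  z2 <- zscore_profile(raw_abund(named_matrix(runif(200), 20, 10)))
  expect_true(all(abs(rowMeans(z2)) < 1e-9))
  expect_true(all(abs(apply(z2, 1, sd) - 1) < 1e-9))
})
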