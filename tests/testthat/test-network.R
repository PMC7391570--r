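test_that("Spearman block matches the rank-then-Pearson oracle", {
  set.seed(61)
  x <- rel_abund(named_matrix(runif(30), 3, 10))
  sm <- spearman_matrix(x, x)
  expect_equal(unname(diag(sm$rho)), rep(1, 3))
  rev_x <- rel_abund(1 - unclass(x)[1, , drop = FALSE])  # antitone transform
  expect_equal(unname(spearman_matrix(x, rev_x)$rho[1, 1]), -1)

  for (rep in 1:30) {
    a <- rel_abund(named_matrix(runif(24), 2, 12))
    b <- rel_abund(named_matrix(runif(24), 2, 12))
    sm <- spearman_matrix(a, b)
    for (i in 1:2) for (j in 1:2)
      expect_equal(sm$rho[i, j], spearman_brute(unclass(a)[i, ], unclass(b)[j, ]),
                   tolerance = 1e-12)
  }
  # invariance to strictly monotone transforms
  a <- rel_abund(named_matrix(runif(12), 1, 12))
  ea <- rel_abund(exp(unclass(a)))
  expect_equal(spearman_matrix(a, b)$rho, spearman_matrix(ea, b)$rho)
  # constant features: rho recorded as 0 with p = 1
  cst <- rel_abund(named_matrix(rep(0.3, 12), 1, 12))
  smc <- spearman_matrix(cst, b)
  expect_equal(unname(smc$rho[1, ]), c(0, 0))
  expect_equal(unname(smc$p[1, ]), c(1, 1))
  # mismatched sample sets are rejected with the difference named
  y <- rel_abund(named_matrix(runif(22), 2, 11))
  expect_error(spearman_matrix(a, y), "mismatch|differ")
})

test_that("edge selection applies BH over the block with strict rho thresholds", {
  rho <- matrix(c(0.4, 0.65, -0.5, 0.1), 2, 2,
                dimnames = list(c("gA", "gB"), c("CutC", "CntA")))
  p <- matrix(c(1e-4, 1e-6, 1e-3, 0.8), 2, 2, dimnames = dimnames(rho))
  ed <- select_edges(list(rho = rho, p = p, n = 50))
  # rho = 0.4 exactly is excluded; 0.65 is included and strong
  expect_false(any(ed$source == "gA" & ed$target == "CutC"))
  hit <- ed[ed$source == "gB" & ed$target == "CutC", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$strong)
  expect_equal(hit$sign, "positive")
  neg <- ed[ed$source == "gA" & ed$target == "CntA", ]
  expect_equal(neg$sign, "negative")
  expect_false(neg$strong)
  # q values are BH over all four tested pairs
  expect_equal(hit$q_value, p.adjust(as.vector(p), "BH")[2])
})

test_that("edge sets shrink as thresholds tighten and ignore feature order", {
  set.seed(62)
  x <- rel_abund(named_matrix(runif(8 * 40), 8, 40))
  y <- rel_abund(named_matrix(unclass(x)[sample(1:8), ] + runif(320, 0, 0.5), 8, 40))
  rownames(y) <- sprintf("e%d", 1:8)
  sm <- spearman_matrix(x, y)
  key <- function(e) sort(paste(e$source, e$target))
  loose <- select_edges(sm, alpha = 0.1, r_min = 0.2)
  tight_r <- select_edges(sm, alpha = 0.1, r_min = 0.5)
  tight_a <- select_edges(sm, alpha = 0.01, r_min = 0.2)
  expect_true(all(key(tight_r) %in% key(loose)))
  expect_true(all(key(tight_a) %in% key(loose)))
  perm <- sample(1:8)
  sm_p <- spearman_matrix(rel_abund(unclass(x)[perm, ]), y)
  expect_setequal(key(select_edges(sm_p, 0.1, 0.2)), key(loose))
})

test_that("a planted monotone genus-enzyme dependence is recovered as an edge", {
  set.seed(63)
  n <- 60
  enz <- named_matrix(rexp(4 * n), 4, n, c("e", "s"))
  rownames(enz) <- ENZYME_FAMILIES
  gen <- named_matrix(rexp(6 * n), 6, n, c("g", "s"))
  gen[1, ] <- enz["CutC", ]^1.7 + rexp(n, rate = 8)  # noisy monotone link
  ed <- select_edges(spearman_matrix(rel_abund(gen), rel_abund(enz)))
  expect_true(any(ed$source == "g1" & ed$target == "CutC" & ed$rho > 0.4))
})

test_that("tripartite assembly keeps connected nodes in stable order", {
  empty <- select_edges(list(rho = matrix(0, 0, 0), p = matrix(0, 0, 0), n = 10))
  net0 <- build_tripartite(empty, empty)
  expect_equal(nrow(net0$nodes), 0L)
  expect_equal(nrow(net0$edges), 0L)

  ge <- data.frame(source = "GenusA", target = "CutC", rho = 0.7, p_value = 1e-5,
                   q_value = 1e-4, sign = "positive", strong = TRUE, tier = "q<0.01")
  fe <- data.frame(source = "CutC", target = "M0001", rho = 0.5, p_value = 1e-3,
                   q_value = 5e-3, sign = "positive", strong = FALSE, tier = "q<0.01")
  net <- build_tripartite(ge, fe)
  expect_equal(net$nodes$node_id, c("GenusA", "CutC", "M0001"))
  expect_equal(net$nodes$layer, c("genera", "enzyme_genes", "functions"))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$nodes$degree[net$nodes$node_id == "CutC"], 2L)

  # counting oracle on a random fixture
  set.seed(64)
  ge2 <- data.frame(source = sample(paste0("G", 1:5), 8, TRUE),
                    target = sample(ENZYME_FAMILIES, 8, TRUE),
                    rho = runif(8, 0.41, 0.9), p_value = 1e-4, q_value = 1e-3,
                    sign = "positive", strong = FALSE, tier = "q<0.05")
  fe2 <- data.frame(source = sample(ENZYME_FAMILIES, 6, TRUE),
                    target = sample(paste0("M", 1:4), 6, TRUE),
                    rho = runif(6, 0.41, 0.9), p_value = 1e-4, q_value = 1e-3,
                    sign = "positive", strong = FALSE, tier = "q<0.05")
  net2 <- build_tripartite(ge2, fe2)
  expect_equal(sum(net2$nodes$layer == "genera"), length(unique(ge2$source)))
  expect_equal(sum(net2$nodes$layer == "functions"), length(unique(fe2$target)))
  expect_equal(sum(net2$nodes$layer == "enzyme_genes"),
               length(unique(c(ge2$target, fe2$source))))
  expect_equal(nrow(net2$edges), nrow(ge2) + nrow(fe2))
  expect_true(all(net2$edges$layer_pair %in% c("genus-enzyme", "enzyme-function")))

  # JSON export round-trips the node-link structure
  tmp <- tempfile(fileext = ".json")
  write_network_json(net2, tmp)
  doc <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(nrow(doc$links), nrow(net2$edges))
  expect_equal(doc$layers, net2$layers)
})
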