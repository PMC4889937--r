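test_that("node flow differences use the zero convention and antisymmetry", {
  s1 <- make_sub(data.frame(from = c("X", "Y"), to = c("G", "G"),
                            flow = c(1.5, 0.5), capacity = 1, pcc = 0.5,
                            cost = 0.7))
  s2 <- make_sub(data.frame(from = c("X", "Y", "Z"), to = c("G", "G", "W"),
                            flow = c(3, 2, 1.2), capacity = 1, pcc = 0.5,
                            cost = 0.7))
  d <- node_flow_difference(s2, s1)
  expect_equal(d$delta_tf[d$gene == "G"], 3.0)      # 5.0 - 2.0
  expect_equal(d$delta_tf[d$gene == "W"], 1.2)      # only in sub2
  expect_true(d$in_sub2[d$gene == "W"] && !d$in_sub1[d$gene == "W"])
  # identical subnetworks give all-zero differences
  d0 <- node_flow_difference(s1, s1)
  expect_true(all(d0$delta_tf == 0))
  # swapping arguments negates entrywise
  d_rev <- node_flow_difference(s1, s2)
  expect_equal(d_rev$delta_tf, -d$delta_tf)
})

test_that("edge prioritization applies flow and ratio thresholds in order", {
  ed <- data.frame(from = c("A", "C", "E"), to = c("B", "D", "F"),
                   flow = c(0.6, 0.4, 0.55), capacity = 0.9,
                   pcc = 0.9, cost = 0.1)
  ec <- data.frame(from = c("A", "E"), to = c("B", "F"),
                   flow = c(0.05, 0.3), capacity = 0.9, pcc = 0.9, cost = 0.1)
  sub_d <- make_sub(ed, phenotype = "phenotype2")
  sub_c <- make_sub(ec, phenotype = "phenotype1")
  set.seed(8)
  v <- matrix(rexp(6 * 8), nrow = 6,
              dimnames = list(c("A", "B", "C", "D", "E", "F"), NULL))
  m <- normalize_expression(make_expr(v))
  out <- suppressMessages(prioritize_edges(sub_d, sub_c, m))
  row <- function(e) out[out$edge == e, ]
  # flow 0.6 / 0.05 -> ratio 12: survives both steps
  expect_true(row("A|B")$pass_flow && row("A|B")$pass_ratio)
  expect_equal(row("A|B")$ratio, 12)
  # flow 0.4 fails step 1 regardless of its (infinite) ratio
  expect_false(row("C|D")$pass_flow)
  expect_equal(row("C|D")$ratio, Inf)
  # flow 0.55 but ratio 0.55/0.3 < 5 fails step 2
  expect_true(row("E|F")$pass_flow)
  expect_false(row("E|F")$pass_ratio)
  # monotone in both thresholds
  lo <- suppressMessages(prioritize_edges(sub_d, sub_c, m, flow_thr = 0.3,
                                          ratio_thr = 1))
  expect_gte(sum(lo$pass_ratio), sum(out$pass_ratio))
})

test_that("PCA flags at most 2k edges per component with recorded loadings", {
  set.seed(9)
  genes <- sprintf("g%02d", 1:40)
  ed <- data.frame(from = genes[1:20], to = genes[21:40],
                   flow = 0.8, capacity = 0.9, pcc = 0.9, cost = 0.1)
  sub_d <- make_sub(ed, phenotype = "phenotype2")
  sub_c <- make_sub(phenotype = "phenotype1")
  v <- matrix(rexp(40 * 12), nrow = 40, dimnames = list(genes, NULL))
  m <- normalize_expression(make_expr(v))
  out <- prioritize_edges(sub_d, sub_c, m, k = 3, n_pcs = 2)
  expect_true(all(out$pass_ratio))  # control flows are all zero
  expect_lte(sum(out$pca_selected), 2 * 3 * 2)
  expect_gte(sum(out$pca_selected), 2 * 3)  # PC1 alone flags 6 distinct edges
  expect_true(all(!is.na(out$loading[out$pca_selected])))
  expect_true(all(out$pc_index[out$pca_selected] %in% 1:2))
})

test_that("per-gene Jaccard matches the neighbour-set definition", {
  sub_a <- make_sub(data.frame(from = c("a", "a"), to = c("b", "c"),
                               flow = 1, capacity = 1, pcc = 1, cost = 0.1))
  sub_b1 <- make_sub(data.frame(from = c("a", "a"), to = c("b", "c"),
                                flow = 1, capacity = 1, pcc = 1, cost = 0.1))
  sub_b2 <- make_sub(data.frame(from = c("a", "a"), to = c("d", "e"),
                                flow = 1, capacity = 1, pcc = 1, cost = 0.1))
  sub_b3 <- make_sub(data.frame(from = c("a", "a"), to = c("c", "d"),
                                flow = 1, capacity = 1, pcc = 1, cost = 0.1))
  j <- function(s1, s2) {
    pg <- jaccard_similarity(s1, s2)$per_gene
    pg$jaccard[pg$gene == "a"]
  }
  expect_equal(j(sub_a, sub_b1), 1)
  expect_equal(j(sub_a, sub_b2), 0)
  expect_equal(j(sub_a, sub_b3), 1 / 3)
  # symmetry
  expect_equal(j(sub_b3, sub_a), j(sub_a, sub_b3))
  # Venn counts over genes and edges
  venn <- jaccard_similarity(sub_a, sub_b3)$venn
  expect_equal(unname(venn$edges), c(1, 1, 1))   # a|b unique, a|c shared, a|d unique
})

test_that("differentially co-expressed edges are enriched among PCA picks", {
  run <- run_small(21)
  ep <- run$res$edge_priority
  ec <- run$fx$truth$edge_cor
  # planted differential co-expression: latent correlation shift >= 0.3
  diffkey <- paste(pmin(ec$gene1, ec$gene2), pmax(ec$gene1, ec$gene2),
                   sep = "|")[abs(ec$cor_phenotype2 - ec$cor_phenotype1) >= 0.3]
  sel <- ep$pca_selected
  is_planted <- ep$edge %in% diffkey
  # odds ratio of selection for planted vs other edges (0.5 continuity)
  or <- ((sum(sel & is_planted) + 0.5) / (sum(!sel & is_planted) + 0.5)) /
    ((sum(sel & !is_planted) + 0.5) / (sum(!sel & !is_planted) + 0.5))
  expect_gt(or, 1)
})
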