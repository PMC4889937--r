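test_that("preferential attachment yields the documented edge count", {
  cfg <- synthetic_config(n_genes = 100, attachment = 2, n_modules = 5,
                          n_samples = 6, n_planted_sources = 0,
                          n_planted_rewired = 0, seed = 1)
  g <- generate_ppi(cfg)
  expect_equal(igraph::vcount(g), 100)
  expect_equal(igraph::ecount(g), 3 + 2 * 97)   # full triangle + 2 per node
  expect_true(igraph::is_simple(g))
  # largest component covers (essentially) every node
  comp <- igraph::components(g)
  expect_gte(max(comp$csize) / 100, 0.95)
  # same seed, same network
  g2 <- generate_ppi(cfg)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  # minimal case: a triangle
  cfg3 <- synthetic_config(n_genes = 3, attachment = 2, n_modules = 1,
                           n_samples = 3, n_planted_sources = 0,
                           n_planted_rewired = 0, seed = 1)
  expect_equal(igraph::ecount(generate_ppi(cfg3)), 3)
})

test_that("fixtures are a pure function of their configuration", {
  cfg <- small_cfg(2)
  a <- suppressWarnings(generate_fixture(cfg))
  b <- suppressWarnings(generate_fixture(cfg))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(igraph::as_edgelist(a$net), igraph::as_edgelist(b$net))
  expect_identical(unclass(a$annot), unclass(b$annot))
  expect_identical(a$truth$sources, b$truth$sources)
  expect_identical(a$truth$rewired, b$truth$rewired)
  # a different seed changes the expression but keeps the shapes
  c_ <- suppressWarnings(generate_fixture(small_cfg(3)))
  expect_false(identical(a$expr$values, c_$expr$values))
  expect_identical(dim(a$expr$values), dim(c_$expr$values))
})

test_that("annotations are modular with sink and planted terms", {
  cfg <- synthetic_config(n_genes = 80, attachment = 2, n_modules = 4,
                          n_samples = 6, n_planted_sources = 5,
                          n_planted_rewired = 1, sink_fraction = 0.15,
                          extra_terms = c(0, 0), seed = 4)
  net <- generate_ppi(cfg)
  truth <- ppiflow:::generate_truth(net, cfg)
  annot <- generate_annotations(net, cfg, truth)
  mem <- truth$membership
  # same module -> shared module term; different modules (unplanted genes,
  # extras disabled) -> no shared term
  plain <- setdiff(names(mem), c(truth$sinks, truth$sources, truth$rewired,
                                 unlist(truth$partners_new),
                                 unlist(truth$partners_flip)))
  same <- plain[mem[plain] == mem[plain][1]][1:2]
  expect_gt(length(intersect(annotation_terms(annot, same[1]),
                             annotation_terms(annot, same[2]))), 0)
  other <- plain[mem[plain] != mem[plain][1]][1]
  expect_length(intersect(annotation_terms(annot, same[1]),
                          annotation_terms(annot, other)), 0)
  # every planted sink carries the transcription-regulation term
  expect_true(all(vapply(truth$sinks, function(g)
    "GO:0006355" %in% annotation_terms(annot, g), logical(1))))
})

test_that("within-module correlations concentrate near the latent value", {
  cfg <- synthetic_config(n_genes = 150, attachment = 3, n_modules = 5,
                          n_samples = 200, module_correlation = 0.9,
                          n_planted_sources = 0, n_planted_rewired = 0,
                          seed = 5)
  fx <- generate_fixture(cfg)
  w <- suppressMessages(
    weight_interactome(fx$net, normalize_expression(fx$expr), "phenotype1"))
  el <- igraph::as_edgelist(w)
  mem <- fx$truth$membership
  within <- mem[el[, 1]] == mem[el[, 2]]
  caps <- igraph::E(w)$capacity[within]
  expect_gte(mean(caps >= 0.8 & caps <= 1), 0.95)
})

test_that("planted sign-flip edges change correlation sign between phenotypes", {
  flips <- c()
  for (seed in 1:10) {
    cfg <- synthetic_config(n_genes = 200, attachment = 3, n_modules = 6,
                            n_samples = 100, n_planted_sources = 10,
                            n_planted_rewired = 2, sink_fraction = 0.1,
                            seed = seed)
    fx <- generate_fixture(cfg)
    expr <- normalize_expression(fx$expr)
    w1 <- suppressMessages(weight_interactome(fx$net, expr, "phenotype1"))
    w2 <- suppressMessages(weight_interactome(fx$net, expr, "phenotype2"))
    for (g in fx$truth$rewired) {
      for (q in fx$truth$partners_flip[[g]]) {
        id1 <- igraph::get_edge_ids(w1, c(g, q))
        id2 <- igraph::get_edge_ids(w2, c(g, q))
        flips <- c(flips, id1 > 0 && id2 > 0 &&
                     sign(igraph::E(w1)$pcc[id1]) !=
                     sign(igraph::E(w2)$pcc[id2]))
      }
    }
  }
  expect_gte(mean(flips), 0.9)
})

test_that("a tiny study runs through the whole pipeline quickly", {
  t0 <- Sys.time()
  cfg <- synthetic_config(n_genes = 50, attachment = 2, n_modules = 3,
                          n_samples = 10, n_planted_sources = 6,
                          n_planted_rewired = 1, sink_fraction = 0.2,
                          seed = 6)
  fx <- suppressWarnings(generate_fixture(cfg))
  rc <- run_config(source_fraction = cfg$n_planted_sources / cfg$n_genes)
  res <- suppressWarnings(suppressMessages(
    run_pairwise(rc, expr = fx$expr, net = fx$net, annot = fx$annot)))
  expect_s3_class(res$sub1, "context_subnetwork")
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
})
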