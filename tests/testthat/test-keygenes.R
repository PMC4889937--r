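test_that("the impact score reproduces the worked example exactly", {
  toy <- impact_toy()
  imp <- suppressMessages(
    impact_scores(toy$sub1, toy$sub2, toy$w1, toy$w2))
  g <- imp[imp$gene == "G", ]
  expect_equal(g$delta_tf, 3)      # TF: 5 - 2
  expect_equal(g$nie, 0.25)        # 2 new inflows / (3 + 5)
  expect_equal(g$ncd, 3L)
  expect_equal(g$ip, 2.25)
})

test_that("NCD = 0 forces IP = 0 and one-sided genes are excluded", {
  toy <- impact_toy()
  # same correlations in both phenotypes -> no sign flips anywhere
  imp <- suppressMessages(
    impact_scores(toy$sub1, toy$sub2, toy$w1, toy$w1))
  expect_equal(imp$ip[imp$gene == "G"], 0)
  # genes D, E carry flow only in sub2 and never get a score
  imp2 <- suppressMessages(
    impact_scores(toy$sub1, toy$sub2, toy$w1, toy$w2))
  expect_false(any(c("D", "E") %in% imp2$gene))
})

test_that("routers are intermediary-only and targets sink-only", {
  e1 <- data.frame(from = c("S", "M", "S"), to = c("M", "T", "T"),
                   flow = c(4, 4, 1), capacity = 5, pcc = 0.5, cost = 0.7)
  e2 <- data.frame(from = c("S", "M", "S"), to = c("M", "T", "T"),
                   flow = c(8, 8, 3), capacity = 12, pcc = 0.5, cost = 0.7)
  sub1 <- make_sub(e1, sources = "S", sinks = "T")
  sub2 <- make_sub(e2, sources = "S", sinks = "T")
  diff <- node_flow_difference(sub2, sub1)
  r <- score_network_routers(diff, sub1, sub2, k = 20)
  expect_equal(r$gene, "M")   # S (source) and T (sink) are excluded
  kt <- score_key_targets(diff, sinks = "T", k = 20)
  expect_equal(kt$gene, "T")
  expect_equal(kt$delta_tf, (8 + 3) - (4 + 1))
  # the two rankings never overlap
  expect_length(intersect(r$gene, kt$gene), 0)
})

test_that("rankings truncate at k per sign and break ties by name", {
  genes <- sprintf("g%02d", 1:10)
  d <- structure(data.frame(gene = genes, tf1 = 0,
                            tf2 = c(5:1, -1, -2, -3, -4, -5),
                            delta_tf = c(5:1, -1, -2, -3, -4, -5),
                            in_sub1 = TRUE, in_sub2 = TRUE),
                 class = c("node_flow_diff", "data.frame"))
  sub <- make_sub(nodes = data.frame(gene = genes, total_flow = 1,
                                     is_source = FALSE, is_sink = FALSE,
                                     role = "intermediary"))
  r <- score_network_routers(d, sub, sub, k = 2)
  expect_equal(r$gene[r$direction == "positive"], c("g01", "g02"))
  expect_equal(r$gene[r$direction == "negative"], c("g10", "g09"))
  # k larger than the candidate pool returns everyone
  r_all <- score_network_routers(d, sub, sub, k = 50)
  expect_equal(nrow(r_all), 10)
  # all-zero differences still rank deterministically
  d0 <- d; d0$delta_tf <- 0
  kt <- score_key_targets(d0, sinks = genes, k = 3)
  expect_equal(kt$gene, c("g01", "g02", "g03"))
})

test_that("prioritized paths need two distinct key-gene types", {
  paths <- list(list(nodes = c("r1", "x", "t1"), flow = 1),   # router+target
                list(nodes = c("r1", "r2"), flow = 1),        # routers only
                list(nodes = c("dual", "y"), flow = 1),       # one gene, 2 types
                list(nodes = c("x", "y"), flow = 1))          # nothing
  ed <- data.frame(from = c("r1", "x", "r1", "dual", "x"),
                   to = c("x", "t1", "r2", "y", "y"),
                   flow = 1, capacity = 1, pcc = 0.5, cost = 0.7)
  sub <- make_sub(ed)
  out <- prioritize_paths(paths, sub, routers = c("r1", "r2"),
                          key_targets = c("t1", "dual"),
                          impact = "dual")
  ids <- vapply(out$paths, function(p) paste(p$nodes, collapse = ">"),
                character(1))
  expect_setequal(ids, c("r1>x>t1", "dual>y"))
  expect_true(all(c("is_router", "is_key_target", "is_high_impact") %in%
                    colnames(out$nodes)))
  expect_true(out$nodes$is_router[out$nodes$gene == "r1"])
})

test_that("planted rewired genes earn extreme impact scores", {
  ok <- c()
  for (seed in 4:6) {
    run <- run_small(seed)
    imp <- run$res$impact
    thr <- stats::quantile(abs(imp$ip), 0.9)
    for (g in run$fx$truth$rewired) {
      ok <- c(ok, g %in% imp$gene && abs(imp$ip[imp$gene == g]) > thr &&
                imp$ncd[imp$gene == g] > 0)
    }
  }
  expect_gte(mean(ok), 0.9)
})
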