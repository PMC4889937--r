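GO1 <- "GO:0000001"; GO2 <- "GO:0000002"; GO3 <- "GO:0000003"
GO4 <- "GO:0000004"; GO7 <- "GO:0000007"

test_that("functional neighbourhood = own terms plus strong partners' terms", {
  w <- make_wnet(data.frame(a = c("P1", "P1"), b = c("X", "Y"),
                            pcc = c(0.97, 0.5)))
  am <- annotation_map(c("P1", "P1", "X", "Y"), c(GO1, GO2, GO7, GO3))
  expect_setequal(functional_neighbourhood("P1", w, am, 0.95),
                  c(GO1, GO2, GO7))
  # a threshold above every capacity leaves only the gene's own terms
  expect_setequal(functional_neighbourhood("P1", w, am, 0.99), c(GO1, GO2))
  # monotone shrinkage across the SFN grid
  sizes <- vapply(c(0.91, 0.93, 0.95, 0.97, 0.99), function(s)
    length(functional_neighbourhood("P1", w, am, s)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("edges survive the process filter only on FN overlap", {
  # P1 -- P2 share GO1/GO7 through neighbourhoods; P1 -- P4 share nothing
  w <- make_wnet(data.frame(a = c("P1", "P1", "P2", "P1"),
                            b = c("X", "P2", "Y", "P4"),
                            pcc = c(0.97, 0.6, 0.96, 0.6)))
  am <- annotation_map(
    c("P1", "P1", "X", "P2", "P2", "Y", "Y", "P4"),
    c(GO1, GO2, GO7, GO1, GO3, GO4, GO7, "GO:0000099"))
  f <- suppressMessages(filter_edges_by_process(w, am, 0.95))
  keys <- apply(igraph::as_edgelist(f), 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_true("P1-P2" %in% keys)
  expect_false("P1-P4" %in% keys)

  # unannotated endpoints with no qualifying partners lose their edge
  w2 <- make_wnet(data.frame(a = "U1", b = "U2", pcc = 0.9))
  f2 <- suppressMessages(filter_edges_by_process(w2, annotation_map("z", GO1),
                                                 0.95))
  expect_equal(igraph::ecount(f2), 0)
})

test_that("flow network construction adds antiparallel arcs and auxiliaries", {
  w <- make_wnet(data.frame(a = "A", b = "B", pcc = 0.9))
  fn <- build_flow_network(w, sources = "A", sinks = "B")
  key <- paste(fn$arcs$from, fn$arcs$to)
  expect_setequal(key, c("__s__ A", "A B", "B A", "B __t__"))
  ab <- fn$arcs[key == "A B", ]
  expect_equal(ab$capacity, 0.9)
  expect_equal(ab$cost, -log(0.9))
  expect_equal(fn$arcs$cost[fn$arcs$type != "ppi"], c(0, 0))

  # a gene may be source and sink at once
  fn2 <- build_flow_network(w, sources = c("A", "B"), sinks = "B")
  key2 <- paste(fn2$arcs$from, fn2$arcs$to)
  expect_true(all(c("__s__ B", "B __t__") %in% key2))

  # sources absent from the network are dropped with a warning; losing all
  # of them is an error
  expect_warning(build_flow_network(w, sources = c("A", "Q"), sinks = "B"),
                 "absent")
  expect_error(suppressWarnings(
    build_flow_network(w, sources = "Q", sinks = "B")), "no source")
})

test_that("a single bottleneck chain carries exactly its capacity", {
  w <- make_wnet(data.frame(a = "A", b = "B", pcc = 0.9))
  fn <- build_flow_network(w, sources = "A", sinks = "B")
  sub <- solve_min_cost_flow(fn)
  expect_equal(sub$total_flow, 0.9, tolerance = 1e-9)
  expect_equal(sub$total_cost, 0.9 * -log(0.9), tolerance = 1e-9)
  expect_equal(sub$edges$from, "A")
  expect_equal(sub$edges$to, "B")
  p <- extract_paths(sub)
  expect_length(p, 1)
  expect_equal(p[[1]]$nodes, c("A", "B"))
  expect_equal(p[[1]]$flow, 0.9, tolerance = 1e-9)
})

test_that("flow prefers the cheap branch of a diamond", {
  arcs <- data.frame(
    from = c("__s__", "A", "A", "B", "C", "D"),
    to = c("A", "B", "C", "D", "D", "__t__"),
    capacity = c(0.5, 0.5, 0.5, 1, 1, 1),
    cost = c(0, 0.1, 2.0, 0, 0, 0),
    pcc = NA_real_, type = c("source", rep("ppi", 4), "sink"),
    stringsAsFactors = FALSE)
  fn <- structure(list(nodes = c("A", "B", "C", "D"), arcs = arcs,
                       sources = "A", sinks = "D", phenotype = "x"),
                  class = "flow_network")
  sub <- solve_min_cost_flow(fn)
  expect_equal(sub$total_flow, 0.5, tolerance = 1e-9)
  e <- sub$edges
  expect_true(all(e$flow[e$from == "A" & e$to == "B"] == 0.5))
  expect_false(any(e$from == "A" & e$to == "C"))
  # matches the LP oracle
  lp <- lp_mcmf(c(fn$nodes, "__s__", "__t__"), fn$arcs)
  expect_equal(sub$total_flow, lp$value, tolerance = 1e-6)
  expect_equal(sub$total_cost, lp$cost, tolerance = 1e-6)
  # and decomposes into paths whose flows sum to the total
  p <- extract_paths(sub)
  expect_equal(sum(vapply(p, `[[`, numeric(1), "flow")), sub$total_flow,
               tolerance = 1e-9)
})

test_that("solver agrees with the LP oracle on random instances", {
  for (seed in 1:40) {
    fn <- rand_flow_instance(seed)
    sub <- solve_min_cost_flow(fn)
    lp <- lp_mcmf(c(fn$nodes, "__s__", "__t__"), fn$arcs)
    expect_equal(sub$total_flow, lp$value, tolerance = 1e-6)
    expect_equal(sub$total_cost, lp$cost, tolerance = 1e-6)
    expect_lt(check_flow_constraints(sub), 1e-9)
  }
})

test_that("each interaction carries flow in at most one direction", {
  for (seed in c(3, 17, 29)) {
    fn <- rand_flow_instance(seed)
    sub <- solve_min_cost_flow(fn)
    if (nrow(sub$edges) > 0) {
      keys <- paste(pmin(sub$edges$from, sub$edges$to),
                    pmax(sub$edges$from, sub$edges$to))
      expect_equal(anyDuplicated(keys), 0L)
    }
  }
})

test_that("degenerate networks yield empty solutions, not errors", {
  # sink unreachable: A-B edge exists but C is the only sink
  w <- make_wnet(data.frame(a = c("A", "C"), b = c("B", "D"),
                            pcc = c(0.9, 0.8)))
  fn <- build_flow_network(w, sources = "A", sinks = "C")
  sub <- solve_min_cost_flow(fn)
  expect_equal(sub$total_flow, 0)
  expect_equal(nrow(sub$edges), 0)
  expect_length(extract_paths(sub), 0)
})
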