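# shared in-code fixtures; everything is generated, nothing read from disk

# weighted interactome with prescribed signed correlations
make_wnet <- function(edges, phenotype = "phenotype1") {
  # edges: data.frame(a, b, pcc)
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  igraph::E(g)$pcc <- edges$pcc
  igraph::E(g)$capacity <- abs(edges$pcc)
  igraph::E(g)$cost <- -log(pmax(abs(edges$pcc), 1e-6))
  g$phenotype <- phenotype
  g
}

# minimal solved-subnetwork stand-in for comparison/key-gene unit tests
make_sub <- function(edges = NULL, nodes = NULL, phenotype = "phenotype1",
                     sources = character(0), sinks = character(0)) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        flow = numeric(0), capacity = numeric(0),
                        pcc = numeric(0), cost = numeric(0))
  }
  if (is.null(nodes)) {
    gs <- sort(unique(c(edges$from, edges$to)), method = "radix")
    inflow <- tapply(edges$flow, edges$to, sum)
    tf <- ifelse(gs %in% names(inflow), inflow[gs], 0)
    nodes <- data.frame(gene = gs, total_flow = as.numeric(tf),
                        is_source = gs %in% sources,
                        is_sink = gs %in% sinks, stringsAsFactors = FALSE)
    nodes$role <- ifelse(nodes$is_source, "source",
                         ifelse(nodes$is_sink, "sink", "intermediary"))
  }
  structure(list(phenotype = phenotype, edges = edges, nodes = nodes,
                 total_flow = sum(edges$flow[edges$from == "__s__"]),
                 total_cost = sum(edges$flow * edges$cost),
                 sources = sources, sinks = sinks,
                 arc_flows = edges, flow_eps = 1e-9),
            class = "context_subnetwork")
}

# expression matrix with controlled per-gene values
make_expr <- function(values, phen = NULL) {
  if (is.null(phen)) {
    phen <- rep(c("phenotype1", "phenotype2"), each = ncol(values) / 2)
  }
  colnames(values) <- colnames(values) %||%
    sprintf("S%02d", seq_len(ncol(values)))
  design <- stats::setNames(phen, colnames(values))
  suppressWarnings(expr_matrix(values, design))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic study used by property and acceptance tests
small_cfg <- function(seed) {
  synthetic_config(n_genes = 300, attachment = 3, n_modules = 8,
                   n_samples = 20, n_planted_sources = 15,
                   n_planted_rewired = 2, sink_fraction = 0.10, seed = seed)
}

run_small <- function(seed, sfn = 0.95) {
  cfg <- small_cfg(seed)
  fx <- generate_fixture(cfg)
  rc <- run_config(source_fraction = cfg$n_planted_sources / cfg$n_genes,
                   sfn = sfn)
  res <- suppressWarnings(
    suppressMessages(run_pairwise(rc, expr = fx$expr, net = fx$net,
                                  annot = fx$annot)))
  list(fx = fx, res = res)
}

# builds the worked impact-score configuration: gene G present in both
# subnetworks with delta_tf = 3, two new inflows, deg1 = 3, deg2 = 5, and
# three incident sign flips -> NIE = 0.25, IP = 3 * 0.25 * 3 = 2.25
impact_toy <- function() {
  e1 <- data.frame(from = c("A", "B", "G"), to = c("G", "G", "C"),
                   flow = c(1, 1, 2), capacity = 2, pcc = 0.5, cost = 0.7)
  e2 <- data.frame(from = c("A", "B", "D", "E", "G"),
                   to = c("G", "G", "G", "G", "C"),
                   flow = c(1, 1, 1.5, 1.5, 5), capacity = 5, pcc = 0.5,
                   cost = 0.7)
  sub1 <- make_sub(e1, phenotype = "p1")
  sub2 <- make_sub(e2, phenotype = "p2")
  # sign flips on A-G, B-G, G-C; D-G and E-G keep their sign
  w1 <- make_wnet(data.frame(a = c("A", "B", "D", "E", "G"),
                             b = c("G", "G", "G", "G", "C"),
                             pcc = c(0.8, 0.7, 0.6, 0.5, 0.4)), "p1")
  w2 <- make_wnet(data.frame(a = c("A", "B", "D", "E", "G"),
                             b = c("G", "G", "G", "G", "C"),
                             pcc = c(-0.8, -0.7, 0.6, 0.5, -0.4)), "p2")
  list(sub1 = sub1, sub2 = sub2, w1 = w1, w2 = w2)
}

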