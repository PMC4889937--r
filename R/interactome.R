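#' Clean a raw protein-protein interaction edge list
#'
#' Removes self-loops and duplicate edges (including reversed duplicates:
#' (A,B) and (B,A) collapse to one undirected edge) and returns a simple
#' undirected graph.
#'
#' @param raw_edges two-column data frame (or matrix) of interacting gene
#'   pairs, as from [read_ppi()].
#' @return an undirected simple [igraph::graph] whose vertices are named by
#'   gene identifier.
#' @export
clean_interactome <- function(raw_edges) {
  raw_edges <- as.data.frame(raw_edges, stringsAsFactors = FALSE)
  if (nrow(raw_edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  a <- as.character(raw_edges[[1]])
  b <- as.character(raw_edges[[2]])
  n_loops <- sum(a == b)
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dup <- length(a) - n_loops - igraph::ecount(g)
  message("interactome cleaned: ", igraph::ecount(g), " edges kept (",
          n_loops, " self-loops, ", n_dup, " duplicate edges removed)")
  g
}

#' Weight an interactome with phenotype-specific co-expression
#'
#' For every interaction whose both endpoints are measured, computes the
#' Pearson correlation coefficient (PCC) of the two genes across the samples
#' of one phenotype only. Each surviving edge carries `pcc` (signed),
#' `capacity = |pcc|` and `cost = -log(max(|pcc|, pcc_floor))`. Edges with an
#' unmeasured endpoint, a gene constant across the phenotype's samples
#' (undefined PCC), or `|pcc| < capacity_floor` are dropped and counted.
#'
#' Both floors are numerical safeguards, not biological filters: the
#' `pcc_floor` caps the cost of near-zero correlations and the
#' `capacity_floor` discards numerically-zero capacities.
#'
#' @param net an undirected simple interactome graph, see [clean_interactome()].
#' @param expr an [expr_matrix()] (normalized or raw; PCC is invariant to the
#'   per-column scaling applied by [normalize_expression()]).
#' @param phenotype phenotype label to subset samples by; needs >= 3 samples.
#' @param capacity_floor drop edges with `|pcc|` below this value.
#' @param pcc_floor floor on `|pcc|` inside the log when computing cost.
#' @return an undirected [igraph::graph] with edge attributes `pcc`,
#'   `capacity`, `cost` and graph attribute `phenotype`.
#' @export
weight_interactome <- function(net, expr, phenotype,
                               capacity_floor = 1e-6, pcc_floor = 1e-6) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!phenotype %in% expr$design) {
    stop("unknown phenotype: ", phenotype)
  }
  smp <- names(expr$design)[expr$design == phenotype]
  if (length(smp) < 3) {
    stop("phenotype '", phenotype, "' has ", length(smp),
         " samples; >= 3 required for Pearson correlation")
  }
  measured <- intersect(igraph::V(net)$name, rownames(expr$values))
  n_unmeasured_nodes <- igraph::vcount(net) - length(measured)
  e_before <- igraph::ecount(net)
  g <- igraph::induced_subgraph(net, measured)
  n_unmeasured_edges <- e_before - igraph::ecount(g)

  X <- expr$values[igraph::V(g)$name, smp, drop = FALSE]
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- sqrt(rowSums(Xc^2))
  constant <- ss == 0
  Z <- Xc / ifelse(ss == 0, 1, ss)

  el <- igraph::as_edgelist(g, names = FALSE)
  pcc <- rowSums(Z[el[, 1], , drop = FALSE] * Z[el[, 2], , drop = FALSE])
  pcc <- pmin(1, pmax(-1, pcc))
  bad_const <- constant[el[, 1]] | constant[el[, 2]]
  keep <- !bad_const & abs(pcc) >= capacity_floor
  message("weighted interactome [", phenotype, "]: ", sum(keep),
          " edges kept (", n_unmeasured_edges, " unmeasured-endpoint, ",
          sum(bad_const), " constant-gene, ",
          sum(!keep & !bad_const), " below-floor edges dropped; ",
          n_unmeasured_nodes, " unmeasured nodes)")
  wg <- igraph::delete_edges(g, which(!keep))
  pcc <- pcc[keep]
  igraph::E(wg)$pcc <- pcc
  igraph::E(wg)$capacity <- abs(pcc)
  igraph::E(wg)$cost <- -log(pmax(abs(pcc), pcc_floor))
  wg$phenotype <- phenotype
  wg
}
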