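#' Functional neighbourhood of a gene
#'
#' The functional neighbourhood of a gene is its own GO terms plus the GO
#' terms of every interacting partner connected by an edge whose capacity is
#' strictly greater than the SFN threshold. Raising `sfn` therefore never
#' adds terms (weak monotone shrinkage towards the gene's own annotation).
#'
#' @param gene gene identifier.
#' @param wnet a weighted interactome, see [weight_interactome()].
#' @param annot an `annotation_map`.
#' @param sfn capacity threshold in `[0, 1)`; partners with edge capacity
#'   `> sfn` contribute their terms (default 0.95).
#' @return character vector of GO terms (possibly empty).
#' @export
functional_neighbourhood <- function(gene, wnet, annot, sfn = 0.95) {
  stopifnot(sfn >= 0, sfn < 1)
  own <- annotation_terms(annot, gene)
  if (!gene %in% igraph::V(wnet)$name) return(sort_cs(own))
  inc <- igraph::incident(wnet, gene)
  if (length(inc) > 0) {
    cap <- igraph::edge_attr(wnet, "capacity", index = inc)
    ends <- igraph::ends(wnet, inc)
    partners <- ifelse(ends[, 1] == gene, ends[, 2], ends[, 1])[cap > sfn]
    if (length(partners) > 0) {
      partner_terms <- unlist(lapply(partners, annotation_terms,
                                     annot = annot), use.names = FALSE)
      own <- union(own, partner_terms)
    }
  }
  sort_cs(unique(own))
}

# all functional neighbourhoods at once, as integer term-id sets
all_functional_neighbourhoods <- function(wnet, annot, sfn) {
  nodes <- igraph::V(wnet)$name
  term_ids <- lapply(nodes, function(g) annotation_terms(annot, g))
  universe <- sort_cs(unique(unlist(term_ids, use.names = FALSE)))
  own <- lapply(term_ids, function(x) match(x, universe))
  names(own) <- nodes
  fn <- own
  el <- igraph::as_edgelist(wnet, names = FALSE)
  cap <- igraph::E(wnet)$capacity
  strong <- which(cap > sfn)
  for (k in strong) {
    i <- el[k, 1]; j <- el[k, 2]
    fn[[i]] <- union(fn[[i]], own[[j]])
    fn[[j]] <- union(fn[[j]], own[[i]])
  }
  fn
}

#' Filter interactome edges by shared biological process
#'
#' An interaction is traversable only if the functional neighbourhoods of its
#' two endpoints share at least one GO term: information is allowed to flow
#' between proteins engaged in a common process, directly or through highly
#' co-expressed partners. Edge weights are preserved on retained edges. This
#' is the algorithm's single tunable filter; it is applied statically before
#' the flow problem is solved.
#'
#' @inheritParams functional_neighbourhood
#' @return the filtered weighted interactome (possibly with zero edges).
#' @export
filter_edges_by_process <- function(wnet, annot, sfn = 0.95) {
  stopifnot(sfn >= 0, sfn < 1)
  if (igraph::ecount(wnet) == 0) return(wnet)
  fn <- all_functional_neighbourhoods(wnet, annot, sfn)
  el <- igraph::as_edgelist(wnet, names = FALSE)
  share <- vapply(seq_len(nrow(el)), function(k) {
    a <- fn[[el[k, 1]]]
    b <- fn[[el[k, 2]]]
    length(a) > 0 && length(b) > 0 && any(a %in% b)
  }, logical(1))
  message("process filter (sfn=", sfn, "): ", sum(share), "/", length(share),
          " edges retained")
  igraph::delete_edges(wnet, which(!share))
}

#' Build the directed flow network with auxiliary source and sink
#'
#' Transforms the undirected weighted interactome into the directed network
#' the min-cost flow problem is solved on: every undirected edge becomes two
#' antiparallel arcs with the edge's capacity and cost; an auxiliary node `s`
#' is connected to every source gene and every sink gene is connected to an
#' auxiliary node `t`. Auxiliary arcs have cost 0 and capacity equal to the
#' gene's total incident capacity, so injection and drainage are never
#' artificially bottlenecked. A gene may be both source and sink.
#'
#' @param wnet weighted (and typically process-filtered) interactome.
#' @param sources character vector of source genes, or a `source_set` from
#'   [template_match()].
#' @param sinks character vector of sink genes, or a `sink_set` from
#'   [define_sinks()].
#' @return a `flow_network`: list with `nodes` (gene names, sorted), `arcs`
#'   (data frame `from`, `to`, `capacity`, `cost`, `pcc`, `type`), `sources`,
#'   `sinks` and `phenotype`.
#' @export
build_flow_network <- function(wnet, sources, sinks) {
  if (inherits(sources, "source_set")) sources <- sources$gene
  sources <- as.character(sources)
  sinks <- as.character(unclass(sinks))
  nodes <- sort_cs(igraph::V(wnet)$name)
  check_aux_collision(nodes)
  drop_s <- setdiff(sources, nodes)
  drop_t <- setdiff(sinks, nodes)
  if (length(drop_s) > 0) {
    warning(length(drop_s), " source gene(s) absent from the weighted ",
            "interactome dropped: ", paste(head(drop_s, 5), collapse = ", "),
            if (length(drop_s) > 5) ", ..." else "")
  }
  if (length(drop_t) > 0) {
    warning(length(drop_t), " sink gene(s) absent from the weighted ",
            "interactome dropped: ", paste(head(drop_t, 5), collapse = ", "),
            if (length(drop_t) > 5) ", ..." else "")
  }
  sources <- sort_cs(intersect(sources, nodes))
  sinks <- sort_cs(intersect(sinks, nodes))
  if (length(sources) == 0) stop("no source gene present in the network")
  if (length(sinks) == 0) stop("no sink gene present in the network")

  el <- igraph::as_edgelist(wnet, names = TRUE)
  cap <- igraph::E(wnet)$capacity
  cost <- igraph::E(wnet)$cost
  pcc <- igraph::E(wnet)$pcc
  ppi_arcs <- data.frame(
    from = c(el[, 1], el[, 2]), to = c(el[, 2], el[, 1]),
    capacity = c(cap, cap), cost = c(cost, cost), pcc = c(pcc, pcc),
    type = "ppi", stringsAsFactors = FALSE)
  strength <- igraph::strength(wnet, weights = igraph::E(wnet)$capacity)
  names(strength) <- igraph::V(wnet)$name
  src_arcs <- data.frame(from = AUX_SOURCE, to = sources,
                         capacity = unname(strength[sources]), cost = 0,
                         pcc = NA_real_, type = "source",
                         stringsAsFactors = FALSE)
  snk_arcs <- data.frame(from = sinks, to = AUX_SINK,
                         capacity = unname(strength[sinks]), cost = 0,
                         pcc = NA_real_, type = "sink",
                         stringsAsFactors = FALSE)
  arcs <- rbind(ppi_arcs, src_arcs, snk_arcs)
  arcs <- arcs[order_cs(arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(nodes = nodes, arcs = arcs, sources = sources,
                 sinks = sinks, phenotype = wnet$phenotype %||% NA_character_),
            class = "flow_network")
}

#' Solve the process-guided minimum-cost maximum-flow problem
#'
#' Finds a maximum flow from the auxiliary source to the auxiliary sink of
#' minimum total cost, by successive shortest paths with node potentials on
#' real-valued capacities. The solution satisfies, up to `flow_eps`:
#' flow non-negativity and capacity bounds on every arc, conservation
#' (inflow = outflow) at every gene, and equality of total injected and
#' drained flow. Antiparallel flows on the two arcs of one undirected edge
#' are cancelled, so each interaction carries flow in at most one direction.
#'
#' @param fn a `flow_network` from [build_flow_network()].
#' @param flow_eps numerical tolerance; arcs with flow below it are treated
#'   as flow-free (default 1e-9).
#' @return a `context_subnetwork`: list with `phenotype`; `edges` (data frame
#'   `from`, `to`, `flow`, `capacity`, `pcc`, `cost` of flow-carrying
#'   interactions, direction = flow orientation); `nodes` (data frame `gene`,
#'   `total_flow`, `role`, `is_source`, `is_sink`); `total_flow`;
#'   `total_cost`; `sources`; `sinks`; and the internal `arc_flows` table
#'   used for path extraction.
#' @export
solve_min_cost_flow <- function(fn, flow_eps = 1e-9) {
  stopifnot(inherits(fn, "flow_network"))
  all_nodes <- c(fn$nodes, AUX_SOURCE, AUX_SINK)
  idx <- stats::setNames(seq_along(all_nodes) - 1L, all_nodes)
  arcs <- fn$arcs
  res <- mcmf_ssp(length(all_nodes),
                  as.integer(idx[arcs$from]), as.integer(idx[arcs$to]),
                  as.numeric(arcs$capacity), as.numeric(arcs$cost),
                  as.integer(idx[AUX_SOURCE]), as.integer(idx[AUX_SINK]),
                  flow_eps)
  arcs$flow <- res$flow

  # cancel antiparallel flow on each undirected PPI edge: net flow per
  # unordered pair, assigned to the direction that dominates
  is_ppi <- arcs$type == "ppi"
  ppi_idx <- which(is_ppi)
  tag <- paste(arcs$from[ppi_idx], arcs$to[ppi_idx], sep = "\r")
  rev_tag <- paste(arcs$to[ppi_idx], arcs$from[ppi_idx], sep = "\r")
  rev_pos <- match(rev_tag, tag)
  net_flow <- arcs$flow
  f <- arcs$flow[ppi_idx]
  f_rev <- ifelse(is.na(rev_pos), 0, f[ifelse(is.na(rev_pos), 1L, rev_pos)])
  net_flow[ppi_idx] <- pmax(f - f_rev, 0)
  arcs$flow <- net_flow

  edges <- arcs[is_ppi & arcs$flow > flow_eps,
                c("from", "to", "flow", "capacity", "pcc", "cost")]
  rownames(edges) <- NULL

  # total flow per gene = inflow (equals outflow at intermediaries)
  inflow <- tapply(arcs$flow, arcs$to, sum)
  tf <- stats::setNames(rep(0, length(fn$nodes)), fn$nodes)
  got <- intersect(names(inflow), fn$nodes)
  tf[got] <- inflow[got]
  present <- names(tf)[tf > flow_eps]
  nodes <- data.frame(gene = present,
                      total_flow = unname(tf[present]),
                      is_source = present %in% fn$sources,
                      is_sink = present %in% fn$sinks,
                      stringsAsFactors = FALSE)
  nodes$role <- ifelse(nodes$is_source, "source",
                       ifelse(nodes$is_sink, "sink", "intermediary"))
  sub <- structure(list(phenotype = fn$phenotype, edges = edges,
                        nodes = nodes, total_flow = res$total_flow,
                        total_cost = res$total_cost,
                        sources = fn$sources, sinks = fn$sinks,
                        arc_flows = arcs[arcs$flow > flow_eps, , drop = FALSE],
                        flow_eps = flow_eps),
                   class = "context_subnetwork")
  viol <- check_flow_constraints(sub, fn)
  if (viol > 1e-6) {
    stop("flow solution violates constraints by ", signif(viol, 3))
  }
  sub
}

#' Verify capacity and conservation constraints of a solved subnetwork
#'
#' Returns the largest violation among: negative flow, flow above capacity,
#' node conservation (inflow minus outflow at every gene), and the imbalance
#' between total injected and total drained flow.
#'
#' @param sub a `context_subnetwork`.
#' @param fn optionally, the `flow_network` it was solved on (for capacities
#'   of flow-free arcs; not needed for the reported violations).
#' @return maximum absolute violation (numeric scalar, 0 when clean).
#' @export
check_flow_constraints <- function(sub, fn = NULL) {
  a <- sub$arc_flows
  if (nrow(a) == 0) return(0)
  viol_cap <- max(0, a$flow - a$capacity, -a$flow)
  genes <- setdiff(unique(c(a$from, a$to)), c(AUX_SOURCE, AUX_SINK))
  inflow <- tapply(a$flow, a$to, sum)
  outflow <- tapply(a$flow, a$from, sum)
  bal <- vapply(genes, function(g) {
    (if (g %in% names(inflow)) inflow[[g]] else 0) -
      (if (g %in% names(outflow)) outflow[[g]] else 0)
  }, numeric(1))
  viol_cons <- if (length(bal) > 0) max(abs(bal)) else 0
  s_out <- sum(a$flow[a$from == AUX_SOURCE])
  t_in <- sum(a$flow[a$to == AUX_SINK])
  max(viol_cap, viol_cons, abs(s_out - t_in))
}

#' Decompose a flow solution into source-to-sink paths
#'
#' Widest-path-first flow decomposition: the path with the highest residual
#' flow (largest bottleneck) is extracted first, subtracted, and the process
#' repeats until no source-to-sink path with positive remaining flow exists.
#' Ties are broken lexicographically by node name, making the decomposition
#' deterministic. Auxiliary nodes are stripped from the reported paths.
#' Cyclic flow (which cannot arise in a minimum-cost solution with strictly
#' positive interaction costs) is left undecomposed and reported with a
#' warning.
#'
#' @param sub a `context_subnetwork` from [solve_min_cost_flow()].
#' @return list of paths, each a list with `nodes` (character vector of
#'   genes, source to sink) and `flow` (its bottleneck flow). The path flows
#'   sum to the subnetwork's total flow up to `flow_eps` per path.
#' @export
extract_paths <- function(sub) {
  stopifnot(inherits(sub, "context_subnetwork"))
  a <- sub$arc_flows
  eps <- sub$flow_eps
  if (nrow(a) == 0 || sub$total_flow <= eps) return(list())
  nodes <- sort_cs(unique(c(a$from, a$to)))
  idx <- stats::setNames(seq_along(nodes) - 1L, nodes)
  raw <- decompose_widest(length(nodes), as.integer(idx[a$from]),
                          as.integer(idx[a$to]), as.numeric(a$flow),
                          as.integer(idx[AUX_SOURCE]),
                          as.integer(idx[AUX_SINK]), eps)
  paths <- lapply(raw, function(p) {
    nm <- nodes[p$nodes + 1L]
    list(nodes = setdiff(nm, c(AUX_SOURCE, AUX_SINK)), flow = p$flow)
  })
  undecomposed <- sub$total_flow -
    sum(vapply(paths, `[[`, numeric(1), "flow"))
  if (undecomposed > eps * (length(paths) + 1)) {
    warning("flow of ", signif(undecomposed, 3),
            " left undecomposed (cyclic remainder)")
  }
  paths
}
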