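top_bottom_k <- function(df, k) {
  # top-k most positive and top-k most negative delta_tf, ties broken by gene
  pos <- df[df$delta_tf > 0, , drop = FALSE]
  neg <- df[df$delta_tf < 0, , drop = FALSE]
  zero <- df[df$delta_tf == 0, , drop = FALSE]
  pos <- pos[order(-pos$delta_tf, pos$gene, method = "radix"), , drop = FALSE]
  neg <- neg[order(neg$delta_tf, neg$gene, method = "radix"), , drop = FALSE]
  # degenerate all-zero case: ranking is defined by gene name
  if (nrow(pos) == 0 && nrow(neg) == 0 && nrow(zero) > 0) {
    zero <- zero[order_cs(zero$gene), , drop = FALSE]
    out <- head(zero, k)
    out$direction <- "zero"
    rownames(out) <- NULL
    return(out)
  }
  pos <- head(pos, k)
  neg <- head(neg, k)
  if (nrow(pos) > 0) pos$direction <- "positive"
  if (nrow(neg) > 0) neg$direction <- "negative"
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Rank network routers
#'
#' Network routers are intermediary genes -- neither injection sources nor
#' sinks in any subnetwork where they appear -- with the most extreme
#' total-flow differences between the two phenotypes. Returns the top `k`
#' most positive and top `k` most negative.
#'
#' @param diff a `node_flow_diff` from [node_flow_difference()].
#' @param sub1,sub2 the two solved `context_subnetwork`s (for node roles).
#' @param k genes per sign (default 20, i.e. up to 40 rows).
#' @return data frame `gene`, `tf1`, `tf2`, `delta_tf`, `direction`.
#' @export
score_network_routers <- function(diff, sub1, sub2, k = 20) {
  role_flags <- function(sub) {
    stats::setNames(sub$nodes$is_source | sub$nodes$is_sink, sub$nodes$gene)
  }
  f1 <- role_flags(sub1)
  f2 <- role_flags(sub2)
  endpoint <- function(g) {
    isTRUE(f1[g]) || isTRUE(f2[g])
  }
  keep <- !vapply(diff$gene, endpoint, logical(1))
  cand <- diff[keep, c("gene", "tf1", "tf2", "delta_tf"), drop = FALSE]
  top_bottom_k(cand, k)
}

#' Rank key targets
#'
#' Key targets are sink genes (where flow terminates) with the most extreme
#' incoming-flow differences between the two phenotypes. Disjoint from
#' network routers by construction.
#'
#' @param diff a `node_flow_diff`.
#' @param sinks a `sink_set` (or character vector) of sink genes.
#' @param k genes per sign (default 20).
#' @return data frame `gene`, `tf1`, `tf2`, `delta_tf`, `direction`.
#' @export
score_key_targets <- function(diff, sinks, k = 20) {
  sinks <- as.character(unclass(sinks))
  cand <- diff[diff$gene %in% sinks,
               c("gene", "tf1", "tf2", "delta_tf"), drop = FALSE]
  top_bottom_k(cand, k)
}

#' Impact scores for genes present in both subnetworks
#'
#' The impact score combines three rewiring signals between phenotype 1 and
#' phenotype 2 for every gene present in both subnetworks:
#' `IP = delta_TF * NIE * NCD`, where `delta_TF` is the total-flow
#' difference, `NIE` is the number of inflow interactions of the gene in the
#' phenotype-2 subnetwork that are absent from the phenotype-1 subnetwork,
#' normalized by the sum of the gene's interaction counts in both
#' subnetworks, and `NCD` is the number of interactions incident to the gene
#' in either subnetwork whose expression-correlation sign differs between the
#' two weighted interactomes (independent of correlation magnitude).
#'
#' @param sub1,sub2 solved `context_subnetwork`s (phenotype 1 and 2).
#' @param wnet1,wnet2 the corresponding weighted interactomes (for signed
#'   correlations; an edge without a defined correlation in both is skipped
#'   for NCD).
#' @param k genes flagged per sign (default 20, the "top 40").
#' @return an `impact_table` data frame `gene`, `tf1`, `tf2`, `delta_tf`,
#'   `nie`, `ncd`, `ip`, `top_positive`, `top_negative`, sorted by
#'   decreasing `ip` (ties by gene name).
#' @export
impact_scores <- function(sub1, sub2, wnet1, wnet2, k = 20) {
  genes <- sort_cs(intersect(sub1$nodes$gene, sub2$nodes$gene))
  if (length(genes) == 0) {
    return(structure(data.frame(gene = character(0), tf1 = numeric(0),
                                tf2 = numeric(0), delta_tf = numeric(0),
                                nie = numeric(0), ncd = integer(0),
                                ip = numeric(0), top_positive = logical(0),
                                top_negative = logical(0)),
                     class = c("impact_table", "data.frame")))
  }
  tf <- function(sub) stats::setNames(sub$nodes$total_flow, sub$nodes$gene)
  tf1 <- tf(sub1)[genes]
  tf2 <- tf(sub2)[genes]
  e1 <- sub1$edges
  e2 <- sub2$edges
  k1 <- edge_key(e1$from, e1$to)
  k2 <- edge_key(e2$from, e2$to)
  pcc_of <- function(wnet) {
    el <- igraph::as_edgelist(wnet, names = TRUE)
    stats::setNames(igraph::E(wnet)$pcc, edge_key(el[, 1], el[, 2]))
  }
  p1 <- pcc_of(wnet1)
  p2 <- pcc_of(wnet2)
  n_skipped <- 0L
  rows <- lapply(genes, function(g) {
    inc1 <- k1[e1$from == g | e1$to == g]
    inc2 <- k2[e2$from == g | e2$to == g]
    inflow2 <- k2[e2$to == g]
    new_in <- sum(!(inflow2 %in% k1))
    denom <- length(inc1) + length(inc2)
    nie <- if (denom > 0) new_in / denom else 0
    union_inc <- union(inc1, inc2)
    s1 <- p1[union_inc]
    s2 <- p2[union_inc]
    def <- !is.na(s1) & !is.na(s2)
    n_skipped <<- n_skipped + sum(!def)
    ncd <- sum(s1[def] * s2[def] < 0)
    data.frame(gene = g, tf1 = unname(tf1[g]), tf2 = unname(tf2[g]),
               delta_tf = unname(tf2[g] - tf1[g]), nie = nie,
               ncd = as.integer(ncd),
               ip = unname(tf2[g] - tf1[g]) * nie * ncd)
  })
  if (n_skipped > 0) {
    message(n_skipped, " incident edge(s) without a signed correlation in ",
            "both interactomes skipped for NCD")
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$ip, out$gene, method = "radix"), , drop = FALSE]
  pos <- which(out$ip > 0)
  neg_ord <- order(out$ip, out$gene, method = "radix")
  neg <- neg_ord[out$ip[neg_ord] < 0]
  out$top_positive <- seq_len(nrow(out)) %in% head(pos, k)
  out$top_negative <- seq_len(nrow(out)) %in% head(neg, k)
  rownames(out) <- NULL
  structure(out, class = c("impact_table", "data.frame"))
}

#' Assemble the prioritized subnetwork from key-gene-bearing paths
#'
#' Retains the flow paths whose genes intersect at least two of the three
#' key-gene categories -- network routers, key targets, high impact genes
#' (their flagged top-k members) -- and returns the union subgraph. A single
#' gene belonging to two categories (e.g. a key target that is also a high
#' impact gene) satisfies the rule.
#'
#' @param paths path list from [extract_paths()] (typically the phenotype-2
#'   subnetwork's paths).
#' @param sub the `context_subnetwork` the paths came from (for edge
#'   annotations).
#' @param routers,key_targets,impact the tables from
#'   [score_network_routers()], [score_key_targets()] and [impact_scores()]
#'   (or plain character vectors of genes). For the impact table only the
#'   flagged top genes are used.
#' @return a `prioritized_subnetwork`: list with `paths` (the retained
#'   paths), `edges` (annotated union of their edges) and `nodes` (data frame
#'   `gene`, `is_router`, `is_key_target`, `is_high_impact`, `role`).
#' @export
prioritize_paths <- function(paths, sub, routers, key_targets, impact) {
  as_genes <- function(x, impact_table = FALSE) {
    if (is.data.frame(x)) {
      if (impact_table && all(c("top_positive", "top_negative") %in% names(x))) {
        x$gene[x$top_positive | x$top_negative]
      } else x$gene
    } else as.character(x)
  }
  r_set <- as_genes(routers)
  t_set <- as_genes(key_targets)
  i_set <- as_genes(impact, impact_table = TRUE)
  hits <- function(nodes) {
    sum(any(nodes %in% r_set), any(nodes %in% t_set), any(nodes %in% i_set))
  }
  keep <- vapply(paths, function(p) hits(p$nodes) >= 2, logical(1))
  kept <- paths[keep]
  edge_rows <- unique(do.call(rbind, c(list(
    data.frame(from = character(0), to = character(0))),
    lapply(kept, function(p) {
      if (length(p$nodes) < 2) return(NULL)
      data.frame(from = p$nodes[-length(p$nodes)], to = p$nodes[-1])
    }))))
  e <- sub$edges
  sel <- paste(e$from, e$to) %in% paste(edge_rows$from, edge_rows$to)
  edges <- e[sel, , drop = FALSE]
  rownames(edges) <- NULL
  genes <- sort_cs(unique(unlist(lapply(kept, `[[`, "nodes"))))
  roles <- stats::setNames(sub$nodes$role, sub$nodes$gene)
  nodes <- data.frame(gene = genes,
                      is_router = genes %in% r_set,
                      is_key_target = genes %in% t_set,
                      is_high_impact = genes %in% i_set,
                      role = unname(roles[genes]),
                      stringsAsFactors = FALSE)
  structure(list(paths = kept, edges = edges, nodes = nodes),
            class = "prioritized_subnetwork")
}
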