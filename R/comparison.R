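#' Per-gene total-flow difference between two context subnetworks
#'
#' Computes `delta_tf = TF(phenotype 2) - TF(phenotype 1)` over the union of
#' the two node sets; a gene absent from one subnetwork contributes total
#' flow zero on that side.
#'
#' @param sub2,sub1 solved `context_subnetwork`s (phenotype 2 and 1).
#' @return a `node_flow_diff` data frame with columns `gene`, `tf1`, `tf2`,
#'   `delta_tf`, `in_sub1`, `in_sub2`, sorted by gene.
#' @export
node_flow_difference <- function(sub2, sub1) {
  g <- sort_cs(union(sub1$nodes$gene, sub2$nodes$gene))
  tf1 <- stats::setNames(rep(0, length(g)), g)
  tf2 <- tf1
  tf1[sub1$nodes$gene] <- sub1$nodes$total_flow
  tf2[sub2$nodes$gene] <- sub2$nodes$total_flow
  structure(data.frame(gene = g, tf1 = unname(tf1), tf2 = unname(tf2),
                       delta_tf = unname(tf2 - tf1),
                       in_sub1 = g %in% sub1$nodes$gene,
                       in_sub2 = g %in% sub2$nodes$gene,
                       row.names = NULL),
            class = c("node_flow_diff", "data.frame"))
}

#' Prioritize protein interaction pairs that separate two phenotypes
#'
#' Three nested criteria on the phenotype-2 ("disease") subnetwork's edges:
#' (1) edge flow above `flow_thr`; (2) ratio of phenotype-2 to phenotype-1
#' edge flow above `ratio_thr`, where an edge absent from the phenotype-1
#' subnetwork has flow 0 and the ratio is `Inf` (it passes); (3) principal
#' component analysis of the edge-activity matrix, flagging the `k` highest-
#' and `k` lowest-loading edges on each of the first `n_pcs` components. The
#' edge-activity matrix has one row per surviving edge and one column per
#' sample; each entry is the product of the two incident genes' normalized
#' expression in that sample, and rows are standardized before the PCA.
#'
#' @param sub_d phenotype-2 (e.g. disease) `context_subnetwork`.
#' @param sub_c phenotype-1 (e.g. control) `context_subnetwork`.
#' @param expr an [expr_matrix()] covering both phenotypes; normalized
#'   internally if not already.
#' @param flow_thr minimum phenotype-2 edge flow (default 0.5).
#' @param ratio_thr minimum phenotype-2/phenotype-1 flow ratio (default 5).
#' @param k edges flagged per extreme per component (default 10).
#' @param n_pcs number of leading principal components used (default 2).
#' @return an `edge_priority` data frame over all phenotype-2 edges with
#'   columns `edge`, `gene1`, `gene2`, `flow_d`, `flow_c`, `ratio`,
#'   `pass_flow`, `pass_ratio`, `pca_selected`, `pc_index`, `loading`.
#' @export
prioritize_edges <- function(sub_d, sub_c, expr, flow_thr = 0.5,
                             ratio_thr = 5, k = 10, n_pcs = 2) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$normalized) expr <- normalize_expression(expr)
  ed <- sub_d$edges
  if (nrow(ed) == 0) {
    return(structure(data.frame(edge = character(0), gene1 = character(0),
                                gene2 = character(0), flow_d = numeric(0),
                                flow_c = numeric(0), ratio = numeric(0),
                                pass_flow = logical(0), pass_ratio = logical(0),
                                pca_selected = logical(0),
                                pc_index = integer(0), loading = numeric(0)),
                     class = c("edge_priority", "data.frame")))
  }
  key_d <- edge_key(ed$from, ed$to)
  ec <- sub_c$edges
  key_c <- if (nrow(ec) > 0) edge_key(ec$from, ec$to) else character(0)
  flow_c <- ifelse(is.na(match(key_d, key_c)), 0,
                   ec$flow[match(key_d, key_c)])
  ratio <- ifelse(flow_c == 0, Inf, ed$flow / flow_c)
  out <- data.frame(edge = key_d,
                    gene1 = pmin(ed$from, ed$to),
                    gene2 = pmax(ed$from, ed$to),
                    flow_d = ed$flow, flow_c = flow_c, ratio = ratio,
                    pass_flow = ed$flow > flow_thr,
                    pass_ratio = ed$flow > flow_thr &
                      ratio > ratio_thr,
                    pca_selected = FALSE, pc_index = NA_integer_,
                    loading = NA_real_, stringsAsFactors = FALSE)
  surv <- which(out$pass_ratio)
  if (length(surv) >= 2) {
    g1 <- out$gene1[surv]
    g2 <- out$gene2[surv]
    M <- expr$values[g1, , drop = FALSE] * expr$values[g2, , drop = FALSE]
    mu <- rowMeans(M)
    s <- apply(M, 1, stats::sd)
    usable <- s > 0
    M <- (M - mu) / ifelse(s == 0, 1, s)
    if (sum(usable) >= 2) {
      pc <- stats::prcomp(t(M[usable, , drop = FALSE]), center = FALSE,
                          scale. = FALSE)
      n_use <- min(n_pcs, ncol(pc$rotation))
      surv_use <- surv[usable]
      for (p in seq_len(n_use)) {
        ld <- pc$rotation[, p]
        kk <- min(k, length(ld))
        hi <- order(-ld, out$edge[surv_use], method = "radix")[seq_len(kk)]
        lo <- order(ld, out$edge[surv_use], method = "radix")[seq_len(kk)]
        for (i in union(hi, lo)) {
          j <- surv_use[i]
          if (!out$pca_selected[j]) {
            out$pca_selected[j] <- TRUE
            out$pc_index[j] <- p
            out$loading[j] <- ld[i]
          }
        }
      }
    } else {
      message("fewer than 2 non-degenerate edge-activity rows; PCA skipped")
    }
  } else {
    message("fewer than 2 edges survive the flow/ratio filters; PCA skipped")
  }
  out <- out[order_cs(out$edge), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("edge_priority", "data.frame"))
}

#' Jaccard similarity of a gene's interaction partners across two subnetworks
#'
#' For every gene present in both subnetworks, the Jaccard index
#' `J = |N1 n N2| / |N1 u N2|` of its neighbour sets (flow direction
#' ignored). Genes isolated in both subnetworks (only possible when flow
#' passes straight from injection to drainage at one node) get `J = NA` and
#' are flagged. Also returns Venn-style overlap counts of genes, edges and
#' paths between the two subnetworks.
#'
#' @param sub1,sub2 solved `context_subnetwork`s.
#' @param paths1,paths2 optional path lists from [extract_paths()]; when
#'   supplied, path overlap counts (exact node-sequence identity) are added.
#' @return list with `per_gene` (data frame `gene`, `jaccard`, `n1`, `n2`,
#'   `isolated`) and `venn` (named list of `c(only1, shared, only2)` counts
#'   for genes, edges and, when paths are given, paths).
#' @export
jaccard_similarity <- function(sub1, sub2, paths1 = NULL, paths2 = NULL) {
  nbr <- function(sub) {
    e <- sub$edges
    if (nrow(e) == 0) return(list())
    both <- rbind(data.frame(g = e$from, n = e$to),
                  data.frame(g = e$to, n = e$from))
    lapply(split(both$n, both$g), unique)
  }
  n1 <- nbr(sub1)
  n2 <- nbr(sub2)
  shared_genes <- sort_cs(intersect(sub1$nodes$gene, sub2$nodes$gene))
  per <- lapply(shared_genes, function(g) {
    a <- n1[[g]] %||% character(0)
    b <- n2[[g]] %||% character(0)
    u <- union(a, b)
    if (length(u) == 0) {
      data.frame(gene = g, jaccard = NA_real_, n1 = 0L, n2 = 0L,
                 isolated = TRUE)
    } else {
      data.frame(gene = g, jaccard = length(intersect(a, b)) / length(u),
                 n1 = length(a), n2 = length(b), isolated = FALSE)
    }
  })
  per_gene <- if (length(per) > 0) do.call(rbind, per) else
    data.frame(gene = character(0), jaccard = numeric(0), n1 = integer(0),
               n2 = integer(0), isolated = logical(0))
  venn3 <- function(a, b) {
    c(only1 = length(setdiff(a, b)), shared = length(intersect(a, b)),
      only2 = length(setdiff(b, a)))
  }
  k1 <- if (nrow(sub1$edges) > 0) edge_key(sub1$edges$from, sub1$edges$to) else character(0)
  k2 <- if (nrow(sub2$edges) > 0) edge_key(sub2$edges$from, sub2$edges$to) else character(0)
  venn <- list(genes = venn3(sub1$nodes$gene, sub2$nodes$gene),
               edges = venn3(k1, k2))
  if (!is.null(paths1) && !is.null(paths2)) {
    pid <- function(p) vapply(p, function(x) paste(x$nodes, collapse = ">"),
                              character(1))
    venn$paths <- venn3(unique(pid(paths1)), unique(pid(paths2)))
  }
  list(per_gene = per_gene, venn = venn)
}
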