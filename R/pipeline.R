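#' Configuration of a pairwise phenotype comparison
#'
#' Collects every input path and tunable parameter of the end-to-end
#' pipeline. Defaults: SFN 0.95, source fraction 0.005 (top 0.5% by template
#' matching), transcription-regulation sink terms, edge-prioritization
#' thresholds flow > 0.5 and ratio > 5 with top-10 loadings on 2 components,
#' and top-20-per-sign key-gene rankings.
#'
#' @param phenotypes ordered character pair: `c(phenotype1, phenotype2)`;
#'   phenotype 2 is the one sources are matched against and differences are
#'   reported as phenotype2 - phenotype1.
#' @param expression,design,ppi,annotations input file paths (may be omitted
#'   when in-memory objects are passed to [run_pairwise()]).
#' @param annotation_format `"tsv"` or `"gaf"`.
#' @param sfn functional-neighbourhood capacity threshold.
#' @param source_fraction top fraction of template-matched genes used as
#'   sources.
#' @param sources optional explicit source genes (character vector or a file
#'   with one gene per line), bypassing template matching.
#' @param sink_terms GO terms defining sinks.
#' @param sinks optional explicit sink genes (vector or file), bypassing the
#'   GO lookup.
#' @param flow_thr,ratio_thr,top_edges,n_pcs edge prioritization parameters.
#' @param top_k key genes per sign in each ranking.
#' @param capacity_floor,pcc_floor,flow_eps numerical floors (see
#'   [weight_interactome()] and [solve_min_cost_flow()]).
#' @param out_dir optional output directory for [run_pairwise()].
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(phenotypes = c("phenotype1", "phenotype2"),
                       expression = NULL, design = NULL, ppi = NULL,
                       annotations = NULL, annotation_format = "tsv",
                       sfn = 0.95, source_fraction = 0.005, sources = NULL,
                       sink_terms = DEFAULT_SINK_TERMS, sinks = NULL,
                       flow_thr = 0.5, ratio_thr = 5, top_edges = 10,
                       n_pcs = 2, top_k = 20, capacity_floor = 1e-6,
                       pcc_floor = 1e-6, flow_eps = 1e-9, out_dir = NULL,
                       seed = 1) {
  stopifnot(length(phenotypes) == 2, sfn >= 0, sfn < 1,
            source_fraction > 0, source_fraction <= 1)
  structure(list(phenotypes = phenotypes, expression = expression,
                 design = design, ppi = ppi, annotations = annotations,
                 annotation_format = annotation_format, sfn = sfn,
                 source_fraction = source_fraction, sources = sources,
                 sink_terms = sink_terms, sinks = sinks, flow_thr = flow_thr,
                 ratio_thr = ratio_thr, top_edges = top_edges, n_pcs = n_pcs,
                 top_k = top_k, capacity_floor = capacity_floor,
                 pcc_floor = pcc_floor, flow_eps = flow_eps,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_gene_arg <- function(x) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1 && file.exists(x)) read_gene_list(x) else as.character(x)
}

#' Run the full pairwise phenotype comparison
#'
#' Executes the whole pipeline: normalization, per-phenotype co-expression
#' weighting, source/sink selection, functional-neighbourhood edge
#' filtering, min-cost max-flow solving for both phenotypes, subnetwork
#' comparison (node flow differences, edge prioritization, Jaccard), key-gene
#' scoring and prioritized-subnetwork assembly. When `out_dir` is set (in
#' the config or as an argument), writes both subnetworks, all score tables
#' and a manifest recording every parameter.
#'
#' @param config a [run_config()].
#' @param expr,net,annot optional in-memory inputs (an [expr_matrix()], a
#'   cleaned interactome graph, an `annotation_map`) overriding the config's
#'   file paths.
#' @param out_dir optional output directory, overriding the config's.
#' @return a `pairwise_result` list: `sub1`, `sub2` (context subnetworks),
#'   `paths1`, `paths2`, `wnet1`, `wnet2`, `sources`, `sinks`, `diff`,
#'   `routers`, `key_targets`, `impact`, `edge_priority`, `jaccard`,
#'   `prioritized`, `manifest`.
#' @export
run_pairwise <- function(config, expr = NULL, net = NULL, annot = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  expr <- expr %||% stage("read_expression",
                          read_expression(config$expression, config$design))
  net <- net %||% stage("interactome",
                        clean_interactome(read_ppi(config$ppi)))
  annot <- annot %||% stage("annotations",
                            read_annotations(config$annotations,
                                             config$annotation_format))
  p1 <- config$phenotypes[1]
  p2 <- config$phenotypes[2]
  if (!all(c(p1, p2) %in% expr$design)) {
    stop("phenotype(s) not present in design: ",
         paste(setdiff(c(p1, p2), expr$design), collapse = ", "))
  }
  expr <- stage("normalize", normalize_expression(expr))
  wnet1 <- stage("weight_interactome",
                 weight_interactome(net, expr, p1, config$capacity_floor,
                                    config$pcc_floor))
  wnet2 <- stage("weight_interactome",
                 weight_interactome(net, expr, p2, config$capacity_floor,
                                    config$pcc_floor))
  sources <- resolve_gene_arg(config$sources) %||%
    stage("template_match",
          template_match(expr, p2, config$source_fraction)$gene)
  sinks <- resolve_gene_arg(config$sinks) %||%
    stage("define_sinks",
          as.character(define_sinks(annot, config$sink_terms, net)))
  solve_one <- function(wnet) {
    filt <- filter_edges_by_process(wnet, annot, config$sfn)
    fnw <- build_flow_network(filt, sources, sinks)
    sub <- solve_min_cost_flow(fnw, config$flow_eps)
    list(sub = sub, paths = extract_paths(sub))
  }
  r1 <- stage("flow", solve_one(wnet1))
  r2 <- stage("flow", solve_one(wnet2))
  diff <- node_flow_difference(r2$sub, r1$sub)
  routers <- score_network_routers(diff, r1$sub, r2$sub, config$top_k)
  key_targets <- score_key_targets(diff, sinks, config$top_k)
  impact <- impact_scores(r1$sub, r2$sub, wnet1, wnet2, config$top_k)
  edge_priority <- prioritize_edges(r2$sub, r1$sub, expr, config$flow_thr,
                                    config$ratio_thr, config$top_edges,
                                    config$n_pcs)
  jac <- jaccard_similarity(r1$sub, r2$sub, r1$paths, r2$paths)
  prioritized <- prioritize_paths(r2$paths, r2$sub, routers, key_targets,
                                  impact)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ppiflow")),
    parameters = unclass(config)[c("phenotypes", "sfn", "source_fraction",
                                   "sink_terms", "flow_thr", "ratio_thr",
                                   "top_edges", "n_pcs", "top_k",
                                   "capacity_floor", "pcc_floor", "flow_eps",
                                   "seed")],
    n_sources = length(sources), n_sinks = length(sinks),
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("expression", "design", "ppi", "annotations")]),
      function(p) unname(tools::md5sum(p))))
  res <- structure(list(sub1 = r1$sub, sub2 = r2$sub, paths1 = r1$paths,
                        paths2 = r2$paths, wnet1 = wnet1, wnet2 = wnet2,
                        sources = sources, sinks = sinks, diff = diff,
                        routers = routers, key_targets = key_targets,
                        impact = impact, edge_priority = edge_priority,
                        jaccard = jac, prioritized = prioritized,
                        manifest = manifest),
                   class = "pairwise_result")
  if (!is.null(out_dir)) write_pairwise_result(res, out_dir)
  res
}

#' Write all outputs of a pairwise comparison
#' @param res a `pairwise_result` from [run_pairwise()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, `out_dir`.
#' @export
write_pairwise_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_subnetwork(res$sub1, out_dir, "phenotype1")
  write_subnetwork(res$sub2, out_dir, "phenotype2")
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(res$diff, "node_flow_diff.tsv")
  wt(res$routers, "routers.tsv")
  wt(res$key_targets, "key_targets.tsv")
  wt(as.data.frame(res$impact), "impact_scores.tsv")
  wt(as.data.frame(res$edge_priority), "edge_priority.tsv")
  wt(res$jaccard$per_gene, "jaccard.tsv")
  jsonlite::write_json(res$jaccard$venn, file.path(out_dir, "venn.json"),
                       auto_unbox = FALSE, digits = NA)
  pri <- res$prioritized
  wt(pri$edges, "prioritized_edges.tsv")
  wt(pri$nodes, "prioritized_nodes.tsv")
  writeLines(if (nrow(pri$edges) > 0)
    paste(pri$edges$from, "flow", pri$edges$to) else character(0),
    file.path(out_dir, "prioritized.sif"))
  g <- igraph::graph_from_data_frame(
    if (nrow(pri$edges) > 0) pri$edges else
      data.frame(from = character(0), to = character(0)),
    directed = TRUE,
    vertices = if (nrow(pri$nodes) > 0) pri$nodes else NULL)
  igraph::write_graph(g, file.path(out_dir, "prioritized.graphml"),
                      format = "graphml")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Robustness sweep over the functional-neighbourhood threshold
#'
#' Reruns the pairwise comparison at each SFN value and compares paths and
#' top key genes against the reference SFN (default 0.95): path counts, the
#' fraction of reference phenotype-2 paths recovered, and the number of
#' reference top key genes (routers, key targets, high impact) recovered per
#' category.
#'
#' @param config a [run_config()]; its `sfn` is ignored in favour of
#'   `sfn_values`.
#' @param sfn_values SFN grid (default `c(0.91, 0.93, 0.95, 0.97, 0.99)`).
#' @param reference_sfn the value other runs are compared to.
#' @inheritParams run_pairwise
#' @return a data frame with one row per SFN value: `sfn`, `n_paths1`,
#'   `n_paths2`, `path_overlap` (fraction of reference paths recovered),
#'   `routers_recovered`, `key_targets_recovered`, `impact_recovered` (and
#'   `*_reference` totals).
#' @export
run_sfn_sweep <- function(config, sfn_values = c(0.91, 0.93, 0.95, 0.97, 0.99),
                          reference_sfn = 0.95, expr = NULL, net = NULL,
                          annot = NULL) {
  stopifnot(inherits(config, "run_config"))
  expr <- expr %||% read_expression(config$expression, config$design)
  net <- net %||% clean_interactome(read_ppi(config$ppi))
  annot <- annot %||% read_annotations(config$annotations,
                                       config$annotation_format)
  run_at <- function(sfn) {
    cfg <- config
    cfg$sfn <- sfn
    cfg$out_dir <- NULL
    run_pairwise(cfg, expr = expr, net = net, annot = annot)
  }
  sfn_all <- sort(unique(c(sfn_values, reference_sfn)))
  runs <- lapply(sfn_all, run_at)
  names(runs) <- as.character(sfn_all)
  ref <- runs[[as.character(reference_sfn)]]
  pid <- function(p) vapply(p, function(x) paste(x$nodes, collapse = ">"),
                            character(1))
  ref_paths <- unique(pid(ref$paths2))
  key_set <- function(run, what) {
    t <- run[[what]]
    if (what == "impact") t$gene[t$top_positive | t$top_negative] else t$gene
  }
  rows <- lapply(sfn_all, function(s) {
    run <- runs[[as.character(s)]]
    data.frame(
      sfn = s,
      n_paths1 = length(run$paths1),
      n_paths2 = length(run$paths2),
      path_overlap = if (length(ref_paths) > 0) {
        length(intersect(unique(pid(run$paths2)), ref_paths)) /
          length(ref_paths)
      } else NA_real_,
      routers_recovered = length(intersect(key_set(run, "routers"),
                                           key_set(ref, "routers"))),
      routers_reference = length(key_set(ref, "routers")),
      key_targets_recovered = length(intersect(key_set(run, "key_targets"),
                                               key_set(ref, "key_targets"))),
      key_targets_reference = length(key_set(ref, "key_targets")),
      impact_recovered = length(intersect(key_set(run, "impact"),
                                          key_set(ref, "impact"))),
      impact_reference = length(key_set(ref, "impact")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
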