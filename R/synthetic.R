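#' Configuration for the synthetic fixture generator
#'
#' Defines the study conditions emulated by the generator: a scale-free
#' interactome, modular GO annotations coupled to co-expression modules, and
#' a two-phenotype expression matrix with planted differentially expressed
#' sources and planted rewired genes (new inflow interactions and
#' correlation-sign flips in phenotype 2). The full fixture is a pure
#' function of this configuration; identical seeds give identical fixtures.
#'
#' @param n_genes number of genes (network nodes).
#' @param attachment preferential-attachment parameter `m`: edges added per
#'   new node. The construction starts from a complete graph on
#'   `attachment + 1` nodes, so the edge count is exactly
#'   `choose(attachment + 1, 2) + attachment * (n_genes - attachment - 1)`.
#' @param n_modules number of co-expression/annotation modules.
#' @param n_samples samples per phenotype (two phenotypes are generated).
#' @param module_correlation latent within-module gene-gene correlation
#'   (rho, in (0,1)).
#' @param noise_sd log-scale standard deviation of every gene; the residual
#'   (non-module) noise of a module gene is `noise_sd * sqrt(1 - rho)`.
#' @param n_planted_sources genes given a mean shift of
#'   `effect_size * noise_sd` (log scale) in phenotype 2. The shift is
#'   constant within each phenotype, so it leaves within-phenotype
#'   correlations (and hence edge capacities) untouched while dominating
#'   the between-phenotype template signal.
#' @param n_planted_rewired genes rewired in phenotype 2: each gains a
#'   strong shared latent factor with 3 network neighbours (new inflows) and
#'   flips its loading sign on a pair factor shared with 2 further
#'   neighbours (correlation sign change).
#' @param effect_size mean shift of planted sources, in units of `noise_sd`.
#' @param sink_fraction fraction of genes annotated as transcription
#'   regulators (GO:0006355), i.e. default sinks; planted rewired genes are
#'   always included so they occur in both phenotype subnetworks.
#' @param extra_terms integer vector `c(min, max)`: random extra GO terms
#'   per gene (set `c(0, 0)` to disable).
#' @param term_pool size of the random extra-term pool.
#' @param seed integer RNG seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, attachment = 5, n_modules = 20,
                             n_samples = 30, module_correlation = 0.90,
                             noise_sd = 0.3, n_planted_sources = 20,
                             n_planted_rewired = 3, effect_size = 2,
                             sink_fraction = 0.08, extra_terms = c(1, 3),
                             term_pool = 60, seed = 1) {
  cfg <- list(n_genes = n_genes, attachment = attachment,
              n_modules = n_modules, n_samples = n_samples,
              module_correlation = module_correlation, noise_sd = noise_sd,
              n_planted_sources = n_planted_sources,
              n_planted_rewired = n_planted_rewired,
              effect_size = effect_size, sink_fraction = sink_fraction,
              extra_terms = extra_terms, term_pool = term_pool, seed = seed)
  stopifnot(n_genes >= 3, attachment >= 1, n_modules >= 1, n_samples >= 3,
            module_correlation > 0, module_correlation < 1, noise_sd > 0,
            n_planted_sources >= 0, n_planted_rewired >= 0, effect_size >= 0,
            sink_fraction > 0, sink_fraction <= 1,
            length(extra_terms) == 2, extra_terms[1] <= extra_terms[2])
  structure(cfg, class = "synthetic_config")
}

#' Generate a scale-free synthetic interactome
#'
#' Preferential attachment starting from a complete graph on
#' `attachment + 1` nodes, adding `attachment` edges per new node; the graph
#' is simple, connected, and has a heavy-tailed degree distribution.
#'
#' @param cfg a [synthetic_config()].
#' @return an undirected simple [igraph::graph] with genes named
#'   `G00001 ...`.
#' @export
generate_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  m <- cfg$attachment
  if (cfg$n_genes < m + 1) stop("n_genes must be at least attachment + 1")
  set.seed(cfg$seed)
  start <- igraph::make_full_graph(m + 1, directed = FALSE)
  g <- igraph::sample_pa(cfg$n_genes, power = 1, m = m, directed = FALSE,
                         start.graph = start)
  igraph::V(g)$name <- sprintf("G%05d", seq_len(cfg$n_genes))
  g
}

# planted structure: module memberships, planted roles, and the per-phenotype
# latent factor loadings (weights) the expression model uses
generate_truth <- function(net, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- igraph::V(net)$name
  n <- length(genes)
  comm <- igraph::cluster_fast_greedy(net)
  n_comm <- length(unique(igraph::membership(comm)))
  membership <- if (n_comm > cfg$n_modules) {
    igraph::cut_at(comm, no = cfg$n_modules)
  } else {
    as.integer(igraph::membership(comm))
  }
  names(membership) <- genes

  set.seed(cfg$seed + 1L)
  deg <- igraph::degree(net)
  rewired <- character(0)
  partners_new <- list()
  partners_flip <- list()
  used <- character(0)
  if (cfg$n_planted_rewired > 0) {
    # a rewired gene needs 5 partners drawn from OTHER modules, so that the
    # gained interactions carry no module correlation in phenotype 1
    shuffle <- function(x) x[sample.int(length(x))]
    elig <- shuffle(sort_cs(genes[deg >= 5]))
    for (g in elig) {
      if (length(rewired) >= cfg$n_planted_rewired) break
      if (g %in% used) next
      nb <- setdiff(sort_cs(igraph::neighbors(net, g)$name), used)
      nb <- nb[membership[nb] != membership[g]]
      if (length(nb) < 5) next
      pool <- shuffle(nb)
      rewired <- c(rewired, g)
      partners_new[[g]] <- pool[1:3]
      partners_flip[[g]] <- pool[4:5]
      used <- c(used, g, pool[1:5])
    }
    if (length(rewired) < cfg$n_planted_rewired) {
      stop("could not place ", cfg$n_planted_rewired, " rewired genes with ",
           "5 cross-module neighbours each; increase n_genes or attachment")
    }
  }
  # planted partners are themselves differentially expressed sources, so
  # their saturated injections expose the rewired gene's gained and
  # sign-flipped interactions in the flow solutions
  partner_sources <- unique(as.character(
    c(unlist(partners_new, use.names = FALSE),
      unlist(partners_flip, use.names = FALSE))))
  if (cfg$n_planted_sources < length(partner_sources)) {
    stop("n_planted_sources must be at least 5 * n_planted_rewired")
  }
  free <- setdiff(genes, used)
  n_rand <- cfg$n_planted_sources - length(partner_sources)
  sources <- partner_sources
  if (n_rand > 0) {
    fr <- sort_cs(free)
    if (length(fr) < n_rand) stop("too few free genes for planted sources")
    sources <- c(sources, fr[sample.int(length(fr), n_rand)])
  }
  free <- setdiff(free, sources)
  n_sinks <- max(1, round(cfg$sink_fraction * n))
  fr <- sort_cs(free)
  sinks <- fr[sample.int(length(fr), min(n_sinks, length(fr)))]
  sinks <- sort_cs(union(sinks, rewired))

  # factor loadings per phenotype: module factors 1..M, then per rewired
  # gene one "new inflow" factor H and two sign-flip pair factors E1, E2
  M <- max(membership)
  R <- length(rewired)
  n_fac <- M + 3L * R
  rho <- cfg$module_correlation
  W1 <- matrix(0, n, n_fac, dimnames = list(genes, NULL))
  W2 <- matrix(0, n, n_fac, dimnames = list(genes, NULL))
  W1[cbind(seq_len(n), membership)] <- sqrt(rho)
  W2[cbind(seq_len(n), membership)] <- sqrt(rho)
  # Rewired gene g, phenotype 2: dominated by a shared "new inflow" factor H.
  # Two of the gained edges are gate-strength (near-perfect correlation, so
  # they open the functional-neighbourhood filter above any realistic SFN
  # in phenotype 2 only). The flip partners, tied to g through pair factors
  # E1/E2 in phenotype 1, load H *negatively* in phenotype 2, so their
  # correlation with g changes sign decisively in both magnitude regimes.
  if (R > 0) {
    for (r in seq_len(R)) {
      g <- rewired[r]
      H <- M + 3L * (r - 1L) + 1L
      E1 <- H + 1L
      E2 <- H + 2L
      W1[g, ] <- 0; W2[g, ] <- 0
      W1[g, membership[g]] <- sqrt(0.25)
      W1[g, E1] <- sqrt(0.35); W1[g, E2] <- sqrt(0.35)
      W2[g, membership[g]] <- sqrt(0.002); W2[g, H] <- sqrt(0.97)
      pn <- partners_new[[g]]
      h_w <- c(0.995, 0.995, 0.50) # two gate-strength inflows, one moderate
      m_w <- c(0.003, 0.003, 0.45)
      for (i in seq_along(pn)) {
        p <- pn[i]
        W2[p, ] <- 0
        W2[p, membership[p]] <- sqrt(m_w[i])
        W2[p, H] <- sqrt(h_w[i])
      }
      qs <- partners_flip[[g]]
      for (i in seq_along(qs)) {
        q <- qs[i]
        E <- if (i == 1) E1 else E2
        W1[q, ] <- 0; W2[q, ] <- 0
        W1[q, membership[q]] <- sqrt(0.10); W1[q, E] <- sqrt(0.85)
        W2[q, membership[q]] <- sqrt(0.45); W2[q, H] <- -sqrt(0.50)
      }
    }
  }

  # latent (pre-noise, pre-transform) edge correlations per phenotype
  el <- igraph::as_edgelist(net, names = TRUE)
  cor1 <- rowSums(W1[el[, 1], , drop = FALSE] * W1[el[, 2], , drop = FALSE])
  cor2 <- rowSums(W2[el[, 1], , drop = FALSE] * W2[el[, 2], , drop = FALSE])
  edge_cor <- data.frame(gene1 = el[, 1], gene2 = el[, 2],
                         cor_phenotype1 = cor1, cor_phenotype2 = cor2,
                         stringsAsFactors = FALSE)

  structure(list(sources = sort_cs(sources), sinks = sinks,
                 rewired = sort_cs(rewired), partners_new = partners_new,
                 partners_flip = partners_flip, membership = membership,
                 weights = list(phenotype1 = W1, phenotype2 = W2),
                 edge_cor = edge_cor),
            class = "synthetic_truth")
}

#' Generate modular GO annotations for a synthetic interactome
#'
#' Genes of one module share a synthetic module term; every gene receives a
#' configurable number of random extra terms from a common pool; planted
#' sink genes additionally carry GO:0006355 (the default sink-defining
#' term); each planted rewired gene shares a dedicated process term with its
#' planted partners, emulating the shared biological process of a rewiring
#' event.
#'
#' @param net synthetic interactome from [generate_ppi()].
#' @param cfg a [synthetic_config()].
#' @param truth optional `synthetic_truth`; computed from `net` and `cfg`
#'   when missing.
#' @return an `annotation_map`.
#' @export
generate_annotations <- function(net, cfg, truth = NULL) {
  truth <- truth %||% generate_truth(net, cfg)
  genes <- igraph::V(net)$name
  set.seed(cfg$seed + 2L)
  module_terms <- sprintf("GO:%07d", 9100000L + seq_len(max(truth$membership)))
  pool <- sprintf("GO:%07d", 9200000L + seq_len(cfg$term_pool))
  g_list <- character(0)
  t_list <- character(0)
  for (g in genes) {
    terms <- module_terms[truth$membership[g]]
    n_extra <- if (cfg$extra_terms[2] > 0) {
      cfg$extra_terms[1] +
        sample.int(cfg$extra_terms[2] - cfg$extra_terms[1] + 1L, 1) - 1L
    } else 0L
    if (n_extra > 0) terms <- c(terms, sample(pool, n_extra))
    g_list <- c(g_list, rep(g, length(terms)))
    t_list <- c(t_list, terms)
  }
  if (length(truth$sinks) > 0) {
    g_list <- c(g_list, truth$sinks)
    t_list <- c(t_list, rep("GO:0006355", length(truth$sinks)))
  }
  if (length(truth$rewired) > 0) {
    for (r in seq_along(truth$rewired)) {
      g <- truth$rewired[r]
      # the gained partners share a process term among themselves (their
      # edges to g become traversable only once a gate edge exceeds the
      # SFN threshold in phenotype 2); the sign-flip pair shares a process
      # with g directly, so those edges are traversable in both phenotypes
      grp_new <- truth$partners_new[[g]]
      grp_flip <- c(g, truth$partners_flip[[g]])
      g_list <- c(g_list, grp_new, grp_flip)
      t_list <- c(t_list,
                  rep(sprintf("GO:%07d", 9310000L + r), length(grp_new)),
                  rep(sprintf("GO:%07d", 9320000L + r), length(grp_flip)))
    }
  }
  annotation_map(g_list, t_list)
}

#' Generate two-phenotype expression with planted structure
#'
#' Latent-factor model: each module has a per-sample standard-normal
#' activity; gene log-expression is its loading combination plus residual
#' noise, scaled to a common log-scale standard deviation (`noise_sd`), with
#' planted sources shifted by `effect_size * noise_sd` in phenotype 2.
#' Values are exponentiated, so the matrix is strictly positive and ready
#' for [normalize_expression()].
#'
#' @param net synthetic interactome.
#' @param truth a `synthetic_truth` from the same configuration.
#' @param cfg a [synthetic_config()].
#' @return an unnormalized [expr_matrix()] with phenotypes `phenotype1` and
#'   `phenotype2`.
#' @export
generate_expression <- function(net, truth, cfg) {
  genes <- igraph::V(net)$name
  n <- length(genes)
  ns <- cfg$n_samples
  set.seed(cfg$seed + 3L)
  samples <- c(sprintf("P1_S%03d", seq_len(ns)), sprintf("P2_S%03d", seq_len(ns)))
  design <- stats::setNames(rep(c("phenotype1", "phenotype2"), each = ns),
                            samples)
  n_fac <- ncol(truth$weights$phenotype1)
  FA <- matrix(rnorm(n_fac * 2 * ns), n_fac, 2 * ns)
  EPS <- matrix(rnorm(n * 2 * ns), n, 2 * ns)
  z <- matrix(0, n, 2 * ns, dimnames = list(genes, samples))
  for (ph in 1:2) {
    cols <- seq((ph - 1) * ns + 1, ph * ns)
    W <- truth$weights[[ph]]
    resid <- sqrt(pmax(0, 1 - rowSums(W^2)))
    z[, cols] <- W %*% FA[, cols, drop = FALSE] +
      resid * EPS[, cols, drop = FALSE]
  }
  z <- z * cfg$noise_sd
  if (length(truth$sources) > 0) {
    z[truth$sources, design == "phenotype2"] <-
      z[truth$sources, design == "phenotype2"] +
      cfg$effect_size * cfg$noise_sd
  }
  expr_matrix(exp(z), design)
}

#' Generate a complete synthetic fixture
#'
#' Produces the interactome, annotations, expression matrix and planted
#' truth for one configuration, optionally writing them in the exact file
#' formats the readers consume (`expression.tsv`, `design.tsv`, `ppi.tsv`,
#' `annotations.tsv`, plus `truth.json` and `config.yaml`).
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir optional output directory.
#' @return (invisibly when writing) a list with `net`, `annot`, `expr`,
#'   `truth`, `cfg` and, if written, `files`.
#' @export
generate_fixture <- function(cfg, out_dir = NULL) {
  net <- generate_ppi(cfg)
  truth <- generate_truth(net, cfg)
  annot <- generate_annotations(net, cfg, truth)
  expr <- generate_expression(net, truth, cfg)
  bundle <- list(net = net, annot = annot, expr = expr, truth = truth,
                 cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f_expr <- file.path(out_dir, "expression.tsv")
    tab <- data.frame(gene = rownames(expr$values), expr$values,
                      check.names = FALSE)
    write.table(tab, f_expr, sep = "\t", quote = FALSE, row.names = FALSE)
    f_des <- file.path(out_dir, "design.tsv")
    write.table(data.frame(sample = names(expr$design),
                           phenotype = unname(expr$design)),
                f_des, sep = "\t", quote = FALSE, row.names = FALSE)
    f_ppi <- file.path(out_dir, "ppi.tsv")
    el <- igraph::as_edgelist(net, names = TRUE)
    write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
                f_ppi, sep = "\t", quote = FALSE, row.names = FALSE)
    f_ann <- file.path(out_dir, "annotations.tsv")
    ann_tab <- data.frame(
      gene = rep(names(annot), lengths(annot)),
      go_term = unlist(unname(annot)))
    write.table(ann_tab, f_ann, sep = "\t", quote = FALSE, row.names = FALSE)
    f_truth <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(sources = truth$sources, sinks = truth$sinks,
           rewired = truth$rewired, partners_new = truth$partners_new,
           partners_flip = truth$partners_flip,
           membership = as.list(truth$membership)),
      f_truth, auto_unbox = FALSE, digits = NA)
    f_cfg <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(cfg), f_cfg)
    bundle$files <- c(expression = f_expr, design = f_des, ppi = f_ppi,
                      annotations = f_ann, truth = f_truth, config = f_cfg)
    return(invisible(bundle))
  }
  bundle
}
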