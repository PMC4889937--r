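#' Default sink-defining GO terms (transcriptional regulation)
#'
#' GO:0003676 nucleic acid binding; GO:0006355 regulation of transcription,
#' DNA-templated; GO:0008134 transcription factor binding.
#' @export
DEFAULT_SINK_TERMS <- c("GO:0003676", "GO:0006355", "GO:0008134")

#' Select source genes by template matching
#'
#' Scores every gene by the Pearson correlation between its expression vector
#' (across all samples of both phenotypes) and the binary phenotype template
#' (1 for samples of the phenotype of interest, 0 otherwise), then returns
#' the top fraction. This is a pure ranking; no significance testing is
#' attached. Genes with undefined scores (constant expression) are excluded.
#' Score ordering is invariant to affine rescaling of any gene's expression.
#'
#' @param expr an [expr_matrix()] whose design has exactly two phenotypes.
#' @param phenotype_of_interest the phenotype matched by the template.
#' @param fraction fraction of genes to keep (default 0.005, i.e. top 0.5%);
#'   `ceiling(fraction * n_genes)` genes are returned.
#' @return a `source_set`: data frame with columns `gene` and `score`, sorted
#'   by decreasing score (ties broken by gene name), with attributes
#'   `fraction` and `phenotype`.
#' @export
template_match <- function(expr, phenotype_of_interest, fraction = 0.005) {
  stopifnot(inherits(expr, "expr_matrix"))
  phen <- unique(expr$design)
  if (length(phen) != 2) {
    stop("template matching needs exactly two phenotypes, got ",
         length(phen))
  }
  if (!phenotype_of_interest %in% phen) {
    stop("unknown phenotype: ", phenotype_of_interest)
  }
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  template <- as.numeric(expr$design[colnames(expr$values)] ==
                           phenotype_of_interest)
  score <- suppressWarnings(as.vector(stats::cor(t(expr$values), template)))
  names(score) <- rownames(expr$values)
  score[!is.finite(score)] <- -Inf
  n_top <- ceiling(fraction * length(score))
  if (n_top < 1) stop("fraction selects zero genes")
  ord <- order(-score, names(score), method = "radix")
  top <- ord[seq_len(n_top)]
  out <- data.frame(gene = names(score)[top], score = score[top],
                    row.names = NULL)
  if (any(!is.finite(out$score))) {
    out <- out[is.finite(out$score), , drop = FALSE]
    if (nrow(out) == 0) stop("no gene has a defined template-matching score")
  }
  structure(out, class = c("source_set", "data.frame"),
            fraction = fraction, phenotype = phenotype_of_interest)
}

#' Define sink genes by GO-term membership
#'
#' Sinks are the network genes annotated with at least one of the defining
#' GO terms. The default terms select genes involved in transcriptional
#' regulation; pass custom terms (e.g. apoptosis, cell cycle, drug targets)
#' to redirect flow to other endpoints. Terms are matched literally, without
#' propagation up the GO hierarchy.
#'
#' @param annot an `annotation_map`, see [read_annotations()].
#' @param terms character vector of defining GO terms.
#' @param net interactome graph; sinks are restricted to its vertices.
#' @return a `sink_set`: sorted character vector of sink genes with
#'   attribute `terms`.
#' @export
define_sinks <- function(annot, terms = DEFAULT_SINK_TERMS, net) {
  nodes <- igraph::V(net)$name
  annotated <- intersect(names(annot), nodes)
  hit <- vapply(annot[annotated],
                function(x) any(terms %in% x), logical(1))
  sinks <- sort_cs(annotated[hit])
  if (length(sinks) == 0) {
    stop("no network gene is annotated with any sink-defining GO term; ",
         "no flow possible")
  }
  structure(sinks, class = "sink_set", terms = terms)
}
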