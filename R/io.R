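#' Construct an expression matrix with a sample design
#'
#' Bundles a genes-by-samples matrix of non-negative expression values with a
#' sample-to-phenotype design. Duplicate gene rows are averaged. A phenotype
#' needs at least 3 samples for a within-phenotype Pearson correlation to be
#' defined; fewer than 5 samples triggers a warning because correlation
#' estimates are unstable at that depth.
#'
#' @param values numeric matrix, genes in rows (rownames required), samples in
#'   columns (colnames required).
#' @param design named character vector mapping sample name to phenotype label.
#' @param normalized logical; whether columns already sum to one.
#' @return an object of class `expr_matrix` with elements `values`, `design`
#'   and `normalized`.
#' @export
expr_matrix <- function(values, design, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (!all(colnames(values) %in% names(design))) {
    missing <- setdiff(colnames(values), names(design))
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  }
  design <- design[colnames(values)]
  if (anyDuplicated(rownames(values))) {
    g <- rownames(values)
    sums <- rowsum(values, group = g)
    counts <- table(g)
    values <- sums / as.vector(counts[rownames(sums)])
  }
  values <- values[order_cs(rownames(values)), , drop = FALSE]
  tab <- table(design)
  if (any(tab < 5)) {
    warning("phenotype(s) with fewer than 5 samples: ",
            paste(names(tab)[tab < 5], collapse = ", "),
            " (correlations need >= 3 samples and are noisy below 5)")
  }
  structure(list(values = values, design = design, normalized = normalized),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples;",
      "phenotypes:", paste(sprintf("%s (n=%d)", names(table(x$design)),
                                   table(x$design)), collapse = ", "),
      if (x$normalized) "[normalized]" else "[raw]", "\n")
  invisible(x)
}

#' Read an expression matrix and its design table
#'
#' The expression file is a tab-delimited table with a header row: first
#' column gene identifiers, remaining columns one per sample. The design file
#' is tab-delimited with columns `sample` and `phenotype`. Duplicate gene rows
#' (e.g. several probesets mapping to one gene) are averaged.
#'
#' @param path path to the expression TSV.
#' @param design_path path to the design TSV.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path, design_path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expression file needs a gene column plus >= 1 sample column")
  genes <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(vals) & !(trimws(cells) %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]))
  }
  rownames(vals) <- genes
  des <- read.delim(design_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character", quote = "")
  if (!all(c("sample", "phenotype") %in% colnames(des))) {
    stop("design file needs columns 'sample' and 'phenotype'")
  }
  design <- stats::setNames(des$phenotype, des$sample)
  expr_matrix(vals, design)
}

#' Normalize expression columns to unit sum
#'
#' Divides every expression value by the total expression of its sample
#' (array), so that each sample column sums to one. Gene-gene Pearson
#' correlations are invariant to this per-column scaling. Idempotent.
#'
#' @param m an [expr_matrix()].
#' @return the normalized `expr_matrix`.
#' @export
normalize_expression <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (any(m$values < 0)) stop("expression values must be non-negative before normalization")
  tot <- colSums(m$values)
  if (any(tot == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(m$values)[tot == 0], collapse = ", "))
  }
  m$values <- sweep(m$values, 2, tot, "/")
  m$normalized <- TRUE
  m
}

#' Read gene-to-GO annotations
#'
#' Two formats: `"tsv"`, a tab-delimited two-column table (gene, GO term)
#' with a header row; `"gaf"`, GO annotation format 2.x, of which only the
#' object symbol (column 3) and GO ID (column 5) are used and rows whose
#' qualifier (column 4) contains `NOT` are skipped. Rows with malformed GO
#' identifiers (not `GO:` + 7 digits) are skipped and counted.
#'
#' @param path input file.
#' @param format `"tsv"` or `"gaf"`.
#' @return an `annotation_map`: named list mapping gene to a character vector
#'   of GO terms. Query genes absent from the map with [annotation_terms()].
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character", quote = "")
    genes <- df[[1]]
    terms <- df[[2]]
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) {
      length(f) >= 5 && !grepl("NOT", f[4], fixed = TRUE)
    }, logical(1))
    fields <- fields[keep]
    genes <- vapply(fields, `[`, character(1), 3)
    terms <- vapply(fields, `[`, character(1), 5)
  }
  ok <- grepl("^GO:[0-9]{7}$", terms)
  if (any(!ok)) {
    message(sum(!ok), " annotation row(s) with malformed GO identifiers skipped")
  }
  genes <- genes[ok]
  terms <- terms[ok]
  amap <- lapply(split(terms, genes), function(x) sort_cs(unique(x)))
  amap <- amap[order_cs(names(amap))]
  structure(amap, class = "annotation_map")
}

#' Build an annotation map from vectors
#' @param genes,terms parallel character vectors of gene/GO-term pairs.
#' @return an `annotation_map`.
#' @export
annotation_map <- function(genes, terms) {
  stopifnot(length(genes) == length(terms))
  amap <- lapply(split(as.character(terms), as.character(genes)),
                 function(x) sort_cs(unique(x)))
  amap <- amap[order_cs(names(amap))]
  structure(amap, class = "annotation_map")
}

#' GO terms of a gene
#' @param annot an `annotation_map`.
#' @param gene gene identifier.
#' @return character vector of GO terms; empty for unannotated genes.
#' @export
annotation_terms <- function(annot, gene) {
  t <- annot[[gene]]
  if (is.null(t)) character(0) else t
}

#' Read a two-column PPI edge list
#'
#' Tab-delimited with a header row; the first two columns are the interacting
#' gene pair. Extra columns are ignored.
#'
#' @param path input TSV.
#' @return a two-column character data frame of raw (uncleaned) edges.
#' @export
read_ppi <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("PPI file needs two columns")
  data.frame(a = df[[1]], b = df[[2]], stringsAsFactors = FALSE)
}

#' Read a plain gene list (one gene per line, no header)
#' @param path input file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write a solved context subnetwork to disk
#'
#' Emits four files under `out_dir`: `<prefix>_edges.tsv` (source_node,
#' target_node, flow, capacity, pcc, cost), `<prefix>.sif` (relation `flow`),
#' `<prefix>.graphml` with the same edge attributes, and `<prefix>_nodes.tsv`
#' (node, total_flow, role). Edge direction records the orientation along
#' which the optimizer routed flow, not causality.
#'
#' @param sub a `context_subnetwork` from [solve_min_cost_flow()].
#' @param out_dir output directory (created if missing).
#' @param prefix file name prefix; defaults to the phenotype label.
#' @return invisibly, the paths written.
#' @export
write_subnetwork <- function(sub, out_dir, prefix = NULL) {
  stopifnot(inherits(sub, "context_subnetwork"))
  prefix <- prefix %||% gsub("[^A-Za-z0-9._-]", "_", sub$phenotype)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  e <- sub$edges
  edge_tab <- data.frame(source_node = e$from, target_node = e$to,
                         flow = e$flow, capacity = e$capacity,
                         pcc = e$pcc, cost = e$cost)
  f_edges <- file.path(out_dir, paste0(prefix, "_edges.tsv"))
  write.table(edge_tab, f_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  f_sif <- file.path(out_dir, paste0(prefix, ".sif"))
  sif <- if (nrow(e) > 0) paste(e$from, "flow", e$to) else character(0)
  writeLines(sif, f_sif)
  f_nodes <- file.path(out_dir, paste0(prefix, "_nodes.tsv"))
  n <- sub$nodes
  write.table(data.frame(node = n$gene, total_flow = n$total_flow,
                         role = n$role),
              f_nodes, sep = "\t", quote = FALSE, row.names = FALSE)
  f_gml <- file.path(out_dir, paste0(prefix, ".graphml"))
  g <- igraph::graph_from_data_frame(
    if (nrow(e) > 0) e else data.frame(from = character(0), to = character(0)),
    directed = TRUE,
    vertices = if (nrow(n) > 0) data.frame(name = n$gene,
                                           total_flow = n$total_flow,
                                           role = n$role) else NULL)
  igraph::write_graph(g, f_gml, format = "graphml")
  invisible(c(edges = f_edges, sif = f_sif, nodes = f_nodes, graphml = f_gml))
}
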