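`%||%` <- function(a, b) if (is.null(a)) b else a

# locale-independent sort, used everywhere a deterministic order matters
sort_cs <- function(x) sort(x, method = "radix")

order_cs <- function(...) order(..., method = "radix")

# canonical undirected edge key "min|max"
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# names of the auxiliary flow nodes; fail loudly on the (pathological)
# collision with a real gene identifier
AUX_SOURCE <- "__s__"
AUX_SINK <- "__t__"

check_aux_collision <- function(genes) {
  if (any(c(AUX_SOURCE, AUX_SINK) %in% genes)) {
    stop("gene identifiers collide with reserved auxiliary node names '",
         AUX_SOURCE, "'/'", AUX_SINK, "'")
  }
  invisible(TRUE)
}
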