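# Independent linear-programming oracle for min-cost max-flow, built on
# pracma::linprog (two-stage: maximize net outflow of s, then minimize cost
# with the flow held at that maximum). Kept free of any code path shared
# with the package's solver.

lp_mcmf <- function(nodes, arcs, s = "__s__", t = "__t__") {
  m <- nrow(arcs)
  mid <- setdiff(nodes, c(s, t))
  Aeq <- matrix(0, length(mid), m)
  for (k in seq_len(m)) {
    i <- match(arcs$from[k], mid)
    j <- match(arcs$to[k], mid)
    if (!is.na(i)) Aeq[i, k] <- Aeq[i, k] + 1
    if (!is.na(j)) Aeq[j, k] <- Aeq[j, k] - 1
  }
  A <- diag(m)
  b <- arcs$capacity
  cc <- as.numeric(arcs$from == s) - as.numeric(arcs$to == s)
  r1 <- pracma::linprog(cc, A = A, b = b, Aeq = Aeq,
                        beq = rep(0, length(mid)), maximize = TRUE,
                        maxiter = 1000)
  val <- sum(r1$x * cc)
  # hold the flow at its maximum and minimize cost; the bigM simplex can
  # cycle on either formulation, so try the inequality bound first and fall
  # back to an equality row
  cost_of <- function(r) {
    if (is.null(r) || !is.numeric(r$x) || anyNA(r$x) ||
        (!is.null(r$errno) && r$errno < 0)) NA_real_
    else sum(r$x * arcs$cost)
  }
  A2 <- rbind(A, -cc)
  b2 <- c(b, -(val - 1e-9))
  r2 <- tryCatch(pracma::linprog(arcs$cost, A = A2, b = b2, Aeq = Aeq,
                                 beq = rep(0, length(mid)), maximize = FALSE,
                                 maxiter = 1000), error = function(e) NULL)
  cost <- cost_of(r2)
  if (is.na(cost)) {
    r3 <- tryCatch(pracma::linprog(arcs$cost, A = A, b = b,
                                   Aeq = rbind(Aeq, cc),
                                   beq = c(rep(0, length(mid)), val),
                                   maximize = FALSE, maxiter = 1000),
                   error = function(e) NULL)
    cost <- cost_of(r3)
  }
  list(value = val, cost = cost)
}

# seeded random multi-source multi-sink flow instance (<= 12 real nodes,
# <= 20 internal arcs) expressed as a flow_network the solver accepts
rand_flow_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- sample(6:20, 1)
  sel <- pairs[sample.int(nrow(pairs), min(m, nrow(pairs))), ]
  arcs <- data.frame(from = sel$from, to = sel$to,
                     capacity = sample(1:20, nrow(sel), TRUE) / 7,
                     cost = sample(0:15, nrow(sel), TRUE) / 11,
                     pcc = NA_real_, type = "ppi", stringsAsFactors = FALSE)
  srcs <- sample(nodes, sample(1:3, 1))
  rest <- setdiff(nodes, srcs)
  snks <- sample(rest, sample(seq_len(min(3, length(rest))), 1))
  aux <- rbind(
    data.frame(from = "__s__", to = srcs, cost = 0, pcc = NA_real_,
               capacity = sample(1:20, length(srcs), TRUE) / 5,
               type = "source", stringsAsFactors = FALSE),
    data.frame(from = snks, to = "__t__", cost = 0, pcc = NA_real_,
               capacity = sample(1:20, length(snks), TRUE) / 5,
               type = "sink", stringsAsFactors = FALSE))
  all_arcs <- rbind(arcs, aux[, colnames(arcs)])
  all_arcs <- all_arcs[order(all_arcs$from, all_arcs$to, method = "radix"), ]
  rownames(all_arcs) <- NULL
  structure(list(nodes = nodes, arcs = all_arcs,
                 sources = sort(srcs, method = "radix"),
                 sinks = sort(snks, method = "radix"), phenotype = "x"),
            class = "flow_network")
}
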