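## ---- brute-force attractor oracle and random network ensembles -------------

#' Exhaustive attractors from the full state transition graph
#'
#' Builds the complete general-asynchronous state transition graph of the
#' environment-reduced network and extracts its terminal strongly connected
#' sets: steady states (no outgoing transitions) and complex attractors
#' (terminal oscillations).  Exponential in the number of free nodes; this
#' is the small-network oracle that the stable-motif method replaces at
#' scale.
#'
#' @param net a [boolean_network()] with environment resolved.
#' @param max_nodes guard on the number of free nodes (default 14).
#' @return list with `steady` (list of named 0/1 vectors over the free
#'   nodes), `oscillations` (list of 0/1 matrices, one row per state of the
#'   terminal set) and `fixed` (the environment-percolated context).
#' @export
brute_force_attractors <- function(net, max_nodes = 14L) {
  stopifnot(inherits(net, "boolean_network"))
  .check_environment(net)
  red <- bn_reduce(net, net$environment)
  nodes <- names(red$network$rules)
  n <- length(nodes)
  if (n > max_nodes)
    stop("state-space enumeration guard: ", n, " free nodes > ", max_nodes)
  if (n == 0L)
    return(list(steady = list(setNames(integer(0), character(0))),
                oscillations = list(), fixed = red$fixed))
  red$network$nodes <- nodes
  S <- .all_states(nodes)
  tts <- bn_truth_tables(red$network)
  Fm <- sapply(nodes, function(nm) .evaluate_rows(tts[[nm]], S))
  Fm <- matrix(Fm, ncol = n)
  idx <- seq_len(2L^n)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    ch <- which(Fm[, i] != S[, i])
    if (length(ch)) {
      from <- c(from, ch)
      to <- c(to, ch + (Fm[ch, i] - S[ch, i]) * 2L^(i - 1L))
    }
  }
  outdeg <- tabulate(from, nbins = 2L^n)
  steady_idx <- which(outdeg == 0L)
  oscillations <- list()
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
    g <- igraph::add_vertices(g, max(0L, 2L^n - igraph::vcount(g)))
    comp <- igraph::components(g, mode = "strong")$membership
    ## terminal components: no edge leaving the component
    leaving <- unique(comp[from[comp[from] != comp[to]]])
    terminal <- setdiff(unique(comp), leaving)
    for (tc in terminal) {
      members <- which(comp == tc)
      if (length(members) == 1L && members %in% steady_idx) next
      if (length(members) == 1L) next   # transient singleton SCC
      oscillations[[length(oscillations) + 1L]] <-
        S[members, , drop = FALSE]
    }
  }
  steady <- lapply(steady_idx, function(j) setNames(S[j, ], nodes))
  list(steady = steady, oscillations = oscillations, fixed = red$fixed)
}

#' Generate a random Boolean network
#'
#' Each node receives `k` distinct regulators chosen uniformly (self-loops
#' allowed) and a random truth table with activation bias `p`.  Fully
#' reproducible from the seed.
#'
#' @param n number of nodes.
#' @param k in-degree (1 <= k <= n).
#' @param p probability that a truth-table row is 1.
#' @param seed integer seed.
#' @return a [boolean_network()] with nodes `x1 ... xn` and no inputs.
#' @export
random_boolean_network <- function(n, k = 2L, p = 0.5, seed = 1L) {
  stopifnot(n >= 1, k >= 1, k <= n, p > 0, p < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  nodes <- sprintf("x%d", seq_len(n))
  rules <- list()
  for (i in seq_len(n)) {
    ins <- sort(sample.int(n, k))
    tt <- rbinom(2L^k, 1L, p)
    rules[[nodes[[i]]]] <- .tt_to_expr(nodes[ins], tt)
  }
  boolean_network(rules)
}
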