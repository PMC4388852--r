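## ---- truth tables ----------------------------------------------------------
## The truth table of a rule lists f over all 2^k assignments of its k inputs,
## with input 1 as the least significant bit:  tt[1 + sum_j bit_j 2^(j-1)].

.MAX_RULE_INPUTS <- 20L

#' Truth table of one update rule
#'
#' @param net a [boolean_network()] object.
#' @param node name of a regulated node.
#' @return list with `inputs` (character vector, network node order) and
#'   `tt` (integer 0/1 vector of length `2^length(inputs)`).
#' @keywords internal
rule_truth_table <- function(net, node) {
  e <- net$rules[[node]]
  if (is.null(e)) stop("no rule for node ", node)
  ins <- expr_inputs(e)
  ins <- net$nodes[net$nodes %in% ins]   # deterministic order
  k <- length(ins)
  if (k > .MAX_RULE_INPUTS)
    stop(sprintf("rule for %s has %d inputs; truth-table guard is %d",
                 node, k, .MAX_RULE_INPUTS))
  if (k == 0L)
    return(list(inputs = character(0),
                tt = as.integer(eval(e, envir = baseenv()))))
  grid <- lapply(seq_len(k), function(j)
    rep(rep(c(FALSE, TRUE), each = 2L^(j - 1L)), length.out = 2L^k))
  names(grid) <- ins
  list(inputs = ins, tt = as.integer(eval(e, envir = grid)))
}

## truth tables for every regulated node (simulation / oracle backend)
bn_truth_tables <- function(net) {
  tts <- lapply(names(net$rules), function(nm) rule_truth_table(net, nm))
  names(tts) <- names(net$rules)
  tts
}

#' Evaluate one node's update rule on a complete system state
#'
#' Pure function: applies the node's Boolean rule to the given state and
#' returns the updated bit without modifying anything.
#'
#' @param net a [boolean_network()] object.
#' @param node node name (must have a rule; input nodes keep their
#'   environment state and evaluate to it).
#' @param state named 0/1 vector covering every node of the network.
#' @return 0 or 1.
#' @examples
#' net <- bn_parse("A* = A")
#' bn_evaluate(net, "A", c(A = 1))
#' @export
bn_evaluate <- function(net, node, state) {
  stopifnot(inherits(net, "boolean_network"))
  if (!node %in% net$nodes) stop("unknown node: ", node)
  missing <- setdiff(net$nodes, names(state))
  if (length(missing))
    stop("incomplete state; missing node(s): ",
         paste(missing, collapse = ", "))
  vals <- .parse_state_value(state)
  names(vals) <- names(state)
  if (!node %in% names(net$rules)) {
    if (node %in% names(net$environment)) return(net$environment[[node]])
    return(vals[[node]])   # unassigned input: retains its state
  }
  env <- as.list(vals == 1L)
  as.integer(eval(net$rules[[node]], envir = env))
}

## vectorized rule evaluation over a 0/1 state matrix (rows = states)
## returns the updated bit of `node` for every row
.evaluate_rows <- function(tt, states) {
  k <- length(tt$inputs)
  if (k == 0L) return(rep(tt$tt, nrow(states)))
  idx <- rep(1L, nrow(states))
  for (j in seq_len(k))
    idx <- idx + states[, tt$inputs[[j]]] * 2L^(j - 1L)
  tt$tt[idx]
}

## all 2^n states over `nodes` as a 0/1 matrix (node 1 = LSB)
.all_states <- function(nodes) {
  n <- length(nodes)
  m <- sapply(seq_len(n), function(j)
    rep(rep(c(0L, 1L), each = 2L^(j - 1L)), length.out = 2L^n))
  m <- matrix(m, nrow = 2L^n, dimnames = list(NULL, nodes))
  m
}
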