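## ---- network reduction (substitute and simplify) ---------------------------

## empty network produced when reduction fixes every node
.empty_network <- function() {
  structure(list(nodes = character(0), rules = list(),
                 inputs = character(0), environment = integer(0)),
            class = "boolean_network")
}

## merge two partial node->state maps; error on conflict
.merge_fixed <- function(a, b) {
  common <- intersect(names(a), names(b))
  bad <- common[a[common] != b[common]]
  if (length(bad))
    stop("contradiction: node(s) fixed to both 0 and 1: ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- c(a, b[setdiff(names(b), names(a))])
  out
}

#' Substitute fixed node states and simplify until closure
#'
#' Fixes the given nodes (overriding their own rules, as an external clamp
#' does), partially evaluates every other rule, and promotes any rule that
#' becomes constant into the fixed set, repeating until no further node
#' stabilizes (logical percolation).  The surviving rules are re-expressed in
#' canonical disjunctive normal form built from their prime implicants, so
#' reduction is idempotent.
#'
#' @param net a [boolean_network()] object.
#' @param fixed named vector of 0/1 (or ON/OFF) states; names must be
#'   network nodes.  May be empty.
#' @return list with `network` (the reduced network on the remaining free
#'   nodes; may be empty) and `fixed` (named integer vector: the total fixed
#'   mapping after percolation, in network node order).
#' @examples
#' net <- bn_parse(c("A* = A and B", "B* = A"))
#' bn_reduce(net, c(A = 0))$fixed
#' @export
bn_reduce <- function(net, fixed = integer(0)) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(fixed)) {
    vals <- .parse_state_value(fixed)
    names(vals) <- names(fixed)
    if (anyDuplicated(names(vals))) {
      dup <- unique(names(vals)[duplicated(names(vals))])
      for (d in dup)
        if (length(unique(vals[names(vals) == d])) > 1L)
          stop("contradiction: node(s) fixed to both 0 and 1: ", d,
               call. = FALSE)
      vals <- vals[!duplicated(names(vals))]
    }
    unknown <- setdiff(names(vals), net$nodes)
    if (length(unknown))
      stop("fixed names not in network: ", paste(unknown, collapse = ", "))
    total <- vals
  } else total <- integer(0)

  tts <- bn_truth_tables(net)
  repeat {
    changed <- FALSE
    for (nm in names(tts)) {
      if (nm %in% names(total)) next
      tt <- .restrict_tt(tts[[nm]], total)
      tts[[nm]] <- tt
      if (length(tt$inputs) == 0L || all(tt$tt == tt$tt[1L])) {
        total <- .merge_fixed(total, setNames(tt$tt[1L], nm))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  free <- setdiff(net$nodes, names(total))
  free_reg <- intersect(names(net$rules), free)
  if (!length(free_reg)) {
    rednet <- .empty_network()
    ## free unregulated inputs (no rule, not fixed) survive untouched
    if (length(free)) {
      rednet$nodes <- free
      rednet$inputs <- free
    }
  } else {
    rules <- lapply(free_reg, function(nm) {
      tt <- tts[[nm]]
      .tt_to_expr(tt$inputs, tt$tt)
    })
    names(rules) <- free_reg
    rednet <- boolean_network(rules)
    keepenv <- intersect(names(net$environment), rednet$inputs)
    keepenv <- setdiff(keepenv, names(total))
    if (length(keepenv)) rednet$environment <- net$environment[keepenv]
  }
  total <- total[order(match(names(total), net$nodes))]
  list(network = rednet, fixed = total)
}

## restrict a truth table by a partial assignment of its inputs
.restrict_tt <- function(tt, fixed) {
  hit <- intersect(tt$inputs, names(fixed))
  if (!length(hit)) return(tt)
  k <- length(tt$inputs)
  keep_rows <- rep(TRUE, 2L^k)
  for (nm in hit) {
    j <- match(nm, tt$inputs)
    bit <- bitwAnd((seq_len(2L^k) - 1L) %/% 2L^(j - 1L), 1L)
    keep_rows <- keep_rows & (bit == fixed[[nm]])
  }
  new_inputs <- setdiff(tt$inputs, hit)
  list(inputs = new_inputs, tt = tt$tt[keep_rows])
}
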