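## ---- stable motifs ---------------------------------------------------------
## A stable motif is a set of node states whose literals form a minimal
## consistent self-sustaining set of the expanded network: every literal in
## the set has at least one prime implicant wholly inside the set, no node
## appears in both states, and no proper subset has the same property.
## Minimality makes the supporting subgraph strongly connected (a source
## strongly connected component of any choice of sustaining implicants would
## itself be self-sustaining), so such sets are exactly the minimal strongly
## connected partial fixed points.

## enumerate all minimal consistent self-sustaining literal sets
.minimal_stable_sets <- function(imps, nlit) {
  found <- list()
  visited <- new.env(parent = emptyenv(), hash = TRUE)

  superset_of_found <- function(S) {
    for (f in found) if (all(f %in% S)) return(TRUE)
    FALSE
  }
  consistent_with <- function(S, I) {
    !any(.lit_compl(I) %in% S) && !any(.lit_compl(I) %in% I)
  }
  expand <- function(S) {
    key <- paste(S, collapse = ",")
    if (!is.null(visited[[key]])) return(invisible())
    assign(key, TRUE, envir = visited)
    if (superset_of_found(S)) return(invisible())
    ## first literal lacking an implicant inside S
    open <- 0L
    for (l in S) {
      ok <- FALSE
      for (im in imps[[l]]) if (all(im %in% S)) { ok <- TRUE; break }
      if (!ok) { open <- l; break }
    }
    if (open == 0L) {
      found[[length(found) + 1L]] <<- S
      return(invisible())
    }
    for (im in imps[[open]]) {
      if (!length(im)) next
      if (all(im %in% S)) next
      if (consistent_with(S, im)) expand(sort(unique(c(S, im))))
    }
    invisible()
  }

  for (seed in seq_len(nlit))
    if (length(imps[[seed]])) expand(seed)

  ## keep only inclusion-minimal sets, deduplicated
  if (!length(found)) return(list())
  keys <- vapply(found, paste, character(1), collapse = ",")
  found <- found[!duplicated(keys)]
  sizes <- vapply(found, length, integer(1))
  found <- found[order(sizes)]
  minimal <- list()
  for (S in found) {
    if (!any(vapply(minimal, function(f) all(f %in% S), logical(1))))
      minimal[[length(minimal) + 1L]] <- S
  }
  minimal
}

#' Find the stable motifs of a Boolean network
#'
#' Stable motifs are self-sustaining sets of node states: the nodes form a
#' minimal strongly connected component of the expanded network and their
#' states are a partial fixed point, so once the motif's states are reached
#' they can never be left ("points of no return").  Input nodes fixed by the
#' environment are external constants and never part of a motif; the search
#' runs on the network reduced by its environment.
#'
#' @param net a [boolean_network()] object with its environment resolved.
#' @return list of `stable_motif` objects, each a named 0/1 integer vector
#'   of node states with a `support` attribute (the literal labels of the
#'   supporting expanded-network vertices), ordered by motif node names and
#'   states.
#' @examples
#' net <- bn_parse("A* = A")
#' find_stable_motifs(net)
#' @export
find_stable_motifs <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  .check_environment(net)
  red <- bn_reduce(net, net$environment)$network
  nodes <- names(red$rules)
  if (!length(nodes)) return(list())
  red$nodes <- nodes
  imps <- .literal_implicants(red)
  sets <- .minimal_stable_sets(imps, 2L * length(nodes))
  motifs <- lapply(sets, function(S) {
    states <- setNames(.lit_state(S), nodes[.lit_node(S)])
    states <- states[order(match(names(states), nodes))]
    structure(states, class = "stable_motif",
              support = sprintf("%s=%d", names(states), states))
  })
  keys <- vapply(motifs, .motif_key, character(1))
  motifs[order(keys)]
}

.motif_key <- function(m) paste(sprintf("%s=%d", names(m), m), collapse = ",")

#' @export
print.stable_motif <- function(x, ...) {
  cat("{", paste(sprintf("%s = %d", names(x), x), collapse = ", "), "}\n")
  invisible(x)
}

#' Test whether a partial state assignment is a partial fixed point
#'
#' A partial assignment is a partial fixed point when updating any assigned
#' node returns its assigned state for every completion of the unassigned
#' nodes.  Decided symbolically: each assigned node's rule, restricted by
#' the assignment, must be the constant equal to its assigned state.
#'
#' @param net a [boolean_network()] object.  Environment states and rules
#'   that become constant under percolation are resolved first, as in the
#'   attractor-finding method itself; the check then applies to the
#'   remaining free nodes.
#' @param partial named vector of 0/1 (or ON/OFF) states; the empty
#'   assignment is vacuously a partial fixed point.  Percolation-fixed
#'   nodes may appear if they carry their percolated state.
#' @return TRUE or FALSE.
#' @export
is_partial_fixed_point <- function(net, partial) {
  stopifnot(inherits(net, "boolean_network"))
  if (!length(partial)) return(TRUE)
  vals <- .parse_state_value(partial)
  names(vals) <- names(partial)
  unknown <- setdiff(names(vals), net$nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  red <- bn_reduce(net, net$environment)
  for (nm in names(vals)) {
    if (nm %in% names(red$fixed)) {
      if (red$fixed[[nm]] != vals[[nm]]) return(FALSE)
      next
    }
    tt <- .restrict_tt(rule_truth_table(red$network, nm), vals)
    if (!all(tt$tt == vals[[nm]])) return(FALSE)
  }
  TRUE
}
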