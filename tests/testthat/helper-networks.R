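## shared fixtures and independent oracles, built in code

toy_network <- function() bn_fixture("toy_fig1")$network

toy_rules <- function() c(
  "A* = A and (B or not E)",
  "B* = A",
  "C* = B or not E",
  "D* = (C and not E) or (D and not B) or (E and not B)",
  "E* = E or (not D and not B)")

## XNOR pair: one fixed point {A=1,B=1} plus a 3-state unstable oscillation
xnor_network <- function() bn_parse(c(
  "A* = (A and B) or (not A and not B)",
  "B* = (A and B) or (not A and not B)"))

motif_keys <- function(motifs)
  sort(vapply(motifs, function(m)
    paste(sprintf("%s=%d", names(m), m), collapse = ","), character(1)))

set_key <- function(s)
  paste(sprintf("%s=%d", names(s), s), collapse = ",")

## independent truth-table evaluation of one rule on a complete state
## (direct lookup; does not share code with bn_evaluate)
oracle_eval <- function(net, node, state) {
  e <- net$rules[[node]]
  ev <- function(x) {
    if (isTRUE(x)) return(1L)
    if (isFALSE(x)) return(0L)
    if (is.name(x)) return(state[[as.character(x)]])
    op <- as.character(x[[1L]])
    if (op == "!") return(1L - ev(x[[2L]]))
    if (op == "&") return(ev(x[[2L]]) * ev(x[[3L]]))
    if (op == "|") return(max(ev(x[[2L]]), ev(x[[3L]])))
    stop("bad op")
  }
  ev(e)
}

## brute-force partial fixed point check by exhaustive completion
oracle_is_pfp <- function(net, partial) {
  free <- setdiff(net$nodes, names(partial))
  grid <- if (length(free))
    expand.grid(rep(list(0:1), length(free)), KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)
  for (r in seq_len(nrow(grid))) {
    st <- partial
    if (length(free)) st[free] <- as.integer(grid[r, ])
    for (nm in names(partial))
      if (oracle_eval(net, nm, st) != partial[[nm]]) return(FALSE)
  }
  TRUE
}

## all minimal nonempty partial fixed points by exhaustive enumeration
## (independent oracle for the stable motif search; feasible for n <= 8)
oracle_minimal_pfps <- function(net) {
  n <- length(net$nodes)
  stopifnot(n <= 8)
  found <- list()
  ## enumerate partial assignments in order of increasing size
  for (size in 1:n) {
    for (cb in utils::combn(n, size, simplify = FALSE)) {
      vals <- expand.grid(rep(list(0:1), size), KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(vals))) {
        p <- setNames(as.integer(vals[r, ]), net$nodes[cb])
        sup <- any(vapply(found, function(f)
          all(names(f) %in% names(p)) && all(p[names(f)] == f), logical(1)))
        if (sup) next
        if (oracle_is_pfp(net, p)) found[[length(found) + 1L]] <- p
      }
    }
  }
  found
}

## compressed attractor signature over a fixed node universe:
## fixed states as 0/1, oscillating nodes as X
qa_signature <- function(nodes, states, osc) {
  v <- setNames(rep("X", length(nodes)), nodes)
  v[names(states)] <- as.character(states)
  v[osc] <- "X"
  paste(v, collapse = "")
}

## signatures of all attractors found by exhaustive state-transition-graph
## analysis (the independent oracle)
stg_signatures <- function(net) {
  bf <- brute_force_attractors(net)
  sig <- vapply(bf$steady, function(s)
    qa_signature(net$nodes, c(s, bf$fixed), character(0)), character(1))
  for (o in bf$oscillations) {
    const <- apply(o, 2, function(col) length(unique(col)) == 1)
    sig <- c(sig, qa_signature(
      net$nodes, c(setNames(o[1, const], colnames(o)[const]), bf$fixed),
      colnames(o)[!const]))
  }
  sort(unique(sig))
}

## distinct stable motifs encountered anywhere in a succession diagram
all_motif_keys <- function(sd)
  sort(unique(unlist(lapply(sd$nodes, function(n)
    vapply(n$motifs, set_key, character(1))))))

control_keys <- function(cs) sort(vapply(cs$sets, set_key, character(1)))

## set key with literals in alphabetical order (for order-free comparison)
canon_key <- function(s) {
  s <- s[order(names(s))]
  paste(sprintf("%s=%d", names(s), s), collapse = ",")
}
canon_keys <- function(cs) sort(vapply(cs$sets, canon_key, character(1)))
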