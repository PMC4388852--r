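## ---- stable motif control and blocking -------------------------------------

#' Motif sequences leading to a target attractor
#'
#' All root-to-leaf paths of the succession diagram whose leaf is the
#' target quasi-attractor, each reported as the ordered list of stable
#' motifs chosen along the path.
#'
#' @param sd a `succession_diagram`.
#' @param target quasi-attractor label (e.g. `"A2"` or a marker label) or a
#'   `quasi_attractor` object.
#' @return list of motif sequences; each sequence is a list of
#'   `stable_motif` objects and carries a `nodes` attribute with the
#'   diagram node ids visited.
#' @export
sequences_to_attractor <- function(sd, target) {
  stopifnot(inherits(sd, "succession_diagram"))
  leaf_ids <- .target_leaf_ids(sd, target)
  if (!length(leaf_ids)) stop("target attractor has no leaf in the diagram")
  out <- list()
  walk <- function(id, seq_motifs, seq_nodes) {
    n <- sd$nodes[[id]]
    if (!length(n$children)) {
      if (id %in% leaf_ids)
        out[[length(out) + 1L]] <<- structure(seq_motifs,
                                             nodes = c(seq_nodes, id))
      return(invisible())
    }
    for (j in seq_along(n$children))
      walk(n$children[[j]], c(seq_motifs, list(n$motifs[[j]])),
           c(seq_nodes, id))
    invisible()
  }
  walk(sd$root, list(), integer(0))
  out
}

## do all leaves below `id` equal the target signature?
.commits_to_target <- function(sd, id, leaf_ids) {
  seen <- logical(length(sd$nodes))
  ok <- TRUE
  rec <- function(i) {
    if (seen[[i]] || !ok) return(invisible())
    seen[[i]] <<- TRUE
    n <- sd$nodes[[i]]
    if (!length(n$children)) {
      if (!(i %in% leaf_ids)) ok <<- FALSE
      return(invisible())
    }
    for (c in n$children) rec(c)
  }
  rec(id)
  ok
}

## follow a motif sequence through the diagram from the root; returns the
## final node id, or NA if some motif is not available at the current node
.follow_sequence <- function(sd, motifs) {
  id <- sd$root
  for (m in motifs) {
    n <- sd$nodes[[id]]
    keys <- vapply(n$motifs, .motif_key, character(1))
    j <- match(.motif_key(m), keys)
    if (is.na(j)) return(NA_integer_)
    id <- n$children[[j]]
  }
  id
}

#' Shorten a motif sequence to the motifs required for commitment
#'
#' Removes motifs that are not needed: a motif is removable when, after
#' following the retained motifs through the succession diagram, every
#' remaining completion of motif choices still reaches the target
#' attractor.  Motifs are tried for removal in order (greedy), and each
#' candidate shortening is validated against the diagram, so the result is
#' deterministic and still leads uniquely to the target.
#'
#' @param sd a `succession_diagram`.
#' @param seq_motifs a motif sequence (list of `stable_motif`), e.g. from
#'   [sequences_to_attractor()].
#' @param target target attractor label or `quasi_attractor`.
#' @return the shortened motif sequence.
#' @export
shorten_sequence <- function(sd, seq_motifs, target) {
  leaf_ids <- .target_leaf_ids(sd, target)
  valid <- function(ms) {
    id <- .follow_sequence(sd, ms)
    !is.na(id) && .commits_to_target(sd, id, leaf_ids)
  }
  if (!valid(seq_motifs))
    stop("sequence does not lead to the target attractor")
  cur <- seq_motifs
  repeat {
    changed <- FALSE
    i <- 1L
    while (i <= length(cur)) {
      cand <- cur[-i]
      if (valid(cand)) { cur <- cand; changed <- TRUE } else i <- i + 1L
    }
    if (!changed) break
  }
  cur
}

#' Minimal driver subsets that lock in a stable motif
#'
#' Finds all inclusion-minimal subsets of the motif's node states that,
#' when fixed in the given network, force every motif node to its motif
#' state through logical percolation.  At worst the whole motif state is
#' its own (only) driver set.
#'
#' @param net the network in which the motif was found (the reduced network
#'   of the corresponding succession-diagram node).
#' @param motif a `stable_motif` (or named 0/1 vector) of `net`.
#' @param warn_size subset search is exponential in motif size; a warning
#'   is issued above this size (default 12).
#' @return list of named 0/1 integer vectors, each a minimal driver set.
#' @export
motif_driver_sets <- function(net, motif, warn_size = 12L) {
  stopifnot(inherits(net, "boolean_network"))
  states <- .parse_state_value(motif)
  names(states) <- names(motif)
  k <- length(states)
  if (k > warn_size)
    warning("driver-set search over a ", k, "-node motif enumerates 2^", k,
            " subsets")
  forces <- function(sub) {
    fx <- bn_reduce(net, sub)$fixed
    all(names(states) %in% names(fx)) && all(fx[names(states)] == states)
  }
  minimal <- list()
  for (size in seq_len(k)) {
    combos <- utils::combn(k, size, simplify = FALSE)
    for (cb in combos) {
      sub <- states[cb]
      if (any(vapply(minimal, function(m)
        all(names(m) %in% names(sub)) && all(sub[names(m)] == m),
        logical(1)))) next   # superset of a known minimal driver
      if (forces(sub)) minimal[[length(minimal) + 1L]] <- sub
    }
  }
  if (!length(minimal)) minimal <- list(states)   # cannot happen: whole motif forces itself
  keys <- vapply(minimal, .motif_key, character(1))
  minimal[order(vapply(minimal, length, integer(1)), keys)]
}

#' Stable motif control sets for a target attractor
#'
#' For every motif sequence leading to the target: shorten it to the motifs
#' required for commitment, replace each motif by its minimal driver
#' subsets, and take the union over one driver choice per motif.  The
#' resulting collection is pruned of duplicates and of supersets of other
#' control sets.  Fixing any control set -- even transiently -- drives the
#' network to the target attractor from any initial state.
#'
#' @param sd a `succession_diagram`.
#' @param target target attractor label or `quasi_attractor`.
#' @return object of class `control_sets`: list with `target` and `sets`
#'   (list of named 0/1 vectors, deterministic order).
#' @examples
#' net <- bn_parse("A* = A")
#' sd <- build_succession_diagram(net)
#' stable_motif_control(sd, "A1")
#' @export
stable_motif_control <- function(sd, target) {
  stopifnot(inherits(sd, "succession_diagram"))
  label <- .target_label(sd, target)
  seqs <- sequences_to_attractor(sd, target)
  all_sets <- list()
  for (s in seqs) {
    short <- shorten_sequence(sd, s, target)
    ## driver sets are computed in the network where each motif arises
    drivers <- vector("list", length(short))
    id <- sd$root
    for (j in seq_along(short)) {
      n <- sd$nodes[[id]]
      keys <- vapply(n$motifs, .motif_key, character(1))
      jj <- match(.motif_key(short[[j]]), keys)
      drivers[[j]] <- motif_driver_sets(n$network, short[[j]])
      id <- n$children[[jj]]
    }
    if (!length(short)) { all_sets <- c(all_sets, list(integer(0))); next }
    ## cross product of driver choices
    idx <- lapply(drivers, seq_along)
    grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(grid))) {
      chosen <- lapply(seq_along(drivers), function(j)
        drivers[[j]][[grid[r, j]]])
      merged <- integer(0)
      ok <- TRUE
      for (ch in chosen) {
        conf <- intersect(names(merged), names(ch))
        if (length(conf) && any(merged[conf] != ch[conf])) { ok <- FALSE; break }
        merged <- c(merged, ch[setdiff(names(ch), names(merged))])
      }
      if (ok) all_sets[[length(all_sets) + 1L]] <- merged
    }
  }
  ## prune duplicates and supersets
  all_sets <- lapply(all_sets, function(s)
    s[order(match(names(s), sd$network$nodes))])
  keys <- vapply(all_sets, .motif_key, character(1))
  all_sets <- all_sets[!duplicated(keys)]
  sizes <- vapply(all_sets, length, integer(1))
  all_sets <- all_sets[order(sizes)]
  pruned <- list()
  for (s in all_sets) {
    sup <- any(vapply(pruned, function(p)
      all(names(p) %in% names(s)) && all(s[names(p)] == p), logical(1)))
    if (!sup) pruned[[length(pruned) + 1L]] <- s
  }
  keys <- vapply(pruned, .motif_key, character(1))
  structure(list(target = label,
                 sets = pruned[order(vapply(pruned, length, integer(1)),
                                     keys)]),
            class = "control_sets")
}

#' @export
print.control_sets <- function(x, ...) {
  cat(sprintf("Stable motif control sets for %s:\n", x$target))
  for (s in x$sets)
    cat("  {", paste(sprintf("%s = %s", names(s),
                             ifelse(s == 1L, "ON", "OFF")), collapse = ", "),
        "}\n")
  invisible(x)
}

#' Stable motif blocking set for a target attractor
#'
#' Collects every stable motif appearing in some sequence that leads to the
#' target attractor and negates each of its node states.  Each resulting
#' single node-state negation (or any combination of them) is a candidate
#' intervention for obstructing the attractor; blocking eliminates the
#' intended attractor from the intervened network, though its overall
#' effectiveness must be measured by simulation.
#'
#' @param sd a `succession_diagram`.
#' @param target target attractor label or `quasi_attractor`.
#' @return object of class `blocking_set`: list with `target`, `motifs`
#'   (the motifs leading to the target) and `sets` (list of single
#'   node-state negations as named 0/1 vectors, deduplicated).
#' @export
stable_motif_blocking <- function(sd, target) {
  stopifnot(inherits(sd, "succession_diagram"))
  label <- .target_label(sd, target)
  seqs <- sequences_to_attractor(sd, target)
  motifs <- list()
  keys <- character(0)
  for (s in seqs) for (m in s) {
    k <- .motif_key(m)
    if (!k %in% keys) { motifs[[length(motifs) + 1L]] <- m; keys <- c(keys, k) }
  }
  neg <- list()
  nkeys <- character(0)
  for (m in motifs) for (j in seq_along(m)) {
    b <- setNames(1L - m[[j]], names(m)[[j]])
    k <- .motif_key(b)
    if (!k %in% nkeys) { neg[[length(neg) + 1L]] <- b; nkeys <- c(nkeys, k) }
  }
  ord <- order(vapply(neg, function(b) match(names(b), sd$network$nodes),
                      integer(1)))
  structure(list(target = label, motifs = motifs, sets = neg[ord]),
            class = "blocking_set")
}

#' @export
print.blocking_set <- function(x, ...) {
  cat(sprintf("Stable motif blocking interventions for %s:\n", x$target))
  cat(" ", paste(vapply(x$sets, function(s)
    sprintf("{%s = %s}", names(s), ifelse(s == 1L, "ON", "OFF")),
    character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Write control/blocking sets as a TSV report
#'
#' @param x a `control_sets` or `blocking_set` object.
#' @param path output file, or `""` for stdout.
#' @return invisibly, the data.frame written.
#' @export
intervention_report <- function(x, path = "") {
  stopifnot(inherits(x, "control_sets") || inherits(x, "blocking_set"))
  strategy <- if (inherits(x, "control_sets")) "control" else "blocking"
  df <- data.frame(
    target = x$target,
    strategy = strategy,
    intervention = vapply(x$sets, function(s)
      paste(sprintf("%s=%s", names(s), ifelse(s == 1L, "ON", "OFF")),
            collapse = ","), character(1)),
    size = vapply(x$sets, length, integer(1)),
    stringsAsFactors = FALSE)
  if (nzchar(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
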