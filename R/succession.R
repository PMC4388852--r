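## ---- stable motif succession diagram ---------------------------------------

.fixed_key <- function(fixed) {
  if (!length(fixed)) return("k:")
  paste0("k:", paste(sprintf("%s=%d", names(fixed), fixed), collapse = ","))
}

#' Reduce a succession-diagram node by one of its stable motifs
#'
#' Merges the motif's states into the accumulated fixed mapping and
#' percolates their downstream effect, yielding the child node.
#'
#' @param node a succession node (list with `fixed`, `network`, `sequence`),
#'   e.g. the root built internally by [build_succession_diagram()].
#' @param motif a stable motif of `node$network`.
#' @return the child succession node.
#' @export
reduce_by_motif <- function(node, motif) {
  if (!is_partial_fixed_point(node$network, motif))
    stop("contradiction: argument is not a stable motif of this ",
         "reduced network", call. = FALSE)
  red <- bn_reduce(node$network, motif)
  list(fixed = .merge_fixed(node$fixed, red$fixed),
       network = red$network,
       sequence = c(node$sequence, list(motif)))
}

#' Build the stable motif succession diagram of a Boolean network
#'
#' Starting from the network reduced by its environment, the diagram
#' records every stable motif choice: reducing the network by a motif gives
#' a child network with its own stable motifs, and so on, until a network
#' with no motifs remains.  A childless node with no free nodes is a steady
#' state; one with free nodes left is an oscillatory quasi-attractor whose
#' free nodes are marked OSC (and should be confirmed by simulation).
#' Nodes with identical accumulated fixed mappings are merged and expanded
#' once.
#'
#' @param net a [boolean_network()] object with its environment resolved.
#' @param markers optional named list of marker partial states used to label
#'   the quasi-attractors (see [classify_attractor()]).
#' @param oscillation_check reduced networks with at most this many free
#'   nodes are additionally screened, by exhaustive state-transition-graph
#'   analysis, for motif-avoidant oscillations (attractors in which no
#'   stable motif ever locks, the "unstable oscillation" special case);
#'   any found become oscillatory quasi-attractors.  Larger reduced
#'   networks are not screened (intracellular models are not known to show
#'   this behaviour); set to 0 to disable.
#' @return an object of class `succession_diagram`.
#' @examples
#' net <- bn_parse("A* = A")
#' sd <- build_succession_diagram(net)
#' summary(sd)
#' @export
build_succession_diagram <- function(net, markers = NULL,
                                     oscillation_check = 10L) {
  stopifnot(inherits(net, "boolean_network"))
  .check_environment(net)
  root_red <- bn_reduce(net, net$environment)
  nodes <- list()
  keymap <- new.env(parent = emptyenv(), hash = TRUE)

  visit <- function(fixed, network) {
    key <- .fixed_key(fixed)
    hit <- keymap[[key]]
    if (!is.null(hit)) return(hit)
    id <- length(nodes) + 1L
    assign(key, id, envir = keymap)
    nodes[[id]] <<- list(id = id, fixed = fixed, network = network,
                         motifs = list(), children = integer(0),
                         free = names(network$rules), avoidant = list())
    motifs <- find_stable_motifs(network)
    children <- integer(length(motifs))
    for (j in seq_along(motifs)) {
      red <- bn_reduce(network, motifs[[j]])
      children[[j]] <- visit(.merge_fixed(fixed, red$fixed), red$network)
    }
    nodes[[id]]$motifs <<- motifs
    nodes[[id]]$children <<- children
    nfree <- length(network$rules)
    if (nfree > 0L && nfree <= oscillation_check) {
      ## with motifs: screen for motif-avoidant oscillations; without:
      ## resolve the oscillatory leaf into its exact terminal orbits
      nodes[[id]]$avoidant <<- .motif_avoidant_oscillations(network, motifs,
                                                            fixed)
      if (!length(motifs) && length(nodes[[id]]$avoidant))
        nodes[[id]]$exact_osc <<- TRUE
    }
    id
  }
  root <- visit(root_red$fixed, root_red$network)

  sd <- structure(list(network = net, nodes = nodes, root = root,
                       markers = markers),
                  class = "succession_diagram")
  sd$attractors <- .collect_quasi_attractors(sd)
  sd
}

## oscillatory attractors of a reduced network in which no stable motif of
## that network ever locks; returned as partial states (constant part) plus
## the oscillating node set, merged with the accumulated fixed mapping
.motif_avoidant_oscillations <- function(network, motifs, fixed) {
  bf <- tryCatch(brute_force_attractors(network),
                 error = function(e) NULL)
  if (is.null(bf)) return(list())
  out <- list()
  for (orbit in bf$oscillations) {
    locked <- FALSE
    for (m in motifs) {
      hit <- orbit[, names(m), drop = FALSE]
      if (all(t(hit) == as.integer(m))) { locked <- TRUE; break }
    }
    if (locked) next
    const <- vapply(seq_len(ncol(orbit)), function(j)
      length(unique(orbit[, j])) == 1L, logical(1))
    states <- setNames(orbit[1L, const], colnames(orbit)[const])
    out[[length(out) + 1L]] <-
      list(fixed = .merge_fixed(fixed, c(states, bf$fixed)),
           osc = colnames(orbit)[!const])
  }
  out
}

## quasi-attractor of a leaf node: fixed part plus OSC free nodes
.leaf_qa <- function(sd, node) {
  all_nodes <- sd$network$nodes
  states <- setNames(rep(NA_integer_, length(all_nodes)), all_nodes)
  states[names(node$fixed)] <- node$fixed
  osc <- all_nodes[is.na(states)]
  structure(list(states = states[!is.na(states)], osc = osc,
                 signature = paste(ifelse(is.na(states), "X", states),
                                   collapse = "")),
            class = "quasi_attractor")
}

.qa_from_parts <- function(sd, fixed, osc) {
  all_nodes <- sd$network$nodes
  states <- setNames(rep(NA_integer_, length(all_nodes)), all_nodes)
  states[names(fixed)] <- fixed
  states[osc] <- NA_integer_
  structure(list(states = states[!is.na(states)],
                 osc = all_nodes[is.na(states)],
                 signature = paste(ifelse(is.na(states), "X", states),
                                   collapse = "")),
            class = "quasi_attractor")
}

.collect_quasi_attractors <- function(sd) {
  leaves <- Filter(function(n) length(n$motifs) == 0L &&
                     !isTRUE(n$exact_osc), sd$nodes)
  qas <- lapply(leaves, function(n) .leaf_qa(sd, n))
  for (n in sd$nodes)
    for (av in n$avoidant)
      qas[[length(qas) + 1L]] <- .qa_from_parts(sd, av$fixed, av$osc)
  sig <- vapply(qas, function(q) q$signature, character(1))
  qas <- qas[!duplicated(sig)]
  ## deterministic order: most active nodes first, then by state signature
  non <- vapply(qas, function(q) sum(q$states == 1L), integer(1))
  sig <- vapply(qas, function(q) q$signature, character(1))
  qas <- qas[order(-non, sig)]
  for (i in seq_along(qas)) {
    qas[[i]]$label <- paste0("A", i)
    if (!is.null(sd$markers))
      qas[[i]]$label <- classify_attractor(qas[[i]], sd$markers)
  }
  qas
}

#' Quasi-attractors of a succession diagram
#'
#' The deduplicated leaf states of the diagram.  A quasi-attractor with no
#' OSC nodes is an exact steady state of the Boolean network; OSC marks
#' nodes left free by every motif and reduction (oscillatory behaviour,
#' to be confirmed by simulation).
#'
#' @param sd a `succession_diagram` from [build_succession_diagram()].
#' @return list of `quasi_attractor` objects in deterministic order (labels
#'   `A1`, `A2`, ... by decreasing number of active nodes, ties broken by
#'   state signature; marker labels if the diagram has markers).
#' @export
quasi_attractors <- function(sd) {
  stopifnot(inherits(sd, "succession_diagram"))
  sd$attractors
}

#' @export
print.quasi_attractor <- function(x, ...) {
  fixed <- paste(sprintf("%s=%d", names(x$states), x$states), collapse = ", ")
  osc <- if (length(x$osc))
    paste0(", OSC: ", paste(x$osc, collapse = ", ")) else ""
  cat(sprintf("%s: {%s%s}\n", x$label, fixed, osc))
  invisible(x)
}

#' Count root-to-leaf motif sequences of a succession diagram
#'
#' Counts ordered sequences of stable motif choices from the original
#' network down to a quasi-attractor.  Distinct orderings of the same
#' motifs are distinct sequences even though diagram nodes with identical
#' accumulated states are merged.
#'
#' @param sd a `succession_diagram`.
#' @return nonnegative integer.
#' @export
count_sequences <- function(sd) {
  stopifnot(inherits(sd, "succession_diagram"))
  memo <- rep(NA_real_, length(sd$nodes))
  paths <- function(id) {
    if (!is.na(memo[[id]])) return(memo[[id]])
    n <- sd$nodes[[id]]
    out <- if (!length(n$children)) 1
           else sum(vapply(n$children, paths, numeric(1)))
    memo[[id]] <<- out
    out
  }
  as.integer(paths(sd$root))
}

#' Label a quasi-attractor with phenotype markers
#'
#' @param qa a `quasi_attractor`.
#' @param markers named list: label -> named partial state (0/1/ON/OFF).
#'   Marker sets must be mutually exclusive; if two labels match the same
#'   quasi-attractor an error signals a bad marker configuration.
#' @return the matching label, or `"unclassified"`.
#' @export
classify_attractor <- function(qa, markers) {
  stopifnot(inherits(qa, "quasi_attractor"))
  hits <- character(0)
  for (lab in names(markers)) {
    mk <- .parse_state_value(markers[[lab]])
    names(mk) <- names(markers[[lab]])
    ok <- all(names(mk) %in% names(qa$states)) &&
      all(qa$states[names(mk)] == mk)
    if (ok) hits <- c(hits, lab)
  }
  if (length(hits) > 1L)
    stop("ambiguous markers: quasi-attractor matches ",
         paste(hits, collapse = " and "), call. = FALSE)
  if (length(hits) == 1L) hits else "unclassified"
}

#' @export
print.succession_diagram <- function(x, ...) {
  cat(sprintf("Stable motif succession diagram: %d nodes, %d quasi-attractors, %d sequences\n",
              length(x$nodes), length(x$attractors), count_sequences(x)))
  invisible(x)
}

#' @export
summary.succession_diagram <- function(object, ...) {
  x <- object
  root <- x$nodes[[x$root]]
  cat(sprintf("Succession diagram of a %d-node network\n",
              length(x$network$nodes)))
  cat(sprintf("  root stable motifs: %d\n", length(root$motifs)))
  for (m in root$motifs) { cat("   "); print(m) }
  cat(sprintf("  diagram nodes (merged): %d\n", length(x$nodes)))
  cat(sprintf("  motif sequences: %d\n", count_sequences(x)))
  cat(sprintf("  quasi-attractors: %d\n", length(x$attractors)))
  for (qa in x$attractors) { cat("   "); print(qa) }
  invisible(x)
}

## ---- exports ---------------------------------------------------------------

#' Export a succession diagram as DOT
#'
#' Diagram nodes show their accumulated fixed states; edges are labelled by
#' the chosen stable motif; quasi-attractor leaves are boxed, with 0/1/OSC
#' states in the label.
#'
#' @param sd a `succession_diagram`.
#' @param path output file, or `""` to return the lines.
#' @return invisibly, the DOT lines.
#' @export
succession_to_dot <- function(sd, path = "") {
  stopifnot(inherits(sd, "succession_diagram"))
  lab <- function(n) {
    if (!length(n$fixed)) return("(root)")
    s <- paste(sprintf("%s=%d", names(n$fixed), n$fixed), collapse = "\\n")
    if (length(n$free) && !length(n$motifs))
      s <- paste0(s, "\\nOSC: ", paste(n$free, collapse = ","))
    s
  }
  lines <- c("digraph succession {", "  rankdir=LR;")
  for (n in sd$nodes) {
    shape <- if (!length(n$motifs)) "box" else "ellipse"
    lines <- c(lines, sprintf('  n%d [shape=%s, label="%s"];',
                              n$id, shape, lab(n)))
  }
  for (n in sd$nodes)
    for (j in seq_along(n$children))
      lines <- c(lines, sprintf('  n%d -> n%d [label="%s", style=dashed];',
                                n$id, n$children[[j]],
                                .motif_key(n$motifs[[j]])))
  lines <- c(lines, "}")
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}

#' Export a succession diagram as JSON
#'
#' Records nodes (accumulated states), motif-labelled edges, the sequence
#' count (ordered motif choices) and the merged node count, and the
#' quasi-attractors, so either path-counting convention can be audited.
#'
#' @param sd a `succession_diagram`.
#' @param path output file, or `""` to return the JSON string.
#' @return invisibly, the JSON string.
#' @export
succession_to_json <- function(sd, path = "") {
  stopifnot(inherits(sd, "succession_diagram"))
  nodes <- lapply(sd$nodes, function(n)
    list(id = n$id,
         fixed = as.list(n$fixed),
         free = n$free,
         leaf = length(n$motifs) == 0L))
  edges <- list()
  for (n in sd$nodes)
    for (j in seq_along(n$children))
      edges[[length(edges) + 1L]] <-
        list(from = n$id, to = n$children[[j]],
             motif = as.list(n$motifs[[j]]))
  qas <- lapply(sd$attractors, function(q)
    list(label = q$label, states = as.list(q$states), osc = q$osc))
  doc <- list(nodes = nodes, edges = edges, root = sd$root,
              sequences = count_sequences(sd),
              merged_nodes = length(sd$nodes),
              quasi_attractors = qas)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (nzchar(path)) writeLines(js, path)
  invisible(js)
}

## resolve a control/blocking target to an attractor label; helper shared
## by control and simulation code.  When markers classify several
## quasi-attractors under one phenotype label, the label designates all of
## them (control then means reaching any attractor of that phenotype).
.target_label <- function(sd, target) {
  qas <- sd$attractors
  labs <- vapply(qas, function(q) q$label, character(1))
  if (inherits(target, "quasi_attractor")) target <- target$label
  if (!target %in% labs)
    stop("target attractor not in diagram: ", target,
         " (available: ", paste(unique(labs), collapse = ", "), ")",
         call. = FALSE)
  target
}

## ids of leaves whose quasi-attractor carries the target label
.target_leaf_ids <- function(sd, target) {
  label <- .target_label(sd, target)
  sigs <- vapply(sd$attractors[vapply(sd$attractors, function(q)
    q$label == label, logical(1))], function(q) q$signature, character(1))
  hits <- integer(0)
  for (n in sd$nodes) {
    if (length(n$motifs)) next
    if (.leaf_qa(sd, n)$signature %in% sigs)
      hits <- c(hits, n$id)
  }
  hits
}
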