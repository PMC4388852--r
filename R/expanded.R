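## ---- expanded network ------------------------------------------------------
## Two literal ("virtual") nodes per network node -- one per state, the
## state-0 literal being the complementary node -- plus one composite node
## per multi-literal prime implicant.  Edges: implicant members -> composite,
## composite (or single literal implicant) -> target literal.

## literal ids: node i state 1 -> 2i-1, state 0 -> 2i
.lit_id <- function(i, state) 2L * i - as.integer(state)
.lit_node <- function(l) (l + 1L) %/% 2L
.lit_state <- function(l) as.integer(l %% 2L == 1L)
.lit_compl <- function(l) ifelse(l %% 2L == 1L, l + 1L, l - 1L)

.lit_label <- function(nodes, l) {
  sprintf("%s=%d", nodes[.lit_node(l)], .lit_state(l))
}

## per-literal Blake prime implicants of an input-free network,
## as lists of literal-id vectors
.literal_implicants <- function(net) {
  nodes <- net$nodes
  nidx <- setNames(seq_along(nodes), nodes)
  imps <- vector("list", 2L * length(nodes))
  for (nm in names(net$rules)) {
    i <- nidx[[nm]]
    for (state in c(1L, 0L)) {
      pif <- prime_implicants(net, nm, state)
      imps[[.lit_id(i, state)]] <- lapply(pif$implicants, function(im)
        sort(.lit_id(nidx[names(im)], im)))
    }
  }
  imps
}

#' Build the expanded network of a Boolean model
#'
#' The expanded network contains one literal node per node state and one
#' composite node per multi-literal prime implicant (Blake canonical form)
#' of each literal, and is the graph on which stable motifs are defined.
#' Input nodes must have environment states; the network is first reduced by
#' its environment so only free, regulated nodes are expanded.
#'
#' @param net a [boolean_network()] object with its environment resolved.
#' @return object of class `expanded_network`: list with `nodes` (free node
#'   names), `literals` (data.frame: id, node, state, label), `composites`
#'   (list of literal-id vectors), `implicants` (per literal id, the list of
#'   its implicants as literal-id vectors) and `edges` (data.frame of
#'   from/to labels, composite nodes labelled `&k`).
#' @export
build_expanded <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  .check_environment(net)
  red <- bn_reduce(net, net$environment)$network
  nodes <- names(red$rules)
  if (!length(nodes)) {
    return(structure(list(nodes = character(0),
                          literals = data.frame(),
                          composites = list(), implicants = list(),
                          edges = data.frame()),
                     class = "expanded_network"))
  }
  red$nodes <- nodes   # input-free by construction
  imps <- .literal_implicants(red)
  literals <- data.frame(
    id = seq_len(2L * length(nodes)),
    node = nodes[.lit_node(seq_len(2L * length(nodes)))],
    state = .lit_state(seq_len(2L * length(nodes))),
    stringsAsFactors = FALSE)
  literals$label <- sprintf("%s=%d", literals$node, literals$state)

  composites <- list()
  ckey <- character(0)
  from <- character(0); to <- character(0)
  for (l in seq_along(imps)) {
    for (im in imps[[l]]) {
      if (length(im) == 1L) {
        from <- c(from, literals$label[[im]])
        to <- c(to, literals$label[[l]])
      } else if (length(im) >= 2L) {
        key <- paste(im, collapse = ",")
        j <- match(key, ckey)
        if (is.na(j)) {
          composites[[length(composites) + 1L]] <- im
          ckey <- c(ckey, key)
          j <- length(composites)
          from <- c(from, literals$label[im])
          to <- c(to, rep(sprintf("&%d", j), length(im)))
        }
        from <- c(from, sprintf("&%d", j))
        to <- c(to, literals$label[[l]])
      }
      ## zero-length implicants (constant rules) cannot occur: constants
      ## are percolated away by the environment reduction above
    }
  }
  structure(list(nodes = nodes, literals = literals,
                 composites = composites, implicants = imps,
                 edges = unique(data.frame(from = from, to = to,
                                           stringsAsFactors = FALSE))),
            class = "expanded_network")
}

#' @export
print.expanded_network <- function(x, ...) {
  cat(sprintf("Expanded network: %d literal nodes, %d composite nodes, %d edges\n",
              nrow(x$literals), length(x$composites), nrow(x$edges)))
  invisible(x)
}

#' Export an expanded network in DOT format
#'
#' Literal nodes are drawn plain (the state-0 literal labelled `!name`),
#' composite nodes filled, following the usual drawing convention for
#' expanded networks.
#'
#' @param x an `expanded_network` object from [build_expanded()].
#' @param path output file, or `""` to return the lines.
#' @return invisibly, the DOT lines.
#' @export
expanded_to_dot <- function(x, path = "") {
  stopifnot(inherits(x, "expanded_network"))
  esc <- function(s) gsub('"', '\\"', s, fixed = TRUE)
  disp <- function(lbl) {
    if (grepl("^&", lbl)) return(lbl)
    node <- sub("=.*$", "", lbl)
    if (grepl("=0$", lbl)) paste0("!", node) else node
  }
  lines <- c("digraph expanded {", "  node [shape=ellipse];")
  for (i in seq_len(nrow(x$literals)))
    lines <- c(lines, sprintf('  "%s" [label="%s"];',
                              esc(x$literals$label[[i]]),
                              esc(disp(x$literals$label[[i]]))))
  for (j in seq_along(x$composites))
    lines <- c(lines, sprintf('  "&%d" [shape=point, style=filled, fillcolor=black];', j))
  if (nrow(x$edges))
    lines <- c(lines, sprintf('  "%s" -> "%s";',
                              esc(x$edges$from), esc(x$edges$to)))
  lines <- c(lines, "}")
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}
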