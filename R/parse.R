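#' @useDynLib stablemotifs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rbinom runif
#' @importFrom utils head tail write.table
NULL

## ---- rule expression trees -------------------------------------------------
## Update rules are stored as R language objects built from `&`, `|`, `!`,
## node symbols and TRUE/FALSE.  R's operator precedence (! > & > |) matches
## the not/and/or precedence of the plain-text dialect, so evaluation can use
## eval() directly and vectorizes over logical vectors.

.tokenize_expr <- function(s, line = NA_integer_) {
  toks <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, val = ch)
      i <- i + 1L
    } else if (ch == "&") {
      toks[[length(toks) + 1L]] <- list(type = "and", val = "&")
      i <- i + if (substr(s, i + 1L, i + 1L) == "&") 2L else 1L
    } else if (ch == "|") {
      toks[[length(toks) + 1L]] <- list(type = "or", val = "|")
      i <- i + if (substr(s, i + 1L, i + 1L) == "|") 2L else 1L
    } else if (ch == "!") {
      toks[[length(toks) + 1L]] <- list(type = "not", val = "!")
      i <- i + 1L
    } else if (grepl("^[A-Za-z0-9_]$", ch)) {
      rest <- substr(s, i, n)
      m <- regmatches(rest, regexpr("^[A-Za-z0-9_]+", rest))
      lw <- tolower(m)
      type <- switch(lw,
        "and" = "and", "or" = "or", "not" = "not",
        "true" = "const1", "on" = "const1", "1" = "const1",
        "false" = "const0", "off" = "const0", "0" = "const0",
        "name")
      ## plain integers other than 0/1 are invalid
      if (type == "name" && grepl("^[0-9]+$", m))
        stop(sprintf("line %s: numeric constant '%s' is not a valid truth value",
                     line, m), call. = FALSE)
      toks[[length(toks) + 1L]] <- list(type = type, val = m)
      i <- i + nchar(m)
    } else {
      stop(sprintf("line %s: unexpected character '%s' in rule expression",
                   line, ch), call. = FALSE)
    }
  }
  toks
}

## recursive-descent parser: or_expr := and_expr ('or' and_expr)*
.parse_tokens <- function(toks, line = NA_integer_) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$type else "eof"
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    if (peek() != type)
      stop(sprintf("line %s: expected %s but found %s", line, type, peek()),
           call. = FALSE)
    advance()
  }
  parse_atom <- function() {
    t <- peek()
    if (t == "not") { advance(); return(call("!", parse_atom())) }
    if (t == "(") {
      advance()
      e <- parse_or()
      expect(")")
      return(e)
    }
    if (t == "const1") { advance(); return(TRUE) }
    if (t == "const0") { advance(); return(FALSE) }
    if (t == "name") return(as.name(advance()$val))
    stop(sprintf("line %s: unexpected token '%s'", line, t), call. = FALSE)
  }
  parse_and <- function() {
    e <- parse_atom()
    while (peek() == "and") { advance(); e <- call("&", e, parse_atom()) }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (peek() == "or") { advance(); e <- call("|", e, parse_and()) }
    e
  }
  e <- parse_or()
  if (peek() != "eof")
    stop(sprintf("line %s: trailing tokens after expression", line),
         call. = FALSE)
  e
}

#' Parse a single Boolean rule expression
#'
#' @param s character string in the rule dialect (operators `and`, `or`,
#'   `not`, parentheses, constants `0`/`1`/`True`/`False`/`ON`/`OFF`).
#' @param line optional line number used in error messages.
#' @return an R language object over `&`, `|`, `!` and node symbols.
#' @keywords internal
parse_rule_expr <- function(s, line = NA_integer_) {
  .parse_tokens(.tokenize_expr(s, line), line)
}

## node names referenced by an expression tree, in order of first appearance
expr_inputs <- function(e) {
  out <- character(0)
  walk <- function(x) {
    if (is.name(x)) out[[length(out) + 1L]] <<- as.character(x)
    else if (is.call(x)) for (a in as.list(x)[-1L]) walk(a)
  }
  walk(e)
  unique(out)
}

## deparse an expression tree back into the rule dialect
expr_to_string <- function(e, parent = "or") {
  if (isTRUE(e)) return("1")
  if (isFALSE(e)) return("0")
  if (is.name(e)) return(as.character(e))
  op <- as.character(e[[1L]])
  if (op == "!") {
    s <- paste0("not ", expr_to_string(e[[2L]], "not"))
    return(s)
  }
  if (op == "&") {
    s <- paste(expr_to_string(e[[2L]], "and"), "and",
               expr_to_string(e[[3L]], "and"))
    if (parent == "not") s <- paste0("(", s, ")")
    return(s)
  }
  if (op == "|") {
    s <- paste(expr_to_string(e[[2L]], "or"), "or",
               expr_to_string(e[[3L]], "or"))
    if (parent %in% c("and", "not")) s <- paste0("(", s, ")")
    return(s)
  }
  stop("unsupported operator in rule expression: ", op)
}

## ---- BooleanNetwork --------------------------------------------------------

#' Construct a Boolean network from update rules
#'
#' A Boolean network consists of named nodes, one Boolean update rule per
#' regulated node, and an environment assigning a fixed 0/1 state to every
#' input node (a node that is referenced by some rule but has no rule of its
#' own, typically an external signal).
#'
#' @param rules named list of rule expressions (as produced by
#'   [parse_rule_expr()]) or of character strings in the rule dialect.
#' @param environment named vector of 0/1 (or ON/OFF) values for input nodes;
#'   may be empty and supplied later via [bn_environment()].
#' @return an object of class `boolean_network` with elements `nodes`
#'   (all node names, rule targets first), `rules` (named list of language
#'   objects for regulated nodes), `inputs` (nodes without rules) and
#'   `environment` (named integer vector of fixed input states).
#' @seealso [bn_parse()], [bn_read()], [bn_write()]
#' @export
boolean_network <- function(rules, environment = NULL) {
  if (is.null(names(rules)) || any(names(rules) == ""))
    stop("rules must be a named list")
  rules <- lapply(rules, function(r)
    if (is.character(r)) parse_rule_expr(r) else r)
  targets <- names(rules)
  if (anyDuplicated(targets))
    stop("duplicate rule for node(s): ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  bad <- targets[!grepl("^[A-Za-z0-9_]+$", targets)]
  if (length(bad))
    stop("invalid node name(s): ", paste(bad, collapse = ", "))
  referenced <- unique(unlist(lapply(rules, expr_inputs), use.names = FALSE))
  inputs <- sort(setdiff(referenced, targets))
  net <- structure(
    list(nodes = c(targets, inputs),
         rules = rules,
         inputs = inputs,
         environment = integer(0)),
    class = "boolean_network")
  if (!is.null(environment) && length(environment))
    net <- bn_environment(net, environment)
  net
}

#' Parse a plain-text rule file into a Boolean network
#'
#' Each non-comment line has the form `NAME* = EXPR` (the `*` is optional),
#' where `EXPR` uses the operators `and`, `or`, `not`, parentheses and the
#' constants `0`/`1`/`True`/`False`/`ON`/`OFF`.  `#` starts a comment.  Node
#' names are case-sensitive and match `[A-Za-z0-9_]+`.  Nodes referenced but
#' never given a rule become input nodes; they must be assigned an
#' environment state (see [bn_environment()]) before any analysis.
#'
#' @param text character scalar or vector with the rule file contents.
#' @param environment optional named vector of input states (0/1/ON/OFF).
#' @return a [boolean_network()] object.
#' @examples
#' net <- bn_parse(c("A* = A and B", "B* = A"))
#' net
#' @export
bn_parse <- function(text, environment = NULL) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  rules <- list()
  for (ln in seq_along(text)) {
    s <- sub("#.*$", "", text[[ln]])
    if (!grepl("\\S", s)) next
    m <- regmatches(s, regexec("^\\s*([A-Za-z0-9_]+)\\s*\\*?\\s*=\\s*(.*\\S)\\s*$", s))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("line %d: not a rule of the form 'NAME* = EXPR': %s",
                   ln, trimws(text[[ln]])), call. = FALSE)
    node <- m[[2L]]
    if (node %in% names(rules))
      stop(sprintf("line %d: duplicate rule for node %s", ln, node),
           call. = FALSE)
    rules[[node]] <- parse_rule_expr(m[[3L]], line = ln)
  }
  if (!length(rules)) stop("no rules found")
  boolean_network(rules, environment)
}

#' Read a Boolean network from a rule file
#'
#' @param path path to a plain-text rule file (see [bn_parse()] for the
#'   dialect).
#' @param environment optional named vector of input states.
#' @return a [boolean_network()] object.
#' @export
bn_read <- function(path, environment = NULL) {
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  bn_parse(readLines(path, warn = FALSE), environment)
}

#' Write a Boolean network as a rule file
#'
#' Produces the same dialect accepted by [bn_parse()]; reading the file back
#' yields an identical network.  Environment values are written as comment
#' lines of the form `# env: NAME = 1` and restored by [bn_read()] only if
#' passed explicitly.
#'
#' @param net a [boolean_network()] object.
#' @param path output file path, or `""` to return the lines invisibly.
#' @return invisibly, the character vector of lines written.
#' @export
bn_write <- function(net, path = "") {
  stopifnot(inherits(net, "boolean_network"))
  lines <- vapply(names(net$rules), function(nm)
    sprintf("%s* = %s", nm, expr_to_string(net$rules[[nm]])), character(1))
  if (length(net$environment))
    lines <- c(lines, sprintf("# env: %s = %d",
                              names(net$environment), net$environment))
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}

.parse_state_value <- function(v) {
  if (is.logical(v)) return(as.integer(v))
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1))) stop("states must be 0 or 1")
    return(as.integer(v))
  }
  up <- toupper(as.character(v))
  out <- ifelse(up %in% c("1", "ON", "TRUE"), 1L,
                ifelse(up %in% c("0", "OFF", "FALSE"), 0L, NA_integer_))
  if (anyNA(out)) stop("invalid state value(s): ",
                       paste(v[is.na(out)], collapse = ", "))
  out
}

#' Assign environment states to input nodes
#'
#' @param net a [boolean_network()] object.
#' @param env named vector of states for input nodes; values may be 0/1,
#'   TRUE/FALSE or the aliases ON/OFF.
#' @return the network with its environment updated.
#' @export
bn_environment <- function(net, env) {
  stopifnot(inherits(net, "boolean_network"))
  vals <- .parse_state_value(env)
  names(vals) <- names(env)
  unknown <- setdiff(names(vals), net$nodes)
  if (length(unknown))
    stop("environment names not in network: ", paste(unknown, collapse = ", "))
  notinput <- setdiff(names(vals), net$inputs)
  if (length(notinput))
    stop("environment can only fix input nodes; regulated: ",
         paste(notinput, collapse = ", "))
  merged <- net$environment
  merged[names(vals)] <- vals
  net$environment <- merged
  net
}

## error unless every input node has an environment value
.check_environment <- function(net) {
  missing <- setdiff(net$inputs, names(net$environment))
  if (length(missing))
    stop("input node(s) without an environment state: ",
         paste(missing, collapse = ", "),
         "; assign them with bn_environment()", call. = FALSE)
  invisible(net)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes (%d regulated, %d inputs)\n",
              length(x$nodes), length(x$rules), length(x$inputs)))
  shown <- head(names(x$rules), 10L)
  for (nm in shown)
    cat(sprintf("  %s* = %s\n", nm, expr_to_string(x$rules[[nm]])))
  if (length(x$rules) > 10L)
    cat(sprintf("  ... and %d more rules\n", length(x$rules) - 10L))
  if (length(x$inputs)) {
    envtxt <- vapply(x$inputs, function(nm)
      if (nm %in% names(x$environment))
        sprintf("%s=%d", nm, x$environment[[nm]]) else sprintf("%s=?", nm),
      character(1))
    cat("  inputs:", paste(envtxt, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of regulatory edges of a Boolean network
#'
#' An edge u -> v is counted when u appears in v's update rule (constant
#' environment substitutions removed).  Input nodes contribute their outgoing
#' edges only.
#'
#' @param net a [boolean_network()] object.
#' @return integer edge count.
#' @export
bn_edge_count <- function(net) {
  sum(vapply(net$rules, function(r) length(expr_inputs(r)), integer(1)))
}
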