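## ---- prime implicants (Blake canonical form) -------------------------------
## Quine-McCluskey over the rule's truth table.  Every prime implicant is
## produced (not just a minimal cover): completeness of the implicant set is
## what guarantees that the expanded network, and hence the stable motif
## search, misses nothing.

## minterms: integer vector of satisfying input indices (0-based)
## returns matrix with columns val, mask (mask bit 1 = position is cared)
.qm_primes <- function(minterms, k) {
  if (k == 0L) return(matrix(integer(0), ncol = 2L,
                             dimnames = list(NULL, c("val", "mask"))))
  full <- 2L^k - 1L
  cur_val <- as.integer(minterms)
  cur_mask <- rep(full, length(cur_val))
  primes_val <- integer(0)
  primes_mask <- integer(0)
  while (length(cur_val)) {
    key <- paste(cur_val, cur_mask)
    keep <- !duplicated(key)
    cur_val <- cur_val[keep]; cur_mask <- cur_mask[keep]
    key <- key[keep]
    combined <- logical(length(cur_val))
    new_val <- integer(0); new_mask <- integer(0)
    for (b in 2L^(seq_len(k) - 1L)) {
      cand <- bitwAnd(cur_mask, b) != 0L
      if (!any(cand)) next
      partner_key <- paste(bitwXor(cur_val, b), cur_mask)
      hit <- cand & (partner_key %in% key)
      if (!any(hit)) next
      combined[hit] <- TRUE
      lower <- hit & bitwAnd(cur_val, b) == 0L
      new_val <- c(new_val, cur_val[lower])
      new_mask <- c(new_mask, bitwAnd(cur_mask[lower], bitwNot(b)))
    }
    primes_val <- c(primes_val, cur_val[!combined])
    primes_mask <- c(primes_mask, cur_mask[!combined])
    cur_val <- new_val
    cur_mask <- bitwAnd(new_mask, full)
  }
  key <- paste(primes_val, primes_mask)
  keep <- !duplicated(key)
  cbind(val = primes_val[keep], mask = primes_mask[keep])
}

## convert (val, mask) rows into named 0/1 vectors over input names
.primes_to_implicants <- function(pm, inputs) {
  k <- length(inputs)
  out <- lapply(seq_len(nrow(pm)), function(i) {
    bits <- 2L^(seq_len(k) - 1L)
    cared <- bitwAnd(pm[i, "mask"], bits) != 0L
    vals <- as.integer(bitwAnd(pm[i, "val"], bits) != 0L)
    setNames(vals[cared], inputs[cared])
  })
  ## canonical order: fewer literals first, then lexicographic on the literals
  keys <- vapply(out, function(im)
    paste(length(im),
          paste(sprintf("%s=%d", names(im), im), collapse = ",")),
    character(1))
  out[order(vapply(out, length, integer(1)),
            vapply(out, function(im)
              paste(sprintf("%s=%d", names(im), im), collapse = ","),
              character(1)))]
}

#' All prime implicants of an update rule (Blake canonical form)
#'
#' For `target_state = 1` the implicants are those of the rule itself; for
#' `target_state = 0`, those of its negation.  Each implicant is a partial
#' input assignment that forces the target literal regardless of all other
#' inputs, the set is complete (every prime implicant is present) and
#' irredundant (no implicant subsumes another).
#'
#' @param net a [boolean_network()] object.
#' @param node regulated node name.
#' @param target_state 0 or 1.
#' @return object of class `prime_implicant_form`: list with `node`, `state`
#'   and `implicants`, a list of named 0/1 vectors (empty list for a
#'   constant rule that never attains the target; a single empty implicant
#'   for a rule that always attains it).
#' @examples
#' net <- bn_parse("C* = A and B")
#' prime_implicants(net, "C", 1)
#' @export
prime_implicants <- function(net, node, target_state) {
  stopifnot(inherits(net, "boolean_network"))
  target_state <- .parse_state_value(target_state)
  tt <- rule_truth_table(net, node)
  k <- length(tt$inputs)
  want <- if (target_state == 1L) tt$tt == 1L else tt$tt == 0L
  if (all(want)) {
    imps <- list(setNames(integer(0), character(0)))
  } else if (!any(want)) {
    imps <- list()
  } else {
    pm <- .qm_primes(which(want) - 1L, k)
    imps <- .primes_to_implicants(pm, tt$inputs)
  }
  structure(list(node = node, state = target_state, implicants = imps),
            class = "prime_implicant_form")
}

#' @export
print.prime_implicant_form <- function(x, ...) {
  lit <- sprintf("%s=%d", x$node, x$state)
  if (!length(x$implicants)) {
    cat(sprintf("%s: unattainable (constant rule)\n", lit))
    return(invisible(x))
  }
  terms <- vapply(x$implicants, function(im)
    if (!length(im)) "1"
    else paste(sprintf("%s=%d", names(im), im), collapse = " & "),
    character(1))
  cat(sprintf("%s <- %s\n", lit, paste0("{", terms, "}", collapse = " | ")))
  invisible(x)
}

## DNF expression from a truth table (used to rebuild reduced rules)
.tt_to_expr <- function(inputs, ttvec) {
  k <- length(inputs)
  if (all(ttvec == 1L)) return(TRUE)
  if (all(ttvec == 0L)) return(FALSE)
  pm <- .qm_primes(which(ttvec == 1L) - 1L, k)
  imps <- .primes_to_implicants(pm, inputs)
  terms <- lapply(imps, function(im) {
    lits <- lapply(seq_along(im), function(j) {
      nm <- as.name(names(im)[[j]])
      if (im[[j]] == 1L) nm else call("!", nm)
    })
    Reduce(function(a, b) call("&", a, b), lits)
  })
  Reduce(function(a, b) call("|", a, b), terms)
}
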