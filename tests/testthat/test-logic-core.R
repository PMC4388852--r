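test_that("rule files parse, round-trip, and report errors with line numbers", {
  net <- bn_parse(c("# comment", "A* = A", "", "B = A and not A"))
  expect_s3_class(net, "boolean_network")
  expect_equal(names(net$rules), c("A", "B"))
  expect_equal(bn_evaluate(net, "B", c(A = 1, B = 0)), 0L)

  ## round trip through the writer
  toy <- toy_network()
  lines <- bn_write(toy)
  again <- bn_parse(lines)
  expect_equal(names(again$rules), names(toy$rules))
  for (nm in names(toy$rules))
    expect_identical(rule_truth_table(again, nm), rule_truth_table(toy, nm))

  expect_error(bn_parse(c("A* = A", "A* = 0")), "line 2.*duplicate")
  expect_error(bn_parse("A* = A and"), "line 1")
  expect_error(bn_parse("A* = 2"), "line 1")
  expect_error(bn_parse("not a rule"), "line 1")

  ## ON/OFF aliases and constants
  net2 <- bn_parse(c("A* = ON", "B* = A and not OFF"))
  expect_equal(rule_truth_table(net2, "A")$tt, 1L)

  ## unassigned inputs are refused at analysis time
  net3 <- bn_parse("A* = A and S")
  expect_equal(net3$inputs, "S")
  expect_error(find_stable_motifs(net3), "environment")
  expect_error(bn_environment(net3, c(Q = 1)), "not in network")
})

test_that("evaluation agrees with direct truth-table lookup on random networks", {
  toy <- toy_network()
  ## every state of the second toy attractor is fixed under every rule
  a2 <- c(A = 1, B = 1, C = 1, D = 1, E = 0)
  for (nm in names(toy$rules))
    expect_equal(bn_evaluate(toy, nm, a2), unname(a2[[nm]]))

  net <- random_boolean_network(8, k = 3, seed = 42)
  states <- expand.grid(rep(list(0:1), 8), KEEP.OUT.ATTRS = FALSE)
  idx <- sample.int(nrow(states), 40)   # spot-check 40 of the 256 states
  for (r in idx) {
    st <- setNames(as.integer(states[r, ]), net$nodes)
    for (nm in net$nodes)
      expect_equal(bn_evaluate(net, nm, st), oracle_eval(net, nm, st))
  }
  expect_error(bn_evaluate(net, "x1", c(x1 = 1)), "incomplete")
})

test_that("prime implicants form the complete, irredundant Blake canonical form", {
  net <- bn_parse("X* = A and B")
  pif <- prime_implicants(net, "X", 1)
  expect_equal(length(pif$implicants), 1L)
  expect_equal(pif$implicants[[1]], c(A = 1L, B = 1L))

  ## target 0 of A or (B and not C)
  net <- bn_parse("X* = A or (B and not C)")
  keys <- motif_keys(prime_implicants(net, "X", 0)$implicants)
  expect_equal(keys, c("A=0,B=0", "A=0,C=1"))

  ## the consensus term of the classic example is present
  net <- bn_parse("X* = (A and B) or (not A and C) or (B and C)")
  keys <- motif_keys(prime_implicants(net, "X", 1)$implicants)
  expect_true("B=1,C=1" %in% keys)

  ## property: on random rules, every implicant forces the target for all
  ## completions, no implicant subsumes another, and the union of the
  ## implicants covers exactly the satisfying set
  for (seed in 1:10) {
    net <- random_boolean_network(5, k = 4, p = 0.4, seed = seed)
    tt <- rule_truth_table(net, "x1")
    k <- length(tt$inputs)
    if (k == 0) next
    for (target in 0:1) {
      pif <- prime_implicants(net, "x1", target)
      states <- expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE)
      names(states) <- tt$inputs
      want <- if (target == 1) tt$tt == 1 else tt$tt == 0
      covered <- rep(FALSE, nrow(states))
      for (im in pif$implicants) {
        hit <- rep(TRUE, nrow(states))
        for (nm in names(im)) hit <- hit & states[[nm]] == im[[nm]]
        expect_true(all(want[hit]))   # implicant forces the target
        covered <- covered | hit
      }
      expect_equal(covered, want)     # completeness of the cover
      if (length(pif$implicants) > 1) {
        for (i in seq_along(pif$implicants)) for (j in seq_along(pif$implicants)) {
          if (i == j) next
          a <- pif$implicants[[i]]; b <- pif$implicants[[j]]
          expect_false(all(names(a) %in% names(b)) &&
                         all(b[names(a)] == a))   # irredundancy
        }
      }
    }
  }
})

test_that("substitution percolates to closure and is idempotent", {
  toy <- toy_network()
  red <- bn_reduce(toy, c(A = 1, B = 1))
  expect_equal(sort(names(red$network$rules)), c("D", "E"))
  expect_equal(red$fixed, c(A = 1L, B = 1L, C = 1L))

  ## fixing a full steady state leaves nothing free
  red2 <- bn_reduce(toy, c(A = 1, B = 1, C = 1, D = 1, E = 0))
  expect_equal(length(red2$network$rules), 0L)

  ## idempotence: reducing a reduced network with nothing new is identity
  again <- bn_reduce(red$network, integer(0))
  expect_equal(names(again$network$rules), names(red$network$rules))
  for (nm in names(red$network$rules))
    expect_identical(rule_truth_table(again$network, nm),
                     rule_truth_table(red$network, nm))

  expect_error(bn_reduce(toy, c(A = 1, A = 0)), "contradiction")

  ## reduced dynamics equal original dynamics conditioned on the fixed set
  for (seed in 1:5) {
    net <- random_boolean_network(6, k = 2, seed = seed)
    fx <- c(x1 = 1L)
    red <- bn_reduce(net, fx)
    free <- names(red$network$rules)
    if (!length(free)) next
    grid <- expand.grid(rep(list(0:1), length(free)), KEEP.OUT.ATTRS = FALSE)
    for (r in head(seq_len(nrow(grid)), 16)) {
      sub <- setNames(as.integer(grid[r, ]), free)
      full <- c(red$fixed, sub)[net$nodes]
      names(full) <- net$nodes
      for (nm in free)
        expect_equal(bn_evaluate(red$network, nm, sub),
                     oracle_eval(net, nm, full))
    }
  }
})
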