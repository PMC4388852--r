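test_that("reduction by a motif percolates into the expected child", {
  toy <- toy_network()
  sd <- build_succession_diagram(toy)
  root <- sd$nodes[[sd$root]]
  keys <- vapply(root$motifs, set_key, character(1))

  ab <- reduce_by_motif(list(fixed = integer(0), network = toy,
                             sequence = list()),
                        root$motifs[[match("A=1,B=1", keys)]])
  expect_equal(sort(names(ab$network$rules)), c("D", "E"))
  expect_equal(motif_keys(find_stable_motifs(ab$network)), c("E=0", "E=1"))

  e1 <- reduce_by_motif(list(fixed = integer(0), network = toy,
                             sequence = list()),
                        root$motifs[[match("E=1", keys)]])
  expect_equal(motif_keys(find_stable_motifs(e1$network)), c("A=0", "A=1,B=1"))

  ## a non-motif argument signals a contradiction
  expect_error(reduce_by_motif(list(fixed = integer(0), network = toy,
                                    sequence = list()),
                               c(A = 1)), "not a stable motif")
})

test_that("the worked example yields four steady-state quasi-attractors", {
  sd <- build_succession_diagram(toy_network())
  qa <- quasi_attractors(sd)
  expect_equal(length(qa), 4L)
  expect_true(all(vapply(qa, function(q) length(q$osc) == 0, logical(1))))
  sigs <- sort(vapply(qa, function(q) q$signature, character(1)))
  expect_equal(sigs, sort(c("11101", "11110", "00011", "00110")))
  ## deterministic labels: most-active first
  expect_equal(vapply(qa, function(q) q$label, character(1)),
               c("A1", "A2", "A3", "A4"))
})

test_that("acyclic networks percolate to a single leaf without motifs", {
  net <- bn_parse(c("A* = S", "B* = A", "C* = A and B"))
  net <- bn_environment(net, c(S = 1))
  sd <- build_succession_diagram(net)
  expect_equal(length(sd$nodes), 1L)
  expect_equal(length(quasi_attractors(sd)), 1L)
  expect_equal(count_sequences(sd), 1L)
})

test_that("unstable oscillations appear as an OSC-marked leaf", {
  sd <- build_succession_diagram(xnor_network())
  qa <- quasi_attractors(sd)
  expect_equal(length(qa), 2L)
  fixed <- Filter(function(q) length(q$osc) == 0, qa)
  osc <- Filter(function(q) length(q$osc) > 0, qa)
  expect_equal(length(fixed), 1L)
  expect_equal(fixed[[1]]$states, c(A = 1L, B = 1L))
  expect_equal(sort(osc[[1]]$osc), c("A", "B"))
})

test_that("sequence counting matches exhaustive path enumeration", {
  sd <- build_succession_diagram(toy_network())
  ## independent count: sum of root-to-leaf paths over all targets
  total <- 0L
  for (q in quasi_attractors(sd))
    total <- total + length(sequences_to_attractor(sd, q$label))
  expect_equal(count_sequences(sd), total)
  expect_equal(count_sequences(build_succession_diagram(bn_parse("A* = A"))), 2L)
})

test_that("quasi-attractors equal brute-force attractors on random ensembles", {
  for (seed in 1:20) {
    net <- random_boolean_network(sample(4:7, 1), k = 2, seed = seed + 900)
    sd <- build_succession_diagram(net)
    qa <- quasi_attractors(sd)
    bf <- brute_force_attractors(net)
    ## every steady state appears as an OSC-free quasi-attractor and vice versa
    qa_fixed <- Filter(function(q) length(q$osc) == 0, qa)
    qs <- sort(vapply(qa_fixed, function(q)
      set_key(q$states[order(names(q$states))]), character(1)))
    bs <- sort(vapply(bf$steady, function(s) {
      full <- c(s, bf$fixed); set_key(full[order(names(full))])
    }, character(1)))
    expect_equal(qs, bs, info = paste("seed", seed))
  }
})

test_that("marker classification is exclusive and falls through", {
  toy <- toy_network()
  markers <- list(up = c(A = 1), down = c(A = 0, D = 0))
  sd <- build_succession_diagram(toy, markers = markers)
  labs <- vapply(quasi_attractors(sd), function(q) q$label, character(1))
  expect_true("up" %in% labs)
  expect_true("unclassified" %in% labs)   # A=0 attractors all have D=1
  bad <- list(one = c(A = 1), two = c(B = 1))
  qa <- quasi_attractors(build_succession_diagram(toy))
  expect_error(classify_attractor(qa[[1]], bad), "ambiguous")
})

test_that("succession diagram exports DOT and JSON", {
  sd <- build_succession_diagram(toy_network())
  dot <- succession_to_dot(sd)
  expect_true(any(grepl("style=dashed", dot)))
  js <- jsonlite::fromJSON(succession_to_json(sd))
  expect_equal(js$sequences, 9L)
  expect_equal(js$merged_nodes, length(sd$nodes))
  expect_equal(nrow(js$quasi_attractors), 4L)
})
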