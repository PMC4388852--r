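test_that("multilinear interpolation matches the rule on vertices and means", {
  net <- bn_parse("C* = A and B")
  f <- boolecube(net, "C")
  expect_equal(f(c(1, 1)), 1)
  expect_equal(f(c(0.5, 0.5)), 0.25)
  f2 <- boolecube(bn_parse("A* = A"), "A")
  for (x in c(0, 0.3, 1)) expect_equal(f2(x), x)

  ## vertex agreement for random rules, boolecube and normalized hillcube
  for (seed in 1:6) {
    net <- random_boolean_network(4, k = 3, seed = seed + 40)
    tt <- rule_truth_table(net, "x1")
    k <- length(tt$inputs)
    if (k == 0) next
    fb <- boolecube(net, "x1")
    fh <- hillcube(net, "x1", hill_params(n = 3))
    verts <- expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(verts))) {
      v <- as.numeric(verts[r, ])
      idx <- 1 + sum(v * 2^(seq_len(k) - 1))
      expect_equal(fb(v), as.numeric(tt$tt[[idx]]))
      expect_equal(fh(v), as.numeric(tt$tt[[idx]]))
    }
  }
})

test_that("Hill responses cross 1/2 at theta and sharpen with n", {
  h <- stablemotifs:::.hill
  expect_equal(h(0.4, 3, 0.4, normalized = FALSE), 0.5)
  ## n = 50 approximates a step at theta
  expect_lt(h(0.45, 50, 0.5, normalized = TRUE), 1e-2)
  expect_gt(h(0.55, 50, 0.5, normalized = TRUE), 1 - 1e-2)
})

test_that("Boolean fixed points are equilibria of the translated model", {
  toy <- toy_network()
  model <- build_ode_model(toy)
  for (q in quasi_attractors(build_succession_diagram(toy)))
    expect_lt(ode_residual(model, q$states[toy$nodes]), 1e-10)

  bi <- bn_parse("A* = A")
  mb <- build_ode_model(bi)
  expect_lt(ode_residual(mb, c(A = 0)), 1e-10)
  expect_lt(ode_residual(mb, c(A = 1)), 1e-10)

  th <- bn_fixture("thelper")
  mth <- build_ode_model(th$network)
  qs <- quasi_attractors(build_succession_diagram(th$network,
                                                  markers = th$markers))
  for (q in qs[1:2])
    expect_lt(ode_residual(mth, q$states[th$network$nodes]), 1e-10)
})

test_that("trajectories stay inside the unit cube", {
  toy <- toy_network()
  model <- build_ode_model(toy)
  set.seed(4)
  x0 <- runif(5)
  out <- deSolve::lsoda(x0, seq(0, 50, by = 1),
                        function(t, y, p) list(model$rhs(t, y)),
                        rtol = 1e-6, atol = 1e-6)
  xs <- out[, -1]
  expect_true(all(xs > -1e-6 & xs < 1 + 1e-6))
})

test_that("clamping the toy control set captures the whole cube", {
  toy <- toy_network()
  qa <- quasi_attractors(build_succession_diagram(toy))
  model <- build_ode_model(toy)
  cfg <- ode_config(n_ic = 25, t_end = 300, seed = 8)
  for (mode in c("permanent", "transient")) {
    est <- ode_attractor_probabilities(model, qa,
                                       intervention(c(A = 1, E = 0), mode),
                                       cfg)
    expect_equal(est$p[est$label == "A2"], 1)
  }
})

test_that("near-value clamping remains effective", {
  toy <- toy_network()
  qa <- quasi_attractors(build_succession_diagram(toy))
  model <- build_ode_model(toy)
  iv <- intervention(c(A = 1, E = 0), "permanent")
  attr(iv, "clamp_values") <- c(0.9, 0.1)
  est <- ode_attractor_probabilities(model, qa, iv,
                                     ode_config(n_ic = 20, t_end = 300, seed = 8))
  expect_gte(est$p[est$label == "A2"], 0.9)
})

test_that("effectiveness is robust across Hill coefficients", {
  toy <- toy_network()
  qa <- quasi_attractors(build_succession_diagram(toy))
  sweep <- ode_parameter_sweep(toy, qa, "A2",
                               intervention(c(A = 1, E = 0), "permanent"),
                               n_values = c(2, 5),
                               config = ode_config(n_ic = 10, t_end = 300,
                                                   seed = 12))
  expect_true(all(sweep$effectiveness >= 0.9))
})
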