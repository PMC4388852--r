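test_that("async updates: fixed points absorb, forced flips flip", {
  toy <- toy_network()
  a2 <- c(A = 1L, B = 1L, C = 1L, D = 1L, E = 0L)
  set.seed(1)
  for (i in 1:20) expect_equal(async_step(toy, a2), a2)

  net <- bn_parse("A* = not A")
  expect_equal(async_step(net, c(A = 0L)), c(A = 1L))
})

test_that("node selection is uniform within 3 standard errors", {
  n <- 10L
  steps <- 1e5
  counts <- stablemotifs:::cpp_selection_counts(n, steps, seed = 2024)
  expect_equal(sum(counts), steps)
  p <- 1 / n
  se <- sqrt(p * (1 - p) * steps)
  expect_true(all(abs(counts - steps * p) < 3 * se))
  ## and a chi-square test does not reject uniformity
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("simulation is reproducible and seed-sensitive", {
  toy <- toy_network()
  qa <- quasi_attractors(build_succession_diagram(toy))
  cfg <- sim_config(n_ic = 500, steps = 200, seed = 5)
  a <- estimate_attractor_probabilities(toy, qa, intervention(), cfg)
  b <- estimate_attractor_probabilities(toy, qa, intervention(), cfg)
  expect_identical(a$p, b$p)
  cfg2 <- sim_config(n_ic = 500, steps = 200, seed = 6)
  c <- estimate_attractor_probabilities(toy, qa, intervention(), cfg2)
  expect_false(identical(a$p, c$p))
})

test_that("standard errors follow the binomial error model", {
  toy <- toy_network()
  qa <- quasi_attractors(build_succession_diagram(toy))
  cfg <- sim_config(n_ic = 2000, steps = 300, seed = 9)
  est <- estimate_attractor_probabilities(toy, qa, intervention(), cfg)
  expect_equal(est$se, sqrt(est$p * (1 - est$p) / 2000))
  ## probabilities plus unresolved sum to one
  expect_equal(sum(est$p) + attr(est, "unresolved"), 1)
})

test_that("the unresolved fraction vanishes as the step budget grows", {
  toy <- toy_network()
  qa <- quasi_attractors(build_succession_diagram(toy))
  unres <- vapply(c(3, 30, 300), function(steps) {
    est <- estimate_attractor_probabilities(
      toy, qa, intervention(), sim_config(n_ic = 400, steps = steps, seed = 3))
    attr(est, "unresolved")
  }, numeric(1))
  expect_true(all(diff(unres) <= 0))
  expect_equal(unres[[3]], 0)
})

test_that("transient interventions release their clamps", {
  toy <- toy_network()
  qa <- quasi_attractors(build_succession_diagram(toy))
  cfg <- sim_config(n_ic = 600, steps = 300, seed = 21)
  ## D=0 held transiently raises the chance of reaching A3 (and cannot
  ## leave the system in a D=0 state, which is not an attractor state here)
  base <- estimate_attractor_probabilities(toy, qa, intervention(), cfg)
  dd <- estimate_attractor_probabilities(toy, qa,
                                         intervention(c(D = 0), "transient"),
                                         cfg)
  p3 <- function(x) x$p[x$label == "A3"]
  expect_gt(p3(dd), p3(base))
  ## permanently clamped D=0 destroys A3 and A4 (both have D=1)
  dperm <- estimate_attractor_probabilities(toy, qa,
                                            intervention(c(D = 0)), cfg)
  expect_equal(p3(dperm), 0)
})

test_that("validation reports mirror the published table format", {
  toy <- toy_network()
  qa <- quasi_attractors(build_succession_diagram(toy))
  cfg <- sim_config(n_ic = 300, steps = 200, seed = 2)
  df <- validation_report(toy, qa,
                          list(intervention(c(A = 1, E = 0), "transient")),
                          cfg)
  expect_true(all(c("intervention", "mode", "attractor", "percent",
                    "se_percent", "baseline_percent", "relative_change",
                    "unresolved_percent") %in% names(df)))
  expect_equal(df$percent[df$attractor == "A2"], 100)
})
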