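test_that("synchronous update is simultaneous and deterministic", {
  bm <- random_boolean_model(n = 5, seed = 7)
  a0 <- stats::setNames(rep(FALSE, 5), bm$variables)
  t1 <- run_sync(bm, a0, max_steps = 40)
  t2 <- run_sync(bm, a0, max_steps = 40)
  expect_identical(t1$assignments, t2$assignments)
  expect_identical(t1$attractor, t2$attractor)
})

test_that("two sync steps equal the symbolic two-step rule composition", {
  # oracle: substitute each rule into itself symbolically, evaluate once
  for (seed in c(3, 11, 23)) {
    bm <- random_boolean_model(n = 5, seed = seed)
    composed <- lapply(bm$rules, subst_rules, rules = bm$rules)
    for (a in all_assignments(bm$variables)) {
      two <- sync_step(bm, sync_step(bm, a))
      oracle <- vapply(bm$variables, function(v)
        eval_expr(composed[[v]], a), logical(1))
      expect_identical(unname(two[bm$variables]), unname(oracle))
    }
  }
})

test_that("a fixed point maps to itself and constant models converge by step 2", {
  bm <- boolean_model(list(A = b_true(), B = b_false(), C = b_atom("A")))
  tr <- run_sync(bm, c(A = FALSE, B = TRUE, C = FALSE))
  expect_equal(tr$attractor$type, "point")
  expect_true(tr$attractor$index <= 2)
  fp <- at_attractor(tr)
  expect_identical(sync_step(bm, fp), fp)
})

test_that("unregulated reactions fire at step 1 and their reversible products at step 2, staying on", {
  bm <- build_bipartite(parse_quick(c("A_ppi_B", "C_P+_D")))
  tr <- run_sync(bm, default_init(bm), max_steps = 20)
  m <- tr$assignments  # row t+1 is time t
  expect_false(any(m[1, c("A_ppi_B", "C_P+_D", "A--B", "D-{P}")]))
  expect_true(all(m[2, c("A_ppi_B", "C_P+_D")]))
  expect_false(any(m[2, c("A--B", "D-{P}")]))
  expect_true(all(m[3:nrow(m), c("A_ppi_B", "C_P+_D", "A--B", "D-{P}")]))
})

test_that("clamped variables hold their value regardless of their rule; one-shot sets recover", {
  bm <- build_bipartite(parse_quick("A_ppi_B"))
  sched <- perturbations(t = c(2, 6), var = "A_ppi_B",
                         value = c(FALSE, FALSE), clamp = c(TRUE, FALSE))
  tr <- run_sync(bm, default_init(bm), sched, max_steps = 15)
  m <- tr$assignments
  # clamp window t = 2..5: held FALSE although components are present
  expect_false(any(m[3:6, "A_ppi_B"]))
  expect_false(m[7, "A_ppi_B"])       # one-shot set at t = 6 releases the clamp
  expect_true(all(m[8:nrow(m), "A_ppi_B"]))  # rule recovers the reaction
  # the bond decays while its producer is clamped off
  expect_false(m[6, "A--B"])
})

test_that("attractor period is minimal", {
  ring <- boolean_model(list(A = b_not(b_atom("C")), B = b_atom("A"),
                             C = b_atom("B")))
  tr <- run_sync(ring, c(A = FALSE, B = FALSE, C = FALSE))
  expect_equal(tr$attractor$type, "cycle")
  p <- tr$attractor$period
  m <- tr$assignments
  i <- tr$attractor$index + 1L
  expect_identical(m[i, ], m[i + p, ])
  divisors <- setdiff(which(p %% seq_len(p - 1L) == 0L), 0L)
  for (d in divisors) {
    expect_false(identical(m[i, ], m[i + d, ]))
  }
})

test_that("asynchronous ensemble means are reproducible and bounded", {
  bm <- build_bipartite(toy_crosstalk())
  a1 <- run_async(bm, default_init(bm, "[Pher]"), n_runs = 20, n_steps = 10, seed = 5)
  a2 <- run_async(bm, default_init(bm, "[Pher]"), n_runs = 20, n_steps = 10, seed = 5)
  expect_identical(unclass(a1), unclass(a2))
  a3 <- run_async(bm, default_init(bm, "[Pher]"), n_runs = 20, n_steps = 10, seed = 6)
  expect_false(identical(unclass(a1), unclass(a3)))
  expect_true(all(a1 >= 0 & a1 <= 1))
  # single run: entries are exact truth values
  a4 <- run_async(bm, default_init(bm), n_runs = 1, n_steps = 5, seed = 1)
  expect_true(all(a4 %in% c(0, 1)))
})

test_that("async negative-feedback cycle has interior long-run means; mutual inhibition settles", {
  # A* = !B, B* = A: exhaustive enumeration of the two update orders shows
  # no configuration is stable under sequential passes, so ensemble means
  # stay strictly between 0 and 1
  cyc <- boolean_model(list(A = b_not(b_atom("B")), B = b_atom("A")))
  act <- run_async(cyc, c(A = FALSE, B = FALSE), n_runs = 400, n_steps = 20, seed = 2)
  final <- act[, ncol(act)]
  expect_true(all(final > 0 & final < 1))

  # mutual-inhibition toggle: every run settles into one of the two point
  # attractors after the first pass, the ensemble splits about evenly
  tog <- boolean_model(list(A = b_not(b_atom("B")), B = b_not(b_atom("A"))))
  for (seed in 1:10) {
    one <- run_async(tog, c(A = FALSE, B = FALSE), n_runs = 1, n_steps = 8, seed = seed)
    expect_true(all(one[, 3:9] == one[, 2]))     # constant after first pass
    expect_equal(sum(one[, 9]), 1)               # exactly one of A/B on
  }
  ens <- run_async(tog, c(A = FALSE, B = FALSE), n_runs = 400, n_steps = 6, seed = 9)
  expect_gt(ens["A", 7], 0.4)
  expect_lt(ens["A", 7], 0.6)
})

test_that("async clamps hold throughout", {
  bm <- build_bipartite(parse_quick("A_ppi_B"))
  act <- run_async(bm, default_init(bm), n_runs = 10, n_steps = 6, seed = 1,
                   clamps = c(`A_ppi_B` = FALSE))
  expect_true(all(act["A_ppi_B", ] == 0))
})
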