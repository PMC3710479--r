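test_that("reaction rules conjoin components, requirements and negated inhibitors", {
  m <- parse_quick(c("Hog1_P+_Hot1; ! Hog1-{P}", "Ssk1_ppi_Ssk2; x Ssk1-{P}",
                     "Sln1_AP_Sln1"))
  expect_true(expr_equal(
    reaction_rule(m, "Hog1_P+_Hot1"),
    b_and(b_atom("Hog1"), b_atom("Hot1"), b_atom("Hog1-{P}"))))
  expect_true(expr_equal(
    reaction_rule(m, "Ssk1_ppi_Ssk2"),
    b_and(b_atom("Ssk1"), b_atom("Ssk2"), b_not(b_atom("Ssk1-{P}")))))
  # no contingencies: components only; autoreaction has a single conjunct
  expect_true(expr_equal(reaction_rule(m, "Sln1_AP_Sln1"), b_atom("Sln1")))
})

test_that("state rules reproduce the irreversible-latch and reversible-decay forms", {
  m <- parse_quick(c("Sln1_AP_Sln1", "Sln1_PT_Ypd1", "Ssk1_ppi_Ssk2"))
  # irreversible producer + consumer: producer | (state & !consumer)
  expect_true(expr_equal(
    state_rule(m, "Sln1-{P}", components_in_states = FALSE),
    b_or(b_atom("Sln1_AP_Sln1"),
         b_and(b_atom("Sln1-{P}"), b_not(b_atom("Sln1_PT_Ypd1"))))))
  # single reversible producer, no consumer: tracks the producer
  expect_true(expr_equal(
    state_rule(m, "Ssk1--Ssk2", components_in_states = FALSE),
    b_atom("Ssk1_ppi_Ssk2")))
  # component conjuncts on by default
  expect_true(expr_equal(
    state_rule(m, "Ssk1--Ssk2"),
    b_and(b_atom("Ssk1"), b_atom("Ssk2"), b_atom("Ssk1_ppi_Ssk2"))))
})

test_that("mixed producers: irreversible synthesis overrides consumption, reversible maintenance is gated", {
  m <- parse_quick(c("A_P+_B", "C_ppi_B", "D_P-_B"))
  # B-{P}: irr producer A_P+_B, consumer D_P-_B
  r <- state_rule(m, "B-{P}", components_in_states = FALSE)
  expect_true(expr_equal(
    r, b_or(b_atom("A_P+_B"), b_and(b_atom("B-{P}"), b_not(b_atom("D_P-_B"))))))
  a <- c(`A_P+_B` = TRUE, `B-{P}` = FALSE, `D_P-_B` = TRUE)
  expect_true(eval_expr(r, a))  # synthesis wins over consumption
})

test_that("flatten_effector expands Boolean nodes recursively to elemental atoms", {
  m <- parse_quick(c(
    "<L1> = AND(A-{P}, <L2>)",
    "<L2> = OR(B--C, <L3>)",
    "<L3> = NOT(C-{P})",
    "A_P+_B",
    "B_ppi_C; ! <L1>",
    "A_P+_C"
  ))
  got <- flatten_effector(m, "<L1>")
  # manual textbook expansion of the 3-level tree
  manual <- b_and(b_atom("A-{P}"), b_or(b_atom("B--C"), b_not(b_atom("C-{P}"))))
  expect_true(expr_equal(got, manual))
  expect_true(expr_equal(flatten_effector(m, "Hog1-{P}"), b_atom("Hog1-{P}")))
  # cycles are named
  mc <- rxncon(tibble::tibble(reaction = "A_ppi_B"),
               bool_nodes = list(X = list(op = "AND", children = c("<Y>", "A--B")),
                                 Y = list(op = "OR", children = c("<X>", "A--B"))))
  expect_error(flatten_effector(mc, "<X>"), "cyclic.*X.*Y")
})

test_that("contingency policy maps K+/K- to !/x by default and drops them when neutral", {
  m <- parse_quick(c("A_P+_B", "A_ppi_B; K+ B-{P}"))
  strict <- reaction_rule(m, "A_ppi_B", policy = "strict-qualitative")
  neutral <- reaction_rule(m, "A_ppi_B", policy = "neutral")
  expect_true(expr_equal(strict, b_and(b_atom("A"), b_atom("B"), b_atom("B-{P}"))))
  expect_true(expr_equal(neutral, b_and(b_atom("A"), b_atom("B"))))
  # the two builds differ by exactly that one conjunct
  bs <- build_bipartite(m, policy = "strict-qualitative")
  bn <- build_bipartite(m, policy = "neutral")
  expect_equal(setdiff(expr_vars(bs$rules[["A_ppi_B"]]),
                       expr_vars(bn$rules[["A_ppi_B"]])), "B-{P}")
  # signs 0 and ? never contribute
  m0 <- parse_quick(c("A_P+_B", "A_ppi_B; 0 B-{P}; ? B-{P}"))
  expect_true(expr_equal(reaction_rule(m0, "A_ppi_B"),
                         b_and(b_atom("A"), b_atom("B"))))
})

test_that("build_bipartite is deterministic and declares every atom it uses", {
  for (seed in 1:10) {
    m <- random_model(n_components = 5, n_reactions = 7, seed = seed)
    b1 <- build_bipartite(m)
    b2 <- build_bipartite(m)
    expect_identical(tidy(b1), tidy(b2))
    for (v in b1$variables) {
      expect_true(all(expr_vars(b1$rules[[v]]) %in% b1$variables))
    }
  }
  # every contingency effector appears in exactly the targeted reaction's rule
  m <- toy_crosstalk()
  bm <- build_bipartite(m)
  rx_cg <- m$contingencies[m$contingencies$target %in% m$reactions$id, ]
  for (j in seq_len(nrow(rx_cg))) {
    tgt <- rx_cg$target[j]; eff <- rx_cg$effector[j]
    expect_true(eff %in% expr_vars(bm$rules[[tgt]]))
    others <- setdiff(m$reactions$id, m$contingencies$target[
      m$contingencies$effector == eff])
    for (o in others) {
      expect_false(eff %in% expr_vars(bm$rules[[o]]))
    }
  }
})

test_that("empty model builds an empty Boolean model", {
  bm <- build_bipartite(rxncon())
  expect_equal(length(bm$variables), 0L)
})

test_that("latch property: irreversibly produced states are monotone while unconsumed", {
  bm <- build_bipartite(parse_quick("A_P+_B"))
  for (a0 in all_assignments(bm$variables)) {
    tr <- run_sync(bm, a0, max_steps = 10)
    s <- tr$assignments[, "B-{P}"]
    expect_true(all(diff(s) >= 0) || !a0[["B"]])  # monotone when B present
  }
})

test_that("decay property: reversible-producer state tracks components & producer one step delayed", {
  bm <- build_bipartite(parse_quick("A_ppi_B"))
  for (a0 in all_assignments(bm$variables)) {
    tr <- run_sync(bm, a0, max_steps = 8)
    m <- tr$assignments
    for (t in seq_len(nrow(m) - 1L)) {
      expect_identical(unname(m[t + 1L, "A--B"]),
                       unname(m[t, "A"] && m[t, "B"] && m[t, "A_ppi_B"]))
    }
  }
})

test_that("frozen states (referenced but never produced) keep their value", {
  m <- parse_quick("A_ppi_B; ! C-{P}")
  bm <- suppressWarnings(build_bipartite(m))
  expect_true(expr_equal(bm$rules[["C-{P}"]], b_atom("C-{P}")))
  expect_true("C-{P}" %in% attr(bm, "frozen_states"))
})

test_that("synthesis and degradation make component presence dynamic", {
  m <- parse_quick(c("A_TRSC_B", "C_DEG_B", "B_P+_D"))
  bm <- build_bipartite(m)
  expect_true(expr_equal(
    bm$rules[["B"]],
    b_or(b_atom("A_TRSC_B"), b_and(b_atom("B"), b_not(b_atom("C_DEG_B"))))))
  # degradation-only component decays once the DEG reaction fires
  m2 <- parse_quick("C_DEG_B")
  bm2 <- build_bipartite(m2)
  tr <- run_sync(bm2)
  expect_false(at_attractor(tr)[["B"]])
})
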