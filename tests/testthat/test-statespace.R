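test_that("hand-enumerable 2-variable system yields two points and a 2-cycle", {
  bm <- boolean_model(list(A = b_atom("B"), B = b_atom("A")))
  tg <- enumerate_full(bm)
  gl <- glance(tg)
  expect_equal(nrow(gl), 3L)
  expect_equal(sort(gl$type), c("cycle", "point", "point"))
  expect_equal(gl$period[gl$type == "cycle"], 2L)
  # basins partition the full space
  expect_equal(sum(gl$basin), 4L)
  # the two fixed points are (0,0) and (1,1)
  points <- unlist(lapply(tg$attractors, function(a)
    if (a$type == "point") a$members))
  expect_setequal(points, c("0", "3"))
})

test_that("every node has out-degree one and basins always partition 2^n", {
  for (seed in c(2, 5, 9)) {
    bm <- random_boolean_model(n = 6, seed = seed)
    tg <- enumerate_full(bm)
    expect_equal(length(tg$nxt), 2^6)
    expect_true(all(tg$nxt >= 1 & tg$nxt <= 2^6))   # total successor map
    expect_equal(sum(glance(tg)$basin), 2^6)
    expect_true(all(tg$attractor_of >= 1))
  }
})

test_that("enumeration agrees with exhaustive synchronous simulation (oracle equivalence)", {
  models <- list(
    build_bipartite(parse_quick(c("A_ppi_B", "C_P+_D; x A--B"))),
    build_bipartite(parse_quick(c("Sln1_AP_Sln1", "Sln1_PT_Ypd1"))),
    random_boolean_model(n = 7, seed = 4)
  )
  for (bm in models) {
    free <- bm$variables[!bm$roles %in% c("component", "input")]
    expect_lte(length(free), 10L)
    tg <- enumerate_full(bm)
    base <- default_init(bm)
    # oracle: run the simulator from every global state, collect attractor sets
    keys_of <- function(assign_rows) {
      fi <- match(free, bm$variables)
      apply(assign_rows, 1L, function(r) rxnbool:::state_key(as.logical(r[fi])))
    }
    found <- character()
    for (a0 in all_assignments(free)) {
      init <- base; init[free] <- a0
      tr <- run_sync(bm, init, max_steps = 2^length(free) + 2L)
      expect_true(tr$converged)
      i <- tr$attractor$index + 1L
      cyc <- tr$assignments[seq(i, i + tr$attractor$period - 1L), , drop = FALSE]
      found <- c(found, paste(sort(keys_of(cyc)), collapse = "|"))
    }
    expect_setequal(unique(found), attractor_fingerprint(tg))
  }
})

test_that("reachable closure from one start is the trajectory plus its cycle", {
  bm <- build_bipartite(parse_quick(c("A_ppi_B", "C_P+_D")))
  start <- default_init(bm)
  tg <- reachable(bm, start)
  tr <- run_sync(bm, start)
  fi <- match(tg$free_vars, bm$variables)
  traj_keys <- unique(apply(tr$assignments, 1L, function(r)
    rxnbool:::state_key(as.logical(r[fi]))))
  expect_setequal(tg$keys, traj_keys)
})

test_that("reachable from all states equals full enumeration", {
  bm <- random_boolean_model(n = 5, seed = 13)
  starts <- all_assignments(bm$variables)
  tg_r <- reachable(bm, starts)
  tg_f <- enumerate_full(bm)
  expect_setequal(tg_r$keys, tg_f$keys)
  expect_equal(attractor_fingerprint(tg_r), attractor_fingerprint(tg_f))
})

test_that("enumeration refuses beyond the cap and points to reachable mode", {
  bm <- random_boolean_model(n = 8, seed = 1)
  expect_error(enumerate_full(bm, cap = 6), "reachable")
})

test_that("components and inputs are excluded from free variables by default", {
  bm <- build_bipartite(simplified_hog())
  free <- rxnbool:::free_variable_set(bm, NULL)
  expect_false(any(bm$roles[free] %in% c("component", "input")))
})

test_that("transition graphs export to igraph/GraphML/DOT", {
  bm <- boolean_model(list(A = b_atom("B"), B = b_atom("A")))
  tg <- enumerate_full(bm)
  g <- as_igraph(tg)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 4L)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".dot")
  export_transition_graph(tg, f1, "graphml")
  export_transition_graph(tg, f2, "dot")
  expect_true(file.size(f1) > 0 && file.size(f2) > 0)
})
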