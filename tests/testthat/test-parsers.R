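test_that("reaction ids parse into components and registered types", {
  r <- parse_reaction_id("Hog1_P+_Hot1")
  expect_equal(r$a, "Hog1")
  expect_equal(r$type, "P+")
  expect_equal(r$b, "Hot1")
  auto <- parse_reaction_id("Sln1_AP_Sln1")
  expect_equal(auto$a, auto$b)
  expect_error(parse_reaction_id("Hog1__Hot1"), "empty reaction type")
  expect_error(parse_reaction_id("Hog1_XX_Hot1"), "unknown reaction type")
  expect_error(parse_reaction_id(""), "empty")
})

test_that("quick format parses reactions, contingencies, outputs and nodes", {
  m <- parse_quick("Ssk1_ppi_Ssk2; x Ssk1-{P}")
  expect_equal(nrow(m$reactions), 1L)
  expect_equal(m$contingencies$sign, "x")
  expect_equal(m$contingencies$effector, "Ssk1-{P}")

  empty <- parse_quick("")
  expect_s3_class(empty, "rxncon_model")
  expect_equal(nrow(empty$reactions), 0L)

  m2 <- parse_quick(c(
    "<Gate> = AND(A-{P}, [Sig])",
    "A_P+_B",
    "A_ppi_B; ! <Gate>",
    "[OUT]; ! A--B"
  ))
  expect_equal(names(m2$bool_nodes), "Gate")
  expect_equal(m2$inputs, "[Sig]")
  expect_equal(m2$outputs, "[OUT]")
  expect_true("<Gate>" %in% m2$contingencies$effector)

  # per-line errors are collected with line numbers
  err <- tryCatch(parse_quick(c("A_ppi_B", "bogus line", "B__C")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "line 2")
  expect_match(err, "line 3")
})

test_that("quick parse equals the object-by-object constructor route", {
  # independent route: build the simplified HOG model via rxncon()
  rx <- tibble::tibble(reaction = c(
    "Sln1_AP_Sln1", "Sln1_PT_Ypd1", "Ypd1_PT_Ssk1", "Ssk1_ppi_Ssk2",
    "Ssk2_P+_Pbs2", "Pbs2_P+_Hog1", "Hog1_P+_Hot1",
    "Ptc1_P-_Ssk1", "Ptc1_P-_Pbs2", "Ptc1_P-_Hog1", "Ptc1_P-_Hot1"))
  cg <- tibble::tibble(
    target = c("Sln1_AP_Sln1", "Sln1_PT_Ypd1", "Ypd1_PT_Ssk1",
               "Ssk1_ppi_Ssk2", "Ssk2_P+_Pbs2", "Pbs2_P+_Hog1",
               "Hog1_P+_Hot1", "[Turgor]"),
    sign = c("!", "!", "!", "x", "!", "!", "!", "!"),
    effector = c("[Turgor]", "Sln1-{P}", "Ypd1-{P}", "Ssk1-{P}",
                 "Ssk1--Ssk2", "Pbs2-{P}", "Hog1-{P}", "Hot1-{P}"))
  manual <- rxncon(reactions = rx, contingencies = cg)
  fix <- simplified_hog()
  expect_setequal(manual$reactions$id, fix$reactions$id)
  expect_setequal(manual$components, fix$components)
  expect_equal(dplyr::arrange(manual$contingencies, target, effector),
               dplyr::arrange(fix$contingencies, target, effector))
  expect_equal(manual$outputs, fix$outputs)
  expect_setequal(model_states(manual)$state, model_states(fix)$state)
})

test_that("quick text round-trips through write_quick", {
  for (m in list(simplified_hog(), toy_crosstalk(),
                 parse_quick(c("<G> = OR(A-{P}, [S])", "A_P+_B; ! <G>; K- B-{P}")))) {
    m2 <- parse_quick(write_quick(m))
    expect_equal(m2$reactions, m$reactions)
    expect_equal(dplyr::arrange(m2$contingencies, target, effector),
                 dplyr::arrange(m$contingencies, target, effector))
    expect_equal(m2$bool_nodes, m$bool_nodes)
    expect_equal(m2$outputs, m$outputs)
    expect_equal(m2$inputs, m$inputs)
  }
})

test_that("tabular loading equals quick parsing of the same content", {
  quick <- parse_quick(c("A_P+_B; ! [Sig]", "A_ppi_B; x B-{P}"))
  tab <- load_tabular(
    tibble::tibble(Reaction = c("A_P+_B", "A_ppi_B")),
    tibble::tibble(Target = c("A_P+_B", "A_ppi_B"),
                   Contingency = c("!", "x"),
                   Modifier = c("[Sig]", "B-{P}")))
  expect_equal(tab$reactions, quick$reactions)
  expect_equal(dplyr::arrange(tab$contingencies, target),
               dplyr::arrange(quick$contingencies, target))
  expect_equal(tab$inputs, quick$inputs)
})

test_that("tabular loader generates ids, reads files, handles node rows", {
  # component/type columns with auto-generated ids
  m <- load_tabular(tibble::tibble(component_a = "A", reaction_type = "ppi",
                                   component_b = "B"))
  expect_equal(m$reactions$id, "A_ppi_B")

  # Boolean nodes defined as contingency rows with a <Node> target
  m2 <- load_tabular(
    tibble::tibble(reaction = c("A_P+_B", "C_ppi_D")),
    tibble::tibble(target = c("<G>", "<G>", "A_P+_B"),
                   sign = c("OR", "OR", "!"),
                   effector = c("C--D", "B-{P}", "<G>")))
  expect_equal(m2$bool_nodes$G$op, "OR")
  expect_equal(sort(m2$bool_nodes$G$children), c("B-{P}", "C--D"))

  # missing mandatory column is a schema error
  expect_error(load_tabular(tibble::tibble(foo = "A_ppi_B")),
               "missing mandatory column")

  # file round trip (TSV pair)
  rp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_tabular(toy_crosstalk(), rp, cp)
  m3 <- load_tabular(rp, cp)
  expect_equal(m3$reactions, toy_crosstalk()$reactions)
  expect_equal(dplyr::arrange(m3$contingencies, target, effector),
               dplyr::arrange(toy_crosstalk()$contingencies, target, effector))
})
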