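# Model container, I/O, validation, GPR evaluation and expression closure.

test_that("a minimal one-metabolite model file loads", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
  "id": "mini", "species": "toy",
  "biomass_reaction": "EX_x_e", "atpm_reaction": "EX_x_e",
  "biomass_gam": 0,
  "metabolites": [
    {"id": "x_e", "name": "x", "compartment": "e", "formula": null,
     "charge": null}
  ],
  "reactions": [
    {"id": "EX_x_e", "name": "exchange", "lower": -10, "upper": 10,
     "gpr": "", "subsystem": "Other", "stoichiometry": {"x_e": -1}}
  ]
}', f)
  m <- readModel(f)
  expect_s4_class(m, "MetabolicModel")
  expect_identical(nrow(metabolites(m)), 1L)
  expect_identical(nrow(reactions(m)), 1L)
  expect_length(validateModel(m), 0)
})

test_that("shipped core model fixtures load, validate, and resolve ids", {
  for (f in c("pcar_core.json", "ppro_core.json")) {
    m <- readModel(system.file("extdata", f, package = "pelocore"))
    expect_length(validateModel(m), 0)
    expect_true(biomassReaction(m) %in% reactions(m)$id)
    expect_true(atpmReaction(m) %in% reactions(m)$id)
    expect_gt(m@biomassGAM, 0)
  }
})

test_that("JSON serialisation is canonical and TSV round-trips", {
  m <- buildPcarCore()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeModel(m, f1)
  writeModel(readModel(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  d <- withr::local_tempdir()
  writeModel(m, d, format = "tsv")
  m2 <- readModel(d)
  expect_equal(m2@S[rownames(m@S), colnames(m@S)], m@S)
  expect_equal(reactions(m2)$lower, reactions(m)$lower)
  expect_identical(reactions(m2)$gpr, reactions(m)$gpr)
})

test_that("structural errors name the offending record", {
  mets <- data.frame(id = "a", name = "a", compartment = "c",
                     formula = NA, charge = NA)
  rxns <- data.frame(id = "R1", name = "r", lower = 0, upper = 1,
                     gpr = "", subsystem = "Other")
  expect_error(
    makeModel("x", "x", mets, rxns, list(c(a = -1, ghost = 1)),
              "R1", "R1"),
    "ghost")
  expect_error(
    makeModel("x", "x", rbind(mets, mets), rxns[c(1, 1), ],
              list(c(a = -1), c(a = -1)), "R1", "R1"),
    "duplicate")
  mets2 <- transform(mets, compartment = "periplasm")
  expect_error(
    makeModel("x", "x", mets2, rxns, list(c(a = -1)), "R1", "R1"),
    "compartment")
})

test_that("validateModel reports imbalance and missing designated reactions", {
  mets <- data.frame(id = c("a", "b"), name = c("a", "b"),
                     compartment = "c",
                     formula = c("CH4", "CH4O"), charge = 0)
  rxns <- data.frame(id = c("R1", "ATPM1"), name = c("a to b", "m"),
                     lower = 0, upper = 1, gpr = "", subsystem = "Other")
  m <- makeModel("x", "x", mets, rxns, list(c(a = -1, b = 1), c(b = -1, a = 1)),
                 biomassReaction = "ATPM1", atpmReaction = "MISSING",
                 check = FALSE)
  v <- validateModel(m)
  expect_true(any(grepl("unbalanced in O", v)))
  expect_true(any(grepl("missing ATPM", v)))
  # the valid core model gives an empty report, with charges too
  expect_length(validateModel(pcarDefault, checkCharge = TRUE), 0)
})

test_that("formula parsing handles multi-letter elements and counts", {
  expect_equal(parseFormula("C23H34N7O17P3S"),
               c(C = 23, H = 34, N = 7, O = 17, P = 3, S = 1))
  expect_equal(unname(parseFormula("Mg")), 1)
  expect_error(parseFormula("C2(H4)"), "parse")
})

test_that("GPR rules follow OR-of-AND semantics", {
  expect_false(evaluateGPR("Pcar_2542 & Pcar_2543", "Pcar_2542"))
  expect_true(evaluateGPR("Pcar_2542 & Pcar_2543",
                          c("Pcar_2542", "Pcar_2543")))
  expect_true(evaluateGPR("", character(0)))
  expect_true(evaluateGPR("(g1 & g2) or g3", "g3"))
  expect_false(evaluateGPR("(g1 & g2) or g3", "g1"))
  expect_error(evaluateGPR("g1 &; g2", "g1"), "malformed")
  expect_setequal(gprGenes("(g1 & g2) or g3"), c("g1", "g2", "g3"))
})

test_that("expression closure with an empty profile is the identity", {
  m2 <- applyExpressionClosure(pcarDefault, numeric(0), threshold = 1)
  expect_equal(reactions(m2), reactions(pcarDefault))
})

test_that("closure reroutes flux through the expressed isozyme", {
  prof <- c(Pcar_2542 = 230, Pcar_2850 = 10)  # 23-fold expression gap
  mc <- applyExpressionClosure(pcarDefault, prof, threshold = 50)
  rx <- reactions(mc)
  expect_identical(rx$upper[rx$id == "PTA2"], 0)
  expect_gt(rx$upper[rx$id == "PTA"], 0)
  r <- runScenario(paperScenarios()$pcar_actn_ferm, model = mc)
  expect_identical(solverStatus(r$solution), "optimal")
  expect_identical(unname(fluxes(r$solution)["PTA2"]), 0)
})

test_that("closing the sole acetoin oxidoreductase abolishes acetoin growth", {
  prof <- c(Pcar_0343 = 0.1)
  mc <- applyExpressionClosure(pcarDefault, prof, threshold = 1)
  r <- runScenario(paperScenarios()$pcar_actn_ferm, model = mc)
  expect_identical(solverStatus(r$solution), "infeasible")
})

test_that("unknown profile genes are ignored with a warning", {
  expect_warning(
    applyExpressionClosure(pcarDefault, c(NotAGene_1 = 5), threshold = 1),
    "NotAGene_1")
})

test_that("SBML export writes a well-formed fbc document", {
  f <- withr::local_tempfile(fileext = ".xml")
  exportSBML(pcarDefault, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns(doc)
  sp <- xml2::xml_find_all(doc, ".//d1:species", ns)
  rx <- xml2::xml_find_all(doc, ".//d1:reaction", ns)
  expect_length(sp, nrow(metabolites(pcarDefault)))
  expect_length(rx, nrow(reactions(pcarDefault)))
})
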