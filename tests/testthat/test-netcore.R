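test_that("reaction and model constructors enforce their invariants", {
  expect_error(reaction("R1", c(A = -1)), "reactant and one product")
  expect_error(reaction("", c(A = -1, B = 1)))
  expect_silent(reaction("EX_A", c(A = 1)))  # exchange namespace may be one-sided
  expect_error(metabolic_model(list(reaction("R1", c(A = -1, B = 1)),
                                    reaction("R1", c(A = -1, C = 1))),
                               model_condition()),
               "duplicate reaction ids")
  expect_error(metabolic_model(list(reaction("R1", c(A = -1, B = 1))),
                               model_condition(), metabolites = c("A")),
               "absent from the model")
  expect_error(metabolic_model(list(reaction("R1", c(A = -1, B = 1))),
                               model_condition(biomass = "Z"),
                               metabolites = c("A", "B")),
               "absent from the model")
  # ids are case-sensitive: 'a' and 'A' are distinct metabolites
  m <- metabolic_model(list(reaction("R1", c(a = -1, A = 1))),
                       model_condition())
  expect_setequal(m$metabolites, c("a", "A"))
})

test_that("TSV reaction tables round-trip all modeled fields", {
  m <- metabolic_model(
    list(reaction("R1", c(A = -1, B = 1), "L2R"),
         reaction("R2", c(B = -2, C = 1), "REVERSIBLE",
                  in_taxonomic_range = FALSE),
         reaction("R3", c(C = -1, D = 0.5), "R2L", is_polymerization = TRUE,
                  gene_associated = TRUE)),
    model_condition(nutrients = c(A = 10), secretions = "D", biomass = "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path, "tsv")
  m2 <- read_model(path, "tsv", condition = m$condition)
  expect_setequal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    expect_true(reaction_fields_equal(m$reactions[[id]], m2$reactions[[id]]))
  }
})

test_that("SBML round-trips all modeled fields, including awkward ids", {
  m <- metabolic_model(
    list(reaction("RXN-1381", c(`PALMITYL-COA` = -1, `GLYCEROL-3P` = -1,
                                `1-PALMITOYLGLYCEROL-3P` = 1, `CO-A` = 1),
                  "L2R"),
         reaction("R2", c(`GLYCEROL-3P` = -1, X = 1), "REVERSIBLE",
                  in_taxonomic_range = FALSE, gene_associated = TRUE)),
    model_condition())
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path, "sbml")
  m2 <- read_model(path, "sbml")
  expect_setequal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    expect_true(reaction_fields_equal(m$reactions[[id]], m2$reactions[[id]]))
  }
  # a reversible reaction must carry a negative lower flux bound
  txt <- paste(readLines(path), collapse = "\n")
  expect_match(txt, "bound_lower")
})

test_that("a reaction row without direction becomes REVERSIBLE with one warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tdirection\tin_taxon\tis_polymer\tgene_assoc",
               "RX\tA -> B\t\ttrue\tfalse\tfalse"), path)
  expect_warning(rxns <- read_reaction_table(path), "no explicit direction")
  expect_identical(rxns$RX$direction, "REVERSIBLE")
})

test_that("parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tdirection\tin_taxon\tis_polymer\tgene_assoc",
               "RX\tA = B\tL2R\ttrue\tfalse\tfalse"), path)
  expect_error(read_reaction_table(path), "line 2")
  writeLines(c("id\tequation\tdirection\tin_taxon\tis_polymer\tgene_assoc",
               "RX\tA -> B\tSIDEWAYS\ttrue\tfalse\tfalse"), path)
  expect_error(read_reaction_table(path), "unknown direction")
})

test_that("condition files round-trip and reject stray entries", {
  cond <- model_condition(nutrients = c(GLC = 10, AMMONIUM = 5),
                          secretions = c("CO2", "ACETATE"),
                          biomass = c(ATP = 2, TRP = 1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_condition(cond, path)
  expect_identical(read_condition(path), cond)
  writeLines("GLC 10", path)
  expect_error(read_condition(path), "before any section")
})

test_that("empty model writes a valid zero-reaction file", {
  m <- metabolic_model(list(), model_condition())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path, "tsv")
  expect_length(read_reaction_table(path), 0L)
})

test_that("toy3 stoichiometric matrix has the expected columns", {
  mat <- build_matrix(toy3_model())
  expect_identical(dim(mat$S), c(3L, 3L))
  expect_setequal(colnames(mat$S), c("R1_fwd", "EX_A", "DM_biomass"))
  expect_equal(mat$cols$ub[mat$cols$col == "EX_A"], 10)
})

test_that("reversible reactions split into negated column pairs", {
  m <- metabolic_model(list(reaction("R1", c(A = -1, B = 2), "REVERSIBLE")),
                       model_condition(nutrients = c(A = 10), biomass = "B"))
  mat <- build_matrix(m)
  expect_true(all(c("R1_fwd", "R1_bwd") %in% colnames(mat$S)))
  expect_equal(as.numeric(mat$S[, "R1_fwd"]), -as.numeric(mat$S[, "R1_bwd"]))
  expect_equal(as.numeric(mat$S[c("A", "B"), "R1_fwd"]), c(-1, 2))
})

test_that("matrix column count follows the splitting rule", {
  for (seed in 1:5) {
    p <- synth_params(n_metabolites = 12, n_backbone_reactions = 10,
                      n_branch_reactions = 4, n_biomass = 2, n_nutrients = 2,
                      reversible_fraction = 0.4, seed = seed)
    m <- generate_truth(p)
    n_rev <- sum(vapply(m$reactions, function(r) r$direction == "REVERSIBLE",
                        logical(1)))
    n_irrev <- length(m$reactions) - n_rev
    n_exchange <- length(m$condition$nutrients) +
      length(m$condition$secretions) + 1L
    mat <- build_matrix(m)
    expect_identical(ncol(mat$S), n_irrev + 2L * n_rev + n_exchange)
    # internal columns carry the reaction stoichiometry exactly
    for (id in names(m$reactions)[1:3]) {
      st <- m$reactions[[id]]$stoichiometry
      col <- paste0(id, if (m$reactions[[id]]$direction == "R2L") "_bwd" else "_fwd")
      sgn <- if (m$reactions[[id]]$direction == "R2L") -1 else 1
      expect_equal(as.numeric(mat$S[names(st), col]), sgn * unname(st))
    }
  }
})

test_that("a model without nutrients yields no uptake columns", {
  m <- metabolic_model(list(reaction("R1", c(A = -1, B = 1), "L2R")),
                       model_condition(biomass = "B"))
  mat <- build_matrix(m)
  expect_false(any(mat$cols$type == "uptake"))
  expect_equal(solve_fba(m)$objective_value, 0)
})
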