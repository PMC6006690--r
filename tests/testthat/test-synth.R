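test_that("generated truth networks have the requested shape and grow", {
  p <- synth_params(n_metabolites = 20, n_backbone_reactions = 18,
                    n_branch_reactions = 6, n_biomass = 3, n_nutrients = 2,
                    seed = 7)
  m <- generate_truth(p)
  expect_length(m$reactions, 24L)
  expect_length(m$metabolites, 20L)
  expect_length(m$condition$biomass, 3L)
  expect_true(grows(m))
  expect_identical(generate_truth(p), m)  # determinism
})

test_that("a pure chain attains the nutrient uptake bound", {
  p <- synth_params(n_metabolites = 6, n_backbone_reactions = 5,
                    n_branch_reactions = 0, n_biomass = 1, n_nutrients = 1,
                    reversible_fraction = 0, seed = 3)
  m <- generate_truth(p)
  expect_equal(solve_fba(m)$objective_value, 10)
})

test_that("parameter invariants are validated", {
  expect_error(synth_params(n_backbone_reactions = 10), "must equal")
  expect_error(synth_params(n_biomass = 0), "n_biomass")
  expect_error(synth_params(n_metabolites = 4, n_backbone_reactions = 2,
                            n_nutrients = 2, n_biomass = 3),
               "exceeds")
})

test_that("benchmarks delete essential reactions and stay recoverable", {
  bm <- test_benchmark(1, n_delete = 1, n_decoys = 4)
  expect_true(grows(bm$truth))
  expect_false(grows(bm$gapped))
  expect_true(all(bm$deleted %in% names(bm$database)))
  expect_length(setdiff(names(bm$gapped$reactions),
                        names(bm$truth$reactions)), 0L)
  # with no decoys the database is exactly the deleted set
  bm0 <- test_benchmark(2, n_delete = 1, n_decoys = 0)
  expect_setequal(names(bm0$database), bm0$deleted)
  # re-adding the deleted reactions restores growth at no more than their cost
  cfg <- gapfill_config()
  sol <- gapfill(bm$gapped, bm$database, cfg)
  del_cost <- sum(vapply(bm$database[bm$deleted], function(r)
    if (r$in_taxonomic_range) cfg$w_insert_in_taxon else cfg$w_insert_out_taxon,
    0))
  expect_lte(sol$total_cost, del_cost)
  expect_true(sol$growth_recheck)
})

test_that("decoys are disconnected and never enter optimal solutions", {
  for (i in 1:6) {
    bm <- test_benchmark(i, n_delete = 1, n_decoys = 5)
    decoy_ids <- grep("^D[0-9]", names(bm$database), value = TRUE)
    expect_length(decoy_ids, 5L)
    sol <- gapfill(bm$gapped, bm$database, gapfill_config())
    expect_length(intersect(sol$added, decoy_ids), 0L)
  }
})

test_that("benchmark generation is deterministic in its seed", {
  a <- test_benchmark(5, n_delete = 2, n_decoys = 4, n_redundant = 1)
  b <- test_benchmark(5, n_delete = 2, n_decoys = 4, n_redundant = 1)
  expect_identical(names(a$database), names(b$database))
  expect_identical(a$deleted, b$deleted)
  expect_identical(a$redundant, b$redundant)
})

test_that("planted redundant reactions are duplicates removable without cost", {
  bm <- test_benchmark(4, n_delete = 1, n_decoys = 2, n_redundant = 2)
  expect_length(bm$redundant, 2L)
  expect_setequal(bm$padded_solution, c(bm$deleted, bm$redundant))
  m <- add_reactions(bm$gapped, unname(bm$database[bm$deleted]))
  expect_true(grows(m))  # the padding is not needed for growth
})
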