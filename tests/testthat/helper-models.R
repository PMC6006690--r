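# Small fixture networks built in code, shared across test files.

# three metabolites, one reaction A -> B; biomass Z is unreachable until a
# candidate closes the gap
toy3_model <- function() {
  metabolic_model(list(reaction("R1", c(A = -1, B = 1), "L2R")),
                  model_condition(nutrients = c(A = 10), biomass = "Z"),
                  metabolites = c("A", "B", "Z"))
}

toy3_db <- function() {
  list(reaction("C1", c(B = -1, Z = 1), "L2R"),
       reaction("C2", c(A = -1, Z = 1), "L2R", in_taxonomic_range = FALSE),
       reaction("C3", c(Z = -1, B = 1), "L2R"))
}

# A -> B + W, B -> Z, W -> B: the W-recycling reaction doubles the yield of Z
recycling_model <- function() {
  metabolic_model(list(reaction("R1", c(A = -1, B = 1, W = 1), "L2R"),
                       reaction("R2", c(B = -1, Z = 1), "L2R"),
                       reaction("R3", c(W = -1, B = 1), "L2R")),
                  model_condition(nutrients = c(A = 10), secretions = "W",
                                  biomass = "Z"))
}

no_recycling_model <- function() {
  m <- recycling_model()
  metabolic_model(m$reactions[c("R1", "R2")], m$condition,
                  metabolites = m$metabolites)
}

# Deterministic benchmark factory: scans seeds (derived from i) until the
# generated truth has enough essential reactions for the requested deletion.
test_benchmark <- function(i, n_delete = 1L, n_decoys = 4L, n_redundant = 0L,
                           n_metabolites = 10L, n_branch = 3L,
                           reversible_fraction = 0.2) {
  seed <- 1000L + i
  repeat {
    p <- synth_params(n_metabolites = n_metabolites,
                      n_backbone_reactions = n_metabolites - 2L,
                      n_branch_reactions = n_branch,
                      n_biomass = 2L, n_nutrients = 2L,
                      reversible_fraction = reversible_fraction, seed = seed)
    truth <- generate_truth(p)
    bm <- tryCatch(make_benchmark(truth, n_delete = n_delete,
                                  n_decoys = n_decoys, seed = seed + 7L,
                                  n_redundant = n_redundant),
                   error = function(e) NULL)
    if (!is.null(bm)) return(bm)
    seed <- seed + 100000L
  }
}

reaction_fields_equal <- function(a, b) {
  ord <- function(s) s[sort(names(s))]
  isTRUE(all.equal(ord(a$stoichiometry), ord(b$stoichiometry))) &&
    identical(a$direction, b$direction) &&
    identical(a$in_taxonomic_range, b$in_taxonomic_range) &&
    identical(a$is_polymerization, b$is_polymerization) &&
    identical(a$gene_associated, b$gene_associated)
}
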