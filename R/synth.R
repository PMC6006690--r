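# Synthetic benchmark generator. Ground-truth networks are nutrient-rooted
# directed pathway trees reaching every biomass metabolite, optionally with
# redundant branch reactions; gapped variants delete known essential
# reactions; candidate databases contain the deleted reactions plus
# mass-balanced decoys. This stands in for a curated reference reaction
# database plus an organism network in recovery experiments.

#' Parameters for synthetic ground-truth networks
#'
#' @param n_metabolites Total metabolite count.
#' @param n_backbone_reactions Number of backbone (pathway-tree) reactions;
#'   must equal `n_metabolites - n_nutrients`, one producing reaction per
#'   non-nutrient metabolite.
#' @param n_branch_reactions Extra redundant reactions between existing
#'   metabolites.
#' @param n_biomass Number of biomass metabolites (>= 1).
#' @param n_nutrients Number of nutrient metabolites (>= 1), each with the
#'   default uptake bound of 10 flux units.
#' @param reversible_fraction Fraction of reactions made reversible.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_metabolites = 20L, n_backbone_reactions = 18L,
                         n_branch_reactions = 6L, n_biomass = 3L,
                         n_nutrients = 2L, reversible_fraction = 0.2,
                         seed = 1L) {
  stopifnot(n_biomass >= 1, n_nutrients >= 1, n_metabolites > 0,
            n_backbone_reactions > 0, n_branch_reactions >= 0,
            reversible_fraction >= 0, reversible_fraction <= 1)
  if (n_backbone_reactions != n_metabolites - n_nutrients) {
    stop("n_backbone_reactions must equal n_metabolites - n_nutrients ",
         "(one producing reaction per non-nutrient metabolite)")
  }
  if (n_biomass > n_metabolites - n_nutrients) {
    stop("n_biomass exceeds the number of non-nutrient metabolites")
  }
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_backbone_reactions = as.integer(n_backbone_reactions),
                 n_branch_reactions = as.integer(n_branch_reactions),
                 n_biomass = as.integer(n_biomass),
                 n_nutrients = as.integer(n_nutrients),
                 reversible_fraction = reversible_fraction,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a ground-truth growing network
#'
#' Builds a deterministic (seeded) network: the first `n_nutrients`
#' metabolites are nutrients; every other metabolite gets one backbone
#' reaction producing it from a randomly chosen earlier metabolite, so each
#' is reachable from a nutrient; branch reactions add redundancy; biomass
#' metabolites are drawn from the most downstream metabolites. Growth is
#' guaranteed by construction and verified by FBA before return.
#'
#' @param params A [synth_params()].
#' @return A `metabolic_model` that grows.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  mets <- sprintf("M%03d", seq_len(p$n_metabolites))
  nutrients <- mets[seq_len(p$n_nutrients)]
  with_seed(p$seed, {
    rxns <- list()
    for (i in (p$n_nutrients + 1L):p$n_metabolites) {
      parent <- mets[if (i == 2L) 1L else sample.int(i - 1L, 1L)]
      dir <- if (stats::runif(1) < p$reversible_fraction) "REVERSIBLE" else "L2R"
      id <- sprintf("R%03d", length(rxns) + 1L)
      rxns[[id]] <- reaction(id, stats::setNames(c(-1, 1), c(parent, mets[i])),
                             direction = dir, gene_associated = TRUE)
    }
    for (k in seq_len(p$n_branch_reactions)) {
      pair <- sort(sample.int(p$n_metabolites, 2L))
      dir <- if (stats::runif(1) < p$reversible_fraction) "REVERSIBLE" else "L2R"
      id <- sprintf("B%03d", k)
      rxns[[id]] <- reaction(id,
                             stats::setNames(c(-1, 1), mets[pair]),
                             direction = dir, gene_associated = TRUE)
    }
    non_nutrient <- mets[-seq_len(p$n_nutrients)]
    biomass <- sample(utils::tail(non_nutrient,
                                  max(p$n_biomass, length(non_nutrient) %/% 2L)),
                      p$n_biomass)
    cond <- model_condition(nutrients = stats::setNames(rep(10, p$n_nutrients),
                                                        nutrients),
                            biomass = sort(biomass))
    model <- metabolic_model(unname(rxns), cond, metabolites = mets)
    if (!grows(model)) stop("internal error: generated truth network does not grow")
    model
  })
}

essential_reactions <- function(model, threshold = 1e-3) {
  ids <- names(model$reactions)
  ids[vapply(ids, function(id) {
    m <- model
    m$reactions[[id]] <- NULL
    !grows(m, threshold)
  }, logical(1))]
}

#' Construct a gapped benchmark with known answer
#'
#' Deletes seeded-random essential reactions from a growing ground-truth
#' network (essentiality established by single-deletion FBA, so the gapped
#' variant provably fails to grow) and assembles a candidate database
#' containing the deleted reactions plus mass-balanced decoys. Decoys act on
#' fresh metabolites disconnected from the biomass-reachable network, so they
#' can never enable growth; a seeded fraction of them is flagged
#' out-of-taxonomic-range. Optionally plants known-redundant reactions
#' (duplicates, under fresh ids, of reactions still present in the gapped
#' model) for minimality-verification experiments.
#'
#' @param truth A growing `metabolic_model` (e.g. from [generate_truth()]).
#' @param n_delete Number of essential reactions to delete (>= 1).
#' @param n_decoys Number of decoy candidates.
#' @param decoy_out_taxon_fraction Fraction of decoys flagged outside the
#'   taxonomic range (default 0.5).
#' @param seed Integer seed.
#' @param n_redundant Number of redundant reactions planted into
#'   `padded_solution` (default 0).
#' @return An object of class `gapfill_benchmark`: `truth`, `gapped`,
#'   `deleted` (ids), `database` (named list of `reaction_spec`, shuffled),
#'   `redundant` (planted redundant ids), `padded_solution`
#'   (`deleted` plus `redundant`).
#' @export
make_benchmark <- function(truth, n_delete = 1L, n_decoys = 4L,
                           decoy_out_taxon_fraction = 0.5, seed = 1L,
                           n_redundant = 0L) {
  stopifnot(n_delete >= 1, n_decoys >= 0, n_redundant >= 0)
  if (!grows(truth)) stop("truth model does not grow")
  ess <- essential_reactions(truth)
  if (length(ess) < n_delete) {
    stop("truth has only ", length(ess), " essential reaction(s); cannot delete ",
         n_delete)
  }
  with_seed(seed, {
    deleted <- sort(sample(ess, n_delete))
    gapped <- truth
    for (id in deleted) gapped$reactions[[id]] <- NULL
    # deleting reactions may orphan metabolites; keep the metabolite set
    gapped <- metabolic_model(unname(gapped$reactions), truth$condition,
                              metabolites = truth$metabolites)

    # deleted reactions enter the database under their own ids (they are no
    # longer in the gapped model, so ids stay disjoint)
    database <- lapply(deleted, function(id) truth$reactions[[id]])
    if (n_decoys > 0) {
      out_taxon <- seq_len(n_decoys) %in%
        sample.int(n_decoys, round(decoy_out_taxon_fraction * n_decoys))
      for (k in seq_len(n_decoys)) {
        st <- stats::setNames(c(-1, 1), sprintf("X%03d", c(2L * k - 1L, 2L * k)))
        database[[length(database) + 1L]] <-
          reaction(sprintf("D%03d", k), st, direction = "L2R",
                   in_taxonomic_range = !out_taxon[k])
      }
    }
    redundant <- character(0)
    if (n_redundant > 0) {
      pool <- names(gapped$reactions)
      picks <- sample(pool, n_redundant)
      for (k in seq_len(n_redundant)) {
        r <- gapped$reactions[[picks[k]]]
        r$id <- sprintf("%s_dup%d", picks[k], k)
        database[[length(database) + 1L]] <- r
        redundant <- c(redundant, r$id)
      }
    }
    database <- database[sample.int(length(database))]
    names(database) <- vapply(database, `[[`, "", "id")

    structure(list(truth = truth, gapped = gapped,
                   deleted = deleted, database = database,
                   redundant = sort(redundant),
                   padded_solution = sort(c(deleted, redundant))),
              class = "gapfill_benchmark")
  })
}

#' @export
print.gapfill_benchmark <- function(x, ...) {
  cat("<gapfill_benchmark> ", length(x$deleted), " deleted reaction(s), ",
      length(x$database), " database candidate(s)",
      if (length(x$redundant)) paste0(", ", length(x$redundant),
                                      " planted redundant"),
      "\n", sep = "")
  invisible(x)
}
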