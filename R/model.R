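#' @keywords internal
"_PACKAGE"

DIRECTIONS <- c("L2R", "R2L", "REVERSIBLE")

# Exchange/demand reactions live in a reserved id namespace; they are generated
# from the model condition, never read from reaction tables.
EXCHANGE_PREFIX_RE <- "^(EX_|SEC_|DM_)"

is_exchange_id <- function(id) grepl(EXCHANGE_PREFIX_RE, id)

#' Define a metabolic reaction
#'
#' A reaction is the unit of gap filling: a signed stoichiometry over
#' metabolite ids, an explicit direction, and the attributes that determine
#' its insertion cost during gap filling (taxonomic-range compatibility and
#' whether it is a polymerization/depolymerization reaction, which the gap
#' filler excludes by default).
#'
#' @param id Unique reaction identifier (case-sensitive, nonempty).
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient; negative coefficients are consumed left-to-right.
#' @param direction One of `"L2R"`, `"R2L"`, `"REVERSIBLE"`.
#' @param in_taxonomic_range Logical; is the source organism within the
#'   reaction's expected taxonomic range? Out-of-range insertions cost more.
#' @param is_polymerization Logical; polymerization/depolymerization reactions
#'   are excluded from gap filling by default.
#' @param gene_associated Logical; whether the reaction has a gene assignment.
#' @return An object of class `reaction_spec`.
#' @examples
#' reaction("R1", c(A = -1, B = 1), direction = "L2R")
#' @export
reaction <- function(id, stoichiometry, direction = "REVERSIBLE",
                     in_taxonomic_range = TRUE, is_polymerization = FALSE,
                     gene_associated = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("stoichiometry must be a named numeric vector of metabolite coefficients")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("duplicate metabolite in stoichiometry of reaction '", id, "'")
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L) {
    stop("reaction '", id, "' has empty stoichiometry")
  }
  direction <- match.arg(direction, DIRECTIONS)
  if (!is_exchange_id(id) &&
      (!any(stoichiometry < 0) || !any(stoichiometry > 0))) {
    stop("reaction '", id,
         "' must have at least one reactant and one product ",
         "(only EX_/SEC_/DM_ ids may be one-sided)")
  }
  structure(list(id = id,
                 stoichiometry = stoichiometry,
                 direction = direction,
                 in_taxonomic_range = isTRUE(in_taxonomic_range),
                 is_polymerization = isTRUE(is_polymerization),
                 gene_associated = isTRUE(gene_associated)),
            class = "reaction_spec")
}

#' Growth condition of a model
#'
#' Mirrors the role of an FBA definition file: which metabolites the
#' environment supplies (nutrients, with maximum uptake rates), which the
#' cell may excrete freely (secretions), and which it must synthesize for
#' growth (biomass metabolites, collected into one lumped biomass demand).
#'
#' @param nutrients Named numeric vector of maximal uptake rates (flux units
#'   are arbitrary but consistent), or a character vector of metabolite ids
#'   (then the default uptake bound of 10 applies).
#' @param secretions Character vector of metabolite ids with unbounded export.
#' @param biomass Named numeric vector of positive biomass coefficients, or a
#'   character vector of ids (coefficients default to 1).
#' @return An object of class `model_condition`.
#' @examples
#' model_condition(nutrients = c(A = 10), biomass = "Z")
#' @export
model_condition <- function(nutrients = numeric(), secretions = character(),
                            biomass = numeric()) {
  as_named <- function(x, default, what) {
    if (is.character(x)) x <- stats::setNames(rep(default, length(x)), x)
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
      stop(what, " must be named by metabolite id")
    if (anyDuplicated(names(x))) stop("duplicate ", what, " metabolite id")
    x
  }
  nutrients <- as_named(nutrients, 10, "nutrients")
  biomass <- as_named(biomass, 1, "biomass")
  if (any(nutrients < 0)) stop("nutrient uptake bounds must be >= 0")
  if (length(biomass) && any(biomass <= 0)) stop("biomass coefficients must be > 0")
  if (anyDuplicated(secretions)) stop("duplicate secretion metabolite id")
  structure(list(nutrients = nutrients,
                 secretions = as.character(secretions),
                 biomass = biomass),
            class = "model_condition")
}

#' Assemble a metabolic model
#'
#' @param reactions List of [reaction()] objects (unique ids).
#' @param condition A [model_condition()].
#' @param metabolites Optional character vector of metabolite ids; defaults to
#'   every id referenced by the reactions or the condition. Supplying extra
#'   ids is allowed (orphan metabolites); missing referenced ids is an error.
#' @return An object of class `metabolic_model`.
#' @examples
#' m <- metabolic_model(list(reaction("R1", c(A = -1, B = 1), "L2R")),
#'                      model_condition(nutrients = c(A = 10), biomass = "B"))
#' @export
metabolic_model <- function(reactions, condition = model_condition(),
                            metabolites = NULL) {
  if (inherits(reactions, "reaction_spec")) reactions <- list(reactions)
  stopifnot(is.list(reactions))
  for (r in reactions) {
    if (!inherits(r, "reaction_spec")) stop("all reactions must be reaction_spec objects")
  }
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reactions) <- ids
  referenced <- unique(c(unlist(lapply(reactions, function(r) names(r$stoichiometry))),
                         names(condition$nutrients), condition$secretions,
                         names(condition$biomass)))
  if (is.null(metabolites)) {
    metabolites <- referenced
  } else {
    metabolites <- as.character(metabolites)
    if (anyDuplicated(metabolites)) stop("duplicate metabolite ids")
    missing <- setdiff(referenced, metabolites)
    if (length(missing)) {
      stop("reactions/condition reference metabolites absent from the model: ",
           paste(missing, collapse = ", "))
    }
  }
  m <- structure(list(metabolites = metabolites,
                      reactions = reactions,
                      condition = condition),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique case-sensitive ids, every
#' referenced metabolite present, condition ids resolvable, explicit reaction
#' directions.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors describe any violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  if (anyDuplicated(mets)) stop("duplicate metabolite ids in model")
  for (r in model$reactions) {
    dangling <- setdiff(names(r$stoichiometry), mets)
    if (length(dangling)) {
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(dangling, collapse = ", "))
    }
    if (!r$direction %in% DIRECTIONS) stop("reaction '", r$id, "' has no explicit direction")
  }
  cond <- model$condition
  dangling <- setdiff(c(names(cond$nutrients), cond$secretions, names(cond$biomass)), mets)
  if (length(dangling)) {
    stop("condition references metabolites absent from the model: ",
         paste(dangling, collapse = ", "))
  }
  invisible(model)
}

reaction_ids <- function(model) names(model$reactions)

#' Add reactions to a model
#'
#' Returns a new model with the given reactions added (metabolite set extended
#' as needed). Used to apply a gap-filling solution.
#'
#' @param model A `metabolic_model`.
#' @param reactions A list of `reaction_spec` (or a single one).
#' @param reverse Character vector of existing reaction ids whose direction is
#'   relaxed to `REVERSIBLE` (the gap filler's costed reversal action).
#' @return The extended `metabolic_model`.
#' @export
add_reactions <- function(model, reactions = list(), reverse = character()) {
  if (inherits(reactions, "reaction_spec")) reactions <- list(reactions)
  rxns <- model$reactions
  for (r in reactions) {
    if (!inherits(r, "reaction_spec")) stop("reactions must be reaction_spec objects")
    if (r$id %in% names(rxns)) stop("reaction '", r$id, "' already in model")
    rxns[[r$id]] <- r
  }
  unknown <- setdiff(reverse, names(rxns))
  if (length(unknown)) stop("cannot reverse unknown reactions: ",
                            paste(unknown, collapse = ", "))
  for (q in reverse) rxns[[q]]$direction <- "REVERSIBLE"
  mets <- unique(c(model$metabolites,
                   unlist(lapply(reactions, function(r) names(r$stoichiometry)))))
  metabolic_model(unname(rxns), model$condition, metabolites = mets)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cond <- x$condition
  cat("<metabolic_model> ", length(x$reactions), " reactions, ",
      length(x$metabolites), " metabolites\n", sep = "")
  cat("  nutrients: ", paste(names(cond$nutrients), collapse = ", "), "\n", sep = "")
  cat("  secretions: ", paste(cond$secretions, collapse = ", "), "\n", sep = "")
  cat("  biomass:   ", length(cond$biomass), " metabolite(s)\n", sep = "")
  invisible(x)
}

#' @export
print.reaction_spec <- function(x, ...) {
  st <- x$stoichiometry
  side <- function(s) paste(ifelse(abs(s) == 1, names(s),
                                   paste(abs(s), names(s))), collapse = " + ")
  arrow <- switch(x$direction, L2R = "->", R2L = "<-", REVERSIBLE = "<->")
  cat(x$id, ": ", side(st[st < 0]), " ", arrow, " ", side(st[st > 0]), "\n", sep = "")
  invisible(x)
}
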