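#' Score a predicted reaction set against a reference set
#'
#' Computes true positives, false positives, false negatives, recall
#' `tp / (tp + fn)` and precision `tp / (tp + fp)` between a predicted
#' gap-filling solution and a reference (e.g. manually curated) solution.
#' Identifier comparison is exact-match: near-equivalent reactions under
#' distinct ids (such as a CoA-specific versus an acyl-carrier-protein
#' variant of the same transformation) count as one false positive plus one
#' false negative. Inputs are treated as sets (order and duplicates are
#' ignored).
#'
#' @param predicted Character vector of predicted reaction ids (nonempty).
#' @param reference Character vector of reference reaction ids (nonempty).
#' @return An object of class `gapfill_eval`: `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `shared`, `predicted_only`, `reference_only`.
#' @examples
#' ev <- evaluate_solution(c("R1", "R2", "R3"), c("R2", "R3", "R4", "R5"))
#' ev$recall     # 0.5
#' ev$precision  # 2/3
#' @export
evaluate_solution <- function(predicted, reference) {
  predicted <- unique(as.character(predicted))
  reference <- unique(as.character(reference))
  if (!length(predicted)) stop("predicted set is empty")
  if (!length(reference)) stop("reference set is empty")
  shared <- sort(intersect(predicted, reference))
  predicted_only <- sort(setdiff(predicted, reference))
  reference_only <- sort(setdiff(reference, predicted))
  tp <- length(shared); fp <- length(predicted_only); fn <- length(reference_only)
  structure(list(tp = tp, fp = fp, fn = fn,
                 recall = tp / (tp + fn),
                 precision = tp / (tp + fp),
                 shared = shared,
                 predicted_only = predicted_only,
                 reference_only = reference_only),
            class = "gapfill_eval")
}

#' @export
print.gapfill_eval <- function(x, ...) {
  cat("<gapfill_eval> tp = ", x$tp, ", fp = ", x$fp, ", fn = ", x$fn, "\n",
      sep = "")
  cat(sprintf("  recall    = %.1f%%\n", 100 * x$recall))
  cat(sprintf("  precision = %.1f%%\n", 100 * x$precision))
  invisible(x)
}

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "gapfillr")
  if (!nzchar(path)) stop("packaged fixture '", file, "' not found")
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' Load the packaged B. longum reference tables
#'
#' Returns the published reference data from a gap-filling comparison on a
#' Bifidobacterium longum subsp. longum JCM 1217 model: the 53-entry biomass
#' metabolite list with pre-gap-fill producibility flags, the automated
#' (12 reactions, 2 of them flagged as excess) and manual (13 reactions)
#' gap-filling solutions, and the 28 reactions whose directionality was
#' manually curated during model development.
#'
#' @return An object of class `reference_fixtures`: `biomass_metabolites`
#'   (data frame: `name`, `biocyc_id`, `producible_pre_gapfill`),
#'   `automated_set` and `manual_set` (character vectors of reaction ids),
#'   `starred` (the automated reactions later shown unnecessary for growth),
#'   `solutions` (the underlying data frame), and `curated_directions`
#'   (data frame: `reaction_id`, `metabolic_goal`, `curated_direction`).
#' @examples
#' fx <- load_fixtures()
#' length(fx$automated_set)  # 12
#' length(fx$manual_set)     # 13
#' @export
load_fixtures <- function() {
  biomass <- read_fixture("blongum_biomass_metabolites.tsv")
  biomass$producible_pre_gapfill <- biomass$producible_pre_gapfill == "true"
  sols <- read_fixture("blongum_gapfill_solutions.tsv")
  sols$starred <- sols$starred == "true"
  dirs <- read_fixture("blongum_curated_directions.tsv")
  if (nrow(biomass) != 53L || nrow(sols) != 17L || nrow(dirs) != 28L) {
    stop("packaged fixture integrity check failed")
  }
  structure(list(biomass_metabolites = biomass,
                 automated_set = sols$reaction_id[grepl("A", sols$added_by)],
                 manual_set = sols$reaction_id[grepl("M", sols$added_by)],
                 starred = sols$reaction_id[sols$starred],
                 solutions = sols,
                 curated_directions = dirs),
            class = "reference_fixtures")
}

#' @export
print.reference_fixtures <- function(x, ...) {
  cat("<reference_fixtures>\n")
  cat("  biomass metabolites: ", nrow(x$biomass_metabolites), " (",
      sum(x$biomass_metabolites$producible_pre_gapfill),
      " producible pre gap fill)\n", sep = "")
  cat("  automated solution:  ", length(x$automated_set), " reactions (",
      length(x$starred), " starred excess)\n", sep = "")
  cat("  manual solution:     ", length(x$manual_set), " reactions\n", sep = "")
  cat("  curated directions:  ", nrow(x$curated_directions), " reactions\n",
      sep = "")
  invisible(x)
}
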