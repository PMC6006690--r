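#' Build the split stoichiometric matrix of a model
#'
#' Constructs the steady-state matrix S with one column per irreversible
#' reaction, two columns (forward/backward, both carrying nonnegative flux)
#' per reversible reaction, one uptake column per nutrient (bounded by its
#' maximal uptake rate), one export column per secretion, and one biomass
#' demand column consuming the biomass metabolites in their coefficients.
#'
#' Column naming: `<id>_fwd` (left-to-right), `<id>_bwd` (right-to-left,
#' entrywise negation of the forward column), `EX_<met>` (uptake),
#' `SEC_<met>` (export), `DM_biomass`.
#'
#' @param model A `metabolic_model`.
#' @return An object of class `stoich_matrix`: list with `S` (sparse
#'   [Matrix::sparseMatrix()] with metabolite rows and named columns) and
#'   `cols` (data frame: `col`, `rxn`, `type`, `ub`).
#' @export
build_matrix <- function(model) {
  validate_model(model)
  mets <- model$metabolites
  met_idx <- stats::setNames(seq_along(mets), mets)
  cond <- model$condition

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  col_id <- character(0); col_rxn <- character(0)
  col_type <- character(0); col_ub <- numeric(0)
  j <- 0L
  push <- function(id, rxn, type, ub, stoich) {
    j <<- j + 1L
    ii <<- c(ii, met_idx[names(stoich)])
    jj <<- c(jj, rep.int(j, length(stoich)))
    xx <<- c(xx, unname(stoich))
    col_id <<- c(col_id, id)
    col_rxn <<- c(col_rxn, rxn)
    col_type <<- c(col_type, type)
    col_ub <<- c(col_ub, ub)
  }

  for (r in model$reactions) {
    st <- r$stoichiometry
    if (r$direction %in% c("L2R", "REVERSIBLE")) {
      push(paste0(r$id, "_fwd"), r$id, "fwd", Inf, st)
    }
    if (r$direction %in% c("R2L", "REVERSIBLE")) {
      push(paste0(r$id, "_bwd"), r$id, "bwd", Inf, -st)
    }
  }
  for (k in seq_along(cond$nutrients)) {
    met <- names(cond$nutrients)[k]
    push(paste0("EX_", met), NA_character_, "uptake",
         unname(cond$nutrients[k]), stats::setNames(1, met))
  }
  for (met in cond$secretions) {
    push(paste0("SEC_", met), NA_character_, "secretion", Inf,
         stats::setNames(-1, met))
  }
  if (length(cond$biomass)) {
    push("DM_biomass", NA_character_, "demand", Inf, -cond$biomass)
  }

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), j),
                            dimnames = list(mets, col_id))
  structure(list(S = S,
                 cols = data.frame(col = col_id, rxn = col_rxn,
                                   type = col_type, ub = col_ub,
                                   stringsAsFactors = FALSE)),
            class = "stoich_matrix")
}

#' @export
print.stoich_matrix <- function(x, ...) {
  cat("<stoich_matrix> ", nrow(x$S), " metabolites x ", ncol(x$S),
      " flux columns\n", sep = "")
  invisible(x)
}
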