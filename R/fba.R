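# Flux balance analysis on the split stoichiometric system: maximize the
# biomass demand flux subject to S v = 0, 0 <= v, and the finite upper bounds
# (nutrient uptake limits). Net fluxes are reported per reaction (fwd - bwd).

fba_lp <- function(mat, objective_col) {
  S <- as.matrix(mat$S)
  n <- ncol(S)
  ub <- mat$cols$ub
  fin <- which(is.finite(ub))
  A <- S
  sense <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  if (length(fin)) {
    Ub <- matrix(0, length(fin), n)
    Ub[cbind(seq_along(fin), fin)] <- 1
    A <- rbind(A, Ub)
    sense <- c(sense, rep("<=", length(fin)))
    rhs <- c(rhs, ub[fin])
  }
  obj <- numeric(n)
  obj[match(objective_col, mat$cols$col)] <- 1
  list(obj = obj, A = A, sense = sense, rhs = rhs)
}

net_fluxes <- function(mat, v) {
  cols <- mat$cols
  out <- numeric(0)
  rxns <- unique(cols$rxn[!is.na(cols$rxn)])
  for (rx in rxns) {
    f <- sum(v[cols$rxn %in% rx & cols$type == "fwd"])
    b <- sum(v[cols$rxn %in% rx & cols$type == "bwd"])
    out[rx] <- f - b
  }
  ex <- which(is.na(cols$rxn))
  out[cols$col[ex]] <- v[ex]
  out
}

#' Flux balance analysis: maximize biomass production
#'
#' Solves the steady-state LP maximizing the flux of the lumped biomass
#' demand reaction. The solution is checked against the mass-balance
#' tolerance before it is returned.
#'
#' @param model A `metabolic_model` with a nonempty biomass definition.
#' @param eps_mass Mass-balance tolerance on `|S v|` (default `1e-6`).
#' @return An object of class `fba_fit`: `fluxes` (named net fluxes per
#'   reaction, plus exchange columns), `objective_value` (biomass demand
#'   flux), `status` (`"optimal"`, `"infeasible"`, `"unbounded"`).
#' @examples
#' m <- metabolic_model(list(reaction("R1", c(A = -1, B = 1), "L2R")),
#'                      model_condition(nutrients = c(A = 10), biomass = "B"))
#' solve_fba(m)$objective_value  # 10: throughput limited by uptake
#' @export
solve_fba <- function(model, eps_mass = 1e-6) {
  if (!length(model$condition$biomass)) {
    stop("model condition defines no biomass metabolites")
  }
  mat <- build_matrix(model)
  lp <- fba_lp(mat, "DM_biomass")
  res <- lp_solve(lp$obj, lp$A, lp$sense, lp$rhs, maximize = TRUE)
  if (res$status != "optimal") {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          status = res$status, model = model),
                     class = "fba_fit"))
  }
  resid <- max(abs(as.vector(mat$S %*% res$x)))
  if (resid > eps_mass) {
    stop("FBA solution violates mass balance beyond eps_mass (residual ",
         format(resid), ")")
  }
  structure(list(fluxes = net_fluxes(mat, res$x),
                 objective_value = res$objval,
                 status = "optimal",
                 raw = stats::setNames(res$x, mat$cols$col),
                 model = model),
            class = "fba_fit")
}

#' @export
print.fba_fit <- function(x, ...) {
  cat("<fba_fit> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat(", biomass flux: ", format(x$objective_value),
        " (", nz, " nonzero net fluxes)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.fba_fit <- function(object, ...) object$fluxes

#' Does the model grow?
#'
#' A model grows when its maximal biomass demand flux exceeds the activity
#' threshold (default `1e-3`, the same lower active-flux bound the gap
#' filler uses).
#'
#' @param model A `metabolic_model`.
#' @param threshold Positive flux threshold.
#' @return Logical scalar.
#' @export
grows <- function(model, threshold = 1e-3) {
  stopifnot(threshold > 0)
  fit <- solve_fba(model)
  if (fit$status == "unbounded") return(TRUE)
  if (fit$status != "optimal") return(FALSE)
  fit$objective_value > threshold
}

#' Which biomass metabolites can the model produce?
#'
#' Tests each biomass metabolite in isolation with a single-metabolite demand
#' LP and returns those whose maximal demand flux exceeds the threshold.
#' This diagnoses *which* biosynthetic routes are broken in a gapped model.
#'
#' @param model A `metabolic_model`.
#' @param threshold Positive flux threshold (default `1e-3`).
#' @return Sorted character vector of producible biomass metabolite ids.
#' @export
producible_biomass_subset <- function(model, threshold = 1e-3) {
  stopifnot(threshold > 0)
  mets <- names(model$condition$biomass)
  ok <- vapply(mets, function(met) {
    cond1 <- model$condition
    cond1$biomass <- stats::setNames(1, met)
    m1 <- model
    m1$condition <- cond1
    grows(m1, threshold)
  }, logical(1))
  sort(mets[ok])
}

#' Compare growth between two model variants
#'
#' Returns the ratio of the variant's maximal biomass flux to the reference
#' model's, i.e. the factor by which the variant grows more slowly (ratio
#' 0.5 means 50% slower). Both models must share the biomass definition.
#'
#' @param model Reference `metabolic_model`; must grow.
#' @param variant Variant `metabolic_model`.
#' @param threshold Growth threshold for the reference (default `1e-3`).
#' @return Dimensionless growth ratio; 0 when the variant does not grow.
#' @export
compare_growth <- function(model, variant, threshold = 1e-3) {
  if (!identical(sort(names(model$condition$biomass)),
                 sort(names(variant$condition$biomass)))) {
    stop("model and variant must share the same biomass definition")
  }
  ref <- solve_fba(model)
  if (ref$status != "optimal" || ref$objective_value <= threshold) {
    stop("reference model does not grow; growth ratio undefined")
  }
  var <- solve_fba(variant)
  if (var$status != "optimal" || var$objective_value <= threshold) return(0)
  var$objective_value / ref$objective_value
}
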