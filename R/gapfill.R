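#' Gap-filling configuration
#'
#' Collects the MILP parameters: the active-flux window `[B_l, B_u]` of the
#' indicator constraints `B_l * s_r <= f_r <= B_u * s_r`, the biomass growth
#' threshold, and the three action weights. The cost ordering
#' `w_reverse < w_insert_in_taxon < w_insert_out_taxon` is enforced: reversing
#' an existing irreversible reaction is cheaper than inserting a database
#' reaction whose taxonomic range covers the organism, which in turn is
#' cheaper than inserting one outside that range.
#'
#' @param B_l Lower bound on the flux of any reaction considered active
#'   (default `1e-3`).
#' @param B_u Upper flux bound for candidate reactions (default `3000`).
#' @param biomass_threshold Minimum biomass flux for growth (default `1e-3`).
#'   The strict inequality "biomass flux > threshold" is realized as
#'   `>= threshold + eps_strict`.
#' @param w_reverse,w_insert_in_taxon,w_insert_out_taxon Action weights
#'   (defaults 1, 2, 4).
#' @param exclude_polymerization Drop polymerization/depolymerization
#'   candidates (default `TRUE`).
#' @param allow_reversals Offer costed reversal of existing irreversible
#'   model reactions as gap-filling actions (default `TRUE`).
#' @param seed Optional integer; when given, equal-cost ties are broken by a
#'   seeded random preference instead of the default lexicographic one. The
#'   optimal cost never depends on the seed, only the choice among equal-cost
#'   optima may.
#' @param time_limit Wall-clock limit in seconds for the selection search
#'   (default `Inf`).
#' @param eps_strict Strictness margin for the growth inequality
#'   (default `1e-9`).
#' @param tol_int Integer feasibility tolerance for [milp_solve()]
#'   (default `1e-6`).
#' @param tol_gap Cost-comparison tolerance (default `1e-6`).
#' @return An object of class `gapfill_config`.
#' @export
gapfill_config <- function(B_l = 1e-3, B_u = 3000, biomass_threshold = 1e-3,
                           w_reverse = 1, w_insert_in_taxon = 2,
                           w_insert_out_taxon = 4,
                           exclude_polymerization = TRUE,
                           allow_reversals = TRUE,
                           seed = NULL, time_limit = Inf,
                           eps_strict = 1e-9, tol_int = 1e-6,
                           tol_gap = 1e-6) {
  if (!(B_l > 0 && B_l < B_u)) stop("need 0 < B_l < B_u")
  if (!(w_reverse > 0 && w_reverse < w_insert_in_taxon &&
        w_insert_in_taxon < w_insert_out_taxon)) {
    stop("need 0 < w_reverse < w_insert_in_taxon < w_insert_out_taxon")
  }
  if (biomass_threshold <= 0) stop("biomass_threshold must be > 0")
  structure(list(B_l = B_l, B_u = B_u, biomass_threshold = biomass_threshold,
                 w_reverse = w_reverse,
                 w_insert_in_taxon = w_insert_in_taxon,
                 w_insert_out_taxon = w_insert_out_taxon,
                 exclude_polymerization = isTRUE(exclude_polymerization),
                 allow_reversals = isTRUE(allow_reversals),
                 seed = seed, time_limit = time_limit,
                 eps_strict = eps_strict, tol_int = tol_int,
                 tol_gap = tol_gap),
            class = "gapfill_config")
}

candidate_weight <- function(r, config) {
  if (r$in_taxonomic_range) config$w_insert_in_taxon else config$w_insert_out_taxon
}

as_database <- function(database) {
  if (inherits(database, "reaction_spec")) database <- list(database)
  stopifnot(is.list(database))
  ids <- vapply(database, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids in database")
  stats::setNames(database, ids)
}

usable_candidates <- function(database, config) {
  database <- as_database(database)
  if (config$exclude_polymerization) {
    database <- Filter(function(r) !r$is_polymerization, database)
  }
  database
}

reversible_actions <- function(model, config) {
  if (!config$allow_reversals) return(character(0))
  ids <- names(model$reactions)
  ids[vapply(model$reactions, function(r) r$direction != "REVERSIBLE", logical(1))]
}

# --- MILP assembly and solution -------------------------------------------
#
# The selection problem is
#   minimize    sum_r c_r s_r + w_reverse sum_q rev_q
#   subject to  S v = 0, uptake bounds, biomass flux > threshold,
#               B_l s_r <= f_r <= B_u s_r  for every action binary,
#               s_r, rev_q in {0, 1}.
# Because the binaries only gate flux capacity, the LP relaxation of the
# big-M form is nearly vacuous (s_r ~ f_r / B_u), so a textbook relaxation
# branch-and-bound enumerates blindly. gapfill() therefore solves the
# program by implicit enumeration: uniform-cost branch-and-bound over the
# action binaries where each indicator constraint is imposed exactly (an
# unselected action's flux columns are capped at zero, a selected one's at
# B_u), with two LP prunes per node: a relaxation prune (even with every
# unfixed action available the model cannot grow) and an acceptance test
# (the fixed-in set alone already grows). Popping nodes in increasing cost
# order makes the first accepted node a provably minimum-cost solution.

# One LP template over model + all action columns; availability is imposed
# through the rhs of per-column gate rows.
gapfill_lp_template <- function(model, actions, config) {
  mets <- unique(c(model$metabolites,
                   unlist(lapply(actions, function(a)
                     if (a$kind == "insert") names(a$reaction$stoichiometry)))))
  base <- model
  base$metabolites <- mets
  mat <- build_matrix(base)
  n0 <- ncol(mat$S)
  Sx <- as.matrix(mat$S)

  extra <- list(); extra_names <- character(0)
  act_cols <- vector("list", length(actions))
  add_col <- function(stoich, nm) {
    v <- numeric(length(mets))
    v[match(names(stoich), mets)] <- stoich
    extra[[length(extra) + 1L]] <<- v
    extra_names <<- c(extra_names, nm)
    length(extra)
  }
  for (k in seq_along(actions)) {
    a <- actions[[k]]
    if (a$kind == "insert") {
      r <- a$reaction
      cols <- integer(0)
      if (r$direction %in% c("L2R", "REVERSIBLE")) {
        cols <- c(cols, add_col(r$stoichiometry, paste0(r$id, "_fwd")))
      }
      if (r$direction %in% c("R2L", "REVERSIBLE")) {
        cols <- c(cols, add_col(-r$stoichiometry, paste0(r$id, "_bwd")))
      }
      act_cols[[k]] <- n0 + cols
    } else {
      r <- model$reactions[[a$id]]
      st <- if (r$direction == "L2R") -r$stoichiometry else r$stoichiometry
      sfx <- if (r$direction == "L2R") "_bwd" else "_fwd"
      act_cols[[k]] <- n0 + add_col(st, paste0(r$id, sfx))
    }
  }
  n <- n0 + length(extra)
  A_mass <- cbind(Sx, if (length(extra)) do.call(cbind, extra) else NULL)

  fin <- which(is.finite(mat$cols$ub))
  A_ub <- matrix(0, length(fin), n)
  A_ub[cbind(seq_along(fin), fin)] <- 1

  gate_cols <- unlist(act_cols)
  A_gate <- matrix(0, length(gate_cols), n)
  A_gate[cbind(seq_along(gate_cols), gate_cols)] <- 1

  A <- rbind(A_mass, A_ub, A_gate)
  sense <- c(rep("=", nrow(A_mass)), rep("<=", length(fin) + length(gate_cols)))
  rhs_fixed <- c(rep(0, nrow(A_mass)), mat$cols$ub[fin])
  obj <- numeric(n)
  obj[match("DM_biomass", mat$cols$col)] <- 1

  list(A = A, sense = sense, rhs_fixed = rhs_fixed, obj = obj,
       act_cols = act_cols, gate_cols = gate_cols, n = n,
       col_names = c(mat$cols$col, extra_names))
}

# maximize biomass with the given subset of actions available
template_growth <- function(tpl, avail, config) {
  gate_rhs <- numeric(length(tpl$gate_cols))
  open_cols <- unlist(tpl$act_cols[avail])
  gate_rhs[match(open_cols, tpl$gate_cols)] <- config$B_u
  lp_solve(tpl$obj, tpl$A, tpl$sense, c(tpl$rhs_fixed, gate_rhs),
           maximize = TRUE)
}

gapfill_actions <- function(model, database, config) {
  cands <- usable_candidates(database, config)
  overlap <- intersect(names(cands), names(model$reactions))
  if (length(overlap)) {
    stop("database ids overlap model reactions: ", paste(overlap, collapse = ", "))
  }
  acts <- c(lapply(cands, function(r)
              list(id = r$id, kind = "insert", weight = candidate_weight(r, config),
                   reaction = r)),
            lapply(reversible_actions(model, config), function(q)
              list(id = q, kind = "reverse", weight = config$w_reverse,
                   reaction = NULL)))
  acts <- unname(acts)
  if (!length(acts)) return(acts)
  # deterministic lexicographic tie-break via an epsilon cost perturbation,
  # optionally randomized by seed (production MILP solvers pick among
  # equal-cost optima arbitrarily; here that behaviour is opt-in and
  # reproducible)
  ids <- vapply(acts, `[[`, "", "id")
  rank <- integer(length(acts)); rank[order(ids)] <- seq_along(acts)
  if (!is.null(config$seed)) rank <- with_seed(config$seed, sample.int(length(acts)))
  eps <- 1e-4 / length(acts)
  for (k in seq_along(acts)) acts[[k]]$pweight <- acts[[k]]$weight + eps * rank[k]
  acts
}

# Exact uniform-cost branch and bound over the action binaries.
# cuts: list of integer action-index sets that may not all be selected
# (integer cuts for enumerating alternate optima).
gapfill_search <- function(tpl, actions, config, cuts = list(),
                           time_limit = Inf) {
  nact <- length(actions)
  pw <- vapply(actions, `[[`, 0, "pweight")
  threshold <- config$biomass_threshold + config$eps_strict
  t0 <- Sys.time()
  grow_cache <- new.env(parent = emptyenv())
  growth <- function(avail) {
    key <- paste0("k", paste(which(avail), collapse = ","))
    hit <- grow_cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- template_growth(tpl, avail, config)
    grow_cache[[key]] <- res
    res
  }
  cut_banned <- function(in_set) {
    for (ct in cuts) if (all(ct %in% which(in_set))) return(TRUE)
    FALSE
  }

  # node: list(f1 = logical fixed-in, f0 = logical fixed-out, bound)
  nodes <- list(list(f1 = rep(FALSE, nact), f0 = rep(FALSE, nact), bound = 0))
  bounds <- 0
  keys <- ""
  nexplored <- 0L
  while (length(nodes)) {
    if (is.finite(time_limit) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      return(list(status = "timeout", nodes = nexplored))
    }
    k <- order(bounds, keys)[1L]
    nd <- nodes[[k]]
    nodes[[k]] <- NULL; bounds <- bounds[-k]; keys <- keys[-k]
    nexplored <- nexplored + 1L

    relax <- growth(nd$f1 | !nd$f0)
    if (relax$status != "optimal" || relax$objval < threshold) next

    if (cut_banned(nd$f1)) next  # every descendant selects the banned set too
    own <- growth(nd$f1)
    if (own$status == "optimal" && own$objval >= threshold) {
      return(list(status = "optimal", selected = which(nd$f1),
                  cost = sum(vapply(actions[nd$f1], `[[`, 0, "weight")),
                  lp = own, nodes = nexplored))
    }

    # branch on the free action carrying the most flux in the relaxation
    free <- which(!nd$f1 & !nd$f0)
    if (!length(free)) next
    load <- vapply(free, function(a) sum(relax$x[tpl$act_cols[[a]]]), 0)
    cand <- free[load > 1e-9]
    j <- if (length(cand)) cand[which.max(load[load > 1e-9])] else free[1L]

    f1 <- nd$f1; f1[j] <- TRUE
    f0 <- nd$f0; f0[j] <- TRUE
    child_in <- list(f1 = f1, f0 = nd$f0, bound = nd$bound + pw[j])
    child_out <- list(f1 = nd$f1, f0 = f0, bound = nd$bound)
    nodes <- c(nodes, list(child_in, child_out))
    bounds <- c(bounds, child_in$bound, child_out$bound)
    keys <- c(keys, paste(which(f1), collapse = ","),
              paste(which(nd$f1), collapse = ","))
  }
  list(status = "infeasible", nodes = nexplored)
}

milp_state_from_search <- function(tpl, actions, found, config) {
  ids <- vapply(actions, `[[`, "", "id")
  kind <- vapply(actions, `[[`, "", "kind")
  sel <- seq_along(actions) %in% found$selected
  activity <- vapply(seq_along(actions), function(a)
    if (sel[a]) sum(found$lp$x[tpl$act_cols[[a]]]) else 0, 0)
  ins <- kind == "insert"
  structure(list(s = stats::setNames(as.numeric(sel[ins]), ids[ins]),
                 f = stats::setNames(activity[ins], ids[ins]),
                 rev = stats::setNames(as.numeric(sel[!ins]), ids[!ins]),
                 rev_f = stats::setNames(activity[!ins], ids[!ins]),
                 solver_status = found$status,
                 objective = found$cost),
            class = "milp_state")
}

#' Gap-fill a metabolic model by minimum-cost MILP
#'
#' Selects a minimum-cost set of database reactions to add (and, optionally,
#' existing irreversible reactions to reverse) so that the model's biomass
#' flux exceeds the growth threshold. The program solved is the standard
#' indicator-constrained MILP -- one binary per action, constraints
#' `B_l * s_r <= f_r <= B_u * s_r`, steady-state mass balance over the union
#' network, minimum-cost objective -- but the binaries are searched by exact
#' uniform-cost branch-and-bound with the indicator constraints imposed
#' combinatorially (an unselected action's flux is capped at zero), which
#' avoids the numerical imprecision big-M formulations are prone to.
#' Every returned solution is re-validated by an independent growth LP on the
#' completed model and an indicator-constraint audit ([audit_solution()]).
#'
#' @param model A `metabolic_model` (typically one that does not grow).
#' @param database List of candidate `reaction_spec`s; ids must be disjoint
#'   from the model's.
#' @param config A [gapfill_config()].
#' @return An object of class `gapfill`: `added` (candidate ids),
#'   `reversed` (model reaction ids), `total_cost`, `status` (`"optimal"`,
#'   `"infeasible"`, `"timeout"`), `flux_state` (an `fba_fit` of the
#'   completed model), `audit` (a `violation_report`), `milp_state`,
#'   `action_costs`, `unproducible` (when infeasible: biomass metabolites
#'   unreachable even with the full database), and `growth_recheck`.
#' @examples
#' toy <- metabolic_model(list(reaction("R1", c(A = -1, B = 1), "L2R")),
#'                        model_condition(nutrients = c(A = 10), biomass = "Z"),
#'                        metabolites = c("A", "B", "Z"))
#' db <- list(reaction("C1", c(B = -1, Z = 1), "L2R"),
#'            reaction("C2", c(A = -1, Z = 1), "L2R",
#'                     in_taxonomic_range = FALSE))
#' sol <- gapfill(toy, db)
#' sol$added       # "C1": in-taxon insertion is cheaper
#' sol$total_cost  # 2
#' @export
gapfill <- function(model, database, config = gapfill_config()) {
  validate_model(model)
  stopifnot(inherits(config, "gapfill_config"))
  database <- as_database(database)

  if (grows(model, config$biomass_threshold)) {
    return(new_gapfill_solution(character(0), character(0), 0,
                                solve_fba(model), "optimal",
                                audit = empty_audit(), milp_state = NULL,
                                config = config))
  }

  actions <- gapfill_actions(model, database, config)
  tpl <- gapfill_lp_template(model, actions, config)
  found <- gapfill_search(tpl, actions, config,
                          time_limit = config$time_limit)

  if (found$status != "optimal") {
    unprod <- character(0)
    if (found$status == "infeasible") {
      relaxed <- add_reactions(model,
                               unname(usable_candidates(database, config)),
                               reverse = reversible_actions(model, config))
      prod <- producible_biomass_subset(relaxed, config$biomass_threshold)
      unprod <- sort(setdiff(names(model$condition$biomass), prod))
    }
    return(new_gapfill_solution(character(0), character(0), NA_real_,
                                NULL, found$status, audit = empty_audit(),
                                milp_state = NULL, config = config,
                                unproducible = unprod))
  }

  state <- milp_state_from_search(tpl, actions, found, config)
  finish_gapfill_solution(model, database, actions, found, state, config)
}

finish_gapfill_solution <- function(model, database, actions, found, state,
                                    config) {
  ids <- vapply(actions, `[[`, "", "id")
  kind <- vapply(actions, `[[`, "", "kind")
  sel <- seq_along(actions) %in% found$selected
  added <- ids[sel & kind == "insert"]
  reversed <- ids[sel & kind == "reverse"]
  weights <- vapply(actions, `[[`, 0, "weight")
  action_costs <- stats::setNames(weights[sel], ids[sel])

  cands <- usable_candidates(database, config)
  completed <- add_reactions(model, unname(cands[added]), reverse = reversed)
  fit <- solve_fba(completed)
  recheck <- fit$status == "optimal" &&
    fit$objective_value > config$biomass_threshold
  new_gapfill_solution(added, reversed, sum(action_costs), fit, "optimal",
                       audit = audit_solution(state, config),
                       milp_state = state, config = config,
                       growth_recheck = recheck, action_costs = action_costs)
}

new_gapfill_solution <- function(added, reversed, total_cost, flux_state,
                                 status, audit, milp_state, config,
                                 unproducible = character(0),
                                 growth_recheck = NA,
                                 action_costs = stats::setNames(numeric(0),
                                                                character(0))) {
  structure(list(added = sort(added), reversed = sort(reversed),
                 total_cost = total_cost, flux_state = flux_state,
                 status = status, audit = audit, milp_state = milp_state,
                 unproducible = unproducible, growth_recheck = growth_recheck,
                 action_costs = action_costs, config = config),
            class = "gapfill")
}

#' Enumerate equal-cost optimal gap-filling solutions
#'
#' A gap-filling problem often has several optima of equal cost (e.g. several
#' database reactions that each enable the same biosynthetic route at the
#' same weight); a solver then effectively picks one arbitrarily. This
#' function makes the ambiguity explicit: it re-solves with integer cuts
#' excluding each found action set until the optimal cost rises, returning
#' all optima up to `limit`.
#'
#' @inheritParams gapfill
#' @param limit Maximum number of solutions to return.
#' @return List of `gapfill` objects sharing `total_cost`, ordered
#'   lexicographically by their added-set.
#' @export
enumerate_equal_cost_solutions <- function(model, database,
                                           config = gapfill_config(),
                                           limit = 10L) {
  stopifnot(limit >= 1)
  first <- gapfill(model, database, config)
  if (first$status != "optimal" || limit == 1L ||
      (length(first$added) + length(first$reversed)) == 0L) {
    return(list(first))
  }
  best_cost <- first$total_cost
  sols <- list(first)
  database <- as_database(database)
  actions <- gapfill_actions(model, database, config)
  ids <- vapply(actions, `[[`, "", "id")
  kind <- vapply(actions, `[[`, "", "kind")
  tpl <- gapfill_lp_template(model, actions, config)
  cuts <- list(which((kind == "insert" & ids %in% first$added) |
                     (kind == "reverse" & ids %in% first$reversed)))
  while (length(sols) < limit) {
    found <- gapfill_search(tpl, actions, config, cuts = cuts,
                            time_limit = config$time_limit)
    if (found$status != "optimal") break
    if (found$cost > best_cost + config$tol_gap) break
    state <- milp_state_from_search(tpl, actions, found, config)
    sols[[length(sols) + 1L]] <-
      finish_gapfill_solution(model, database, actions, found, state, config)
    cuts[[length(cuts) + 1L]] <- found$selected
  }
  key <- vapply(sols, function(s)
    paste(c(s$added, paste0("rev:", s$reversed)), collapse = "|"), "")
  sols[order(key)]
}

#' @export
print.gapfill <- function(x, ...) {
  cat("<gapfill> status: ", x$status, "\n", sep = "")
  if (x$status %in% c("optimal", "feasible")) {
    cat("  added:    ", if (length(x$added)) paste(x$added, collapse = ", ")
        else "(none)", "\n", sep = "")
    cat("  reversed: ", if (length(x$reversed)) paste(x$reversed, collapse = ", ")
        else "(none)", "\n", sep = "")
    cat("  total cost: ", format(x$total_cost), "\n", sep = "")
    cat("  audit: ", if (x$audit$clean) "clean"
        else paste(nrow(x$audit$violations), "violation(s)"), "\n", sep = "")
  } else if (length(x$unproducible)) {
    cat("  unproducible biomass metabolites: ",
        paste(x$unproducible, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.gapfill <- function(object, ...) {
  out <- list(status = object$status,
              n_added = length(object$added),
              n_reversed = length(object$reversed),
              total_cost = object$total_cost,
              biomass_flux = if (!is.null(object$flux_state))
                object$flux_state$objective_value else NA_real_,
              audit_clean = object$audit$clean,
              growth_recheck = object$growth_recheck)
  class(out) <- "summary.gapfill"
  out
}

#' @export
print.summary.gapfill <- function(x, ...) {
  cat("Gap-filling solution (", x$status, ")\n", sep = "")
  cat("  reactions added:   ", x$n_added, "\n")
  cat("  reactions reversed:", x$n_reversed, "\n")
  cat("  total cost:        ", format(x$total_cost), "\n")
  cat("  biomass flux:      ", format(x$biomass_flux), "\n")
  cat("  audit clean:       ", x$audit_clean, "\n")
  cat("  growth re-check:   ", x$growth_recheck, "\n")
  invisible(x)
}

#' @export
coef.gapfill <- function(object, ...) object$action_costs
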