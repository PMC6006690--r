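# Post-hoc quality control for gap-filler output. MILP solvers can return
# selections whose binaries contradict the fluxes they are supposed to gate
# (numerical imprecision in indicator constraints); solutions can also be
# non-minimal. Both failure modes are checked here with independent LPs,
# never trusted from the MILP itself.

empty_audit <- function() {
  structure(list(violations = data.frame(reaction = character(0),
                                         s_value = numeric(0),
                                         f_value = numeric(0),
                                         bound = character(0),
                                         stringsAsFactors = FALSE),
                 clean = TRUE),
            class = "violation_report")
}

#' Audit indicator constraints of a MILP gap-filling state
#'
#' Checks every candidate's indicator constraint
#' `B_l * s_r <= f_r <= B_u * s_r` at the configured tolerance. A violation
#' is recorded iff `s_r = 0` while `|f_r| >= B_l` (an unselected reaction
#' carrying active flux) or `s_r = 1` while `|f_r| > B_u + tol` (flux above
#' the active upper bound). Pure function of its inputs.
#'
#' @param milp_state A `milp_state` (as embedded in a [gapfill()] result) or
#'   any list with named numeric `s` and `f` over the same candidate ids.
#' @param config A [gapfill_config()] supplying `B_l` and `B_u`.
#' @param tol Numerical tolerance on the upper-bound comparison
#'   (default `1e-9`).
#' @return An object of class `violation_report`: `violations` (data frame
#'   with columns `reaction`, `s_value`, `f_value`, `bound`) and `clean`.
#' @examples
#' cfg <- gapfill_config()
#' st <- list(s = c(C1 = 0), f = c(C1 = 5))
#' audit_solution(st, cfg)  # one lower-bound violation
#' @export
audit_solution <- function(milp_state, config, tol = 1e-9) {
  s <- milp_state$s; f <- milp_state$f
  if (is.null(s) || is.null(f)) stop("milp_state must carry 's' and 'f'")
  if (!setequal(names(s), names(f))) {
    stop("missing s or f entry for: ",
         paste(union(setdiff(names(s), names(f)),
                     setdiff(names(f), names(s))), collapse = ", "))
  }
  f <- f[names(s)]
  lower <- s < 0.5 & abs(f) >= config$B_l
  upper <- s >= 0.5 & abs(f) > config$B_u + tol
  viol <- data.frame(reaction = names(s)[lower | upper],
                     s_value = unname(s[lower | upper]),
                     f_value = unname(f[lower | upper]),
                     bound = c("lower", "upper")[1 + upper[lower | upper]],
                     stringsAsFactors = FALSE)
  structure(list(violations = viol, clean = nrow(viol) == 0L),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  if (x$clean) {
    cat("<violation_report> clean: all indicator constraints satisfied\n")
  } else {
    cat("<violation_report> ", nrow(x$violations), " violation(s):\n", sep = "")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

solution_costs <- function(solution, database, config) {
  database <- as_database(database)
  vapply(solution, function(id) {
    if (id %in% names(database)) candidate_weight(database[[id]], config)
    else config$w_reverse  # a reversal of an existing reaction
  }, 0)
}

#' Verify minimality of a gap-filling solution by iterative removal
#'
#' Greedily attempts to remove each solution reaction, in descending cost
#' order (ties broken lexicographically by id), permanently dropping any
#' reaction whose removal leaves the model growing. The result is *a*
#' minimal set -- every member is essential -- but not necessarily the
#' minimum-cost completion; greedy removal cannot distinguish the two.
#'
#' @param model The gapped `metabolic_model` (without the solution).
#' @param solution Character vector of database reaction ids whose addition
#'   makes the model grow.
#' @param database List of `reaction_spec` containing the solution reactions.
#' @param config A [gapfill_config()] (supplies costs and the threshold).
#' @return List with `minimal_set` (sorted ids, each essential) and
#'   `removed` (sorted ids dropped as redundant).
#' @export
verify_minimality <- function(model, solution, database,
                              config = gapfill_config()) {
  database <- as_database(database)
  solution <- unique(as.character(solution))
  missing <- setdiff(solution, names(database))
  if (length(missing)) {
    stop("solution ids not present in database: ", paste(missing, collapse = ", "))
  }
  completed <- add_reactions(model, unname(database[solution]))
  if (!grows(completed, config$biomass_threshold)) {
    stop("solution does not enable growth")
  }
  costs <- solution_costs(solution, database, config)
  order_ids <- solution[order(-costs, solution)]
  current <- solution
  removed <- character(0)
  for (id in order_ids) {
    trial <- setdiff(current, id)
    m <- add_reactions(model, unname(database[trial]))
    if (grows(m, config$biomass_threshold)) {
      current <- trial
      removed <- c(removed, id)
    }
  }
  list(minimal_set = sort(current), removed = sort(removed))
}

#' Brute-force minimum-cost gap filling (test oracle)
#'
#' Enumerates action subsets (database insertions plus, when the
#' configuration allows, reversals of existing irreversible reactions --
#' the same action space the MILP searches) in increasing total cost and
#' returns the first subset whose application makes the model grow. Exact by
#' construction, and therefore the independent oracle against which the MILP
#' is tested; only usable on small instances.
#'
#' @param model A `metabolic_model`.
#' @param database List of candidate `reaction_spec`s.
#' @param config A [gapfill_config()].
#' @param max_size Largest subset cardinality searched (default 6).
#' @return List with `feasible` (logical), `added` and `reversed` (character
#'   vectors), and `cost`. When no subset enables growth even with every
#'   action applied, `feasible = FALSE` and `cost = NA`.
#' @export
brute_force_min_gapfill <- function(model, database,
                                    config = gapfill_config(),
                                    max_size = 6L) {
  database <- usable_candidates(database, config)
  rev_ids <- reversible_actions(model, config)
  actions <- c(stats::setNames(rep("insert", length(database)), names(database)),
               stats::setNames(rep("reverse", length(rev_ids)), rev_ids))
  n <- length(actions)
  if (n > 20L) stop("brute-force oracle refuses > 20 actions (", n, " given)")
  costs <- c(vapply(database, candidate_weight, 0, config = config),
             stats::setNames(rep(config$w_reverse, length(rev_ids)), rev_ids))

  apply_actions <- function(idx) {
    ids <- names(actions)[idx]
    ins <- ids[actions[idx] == "insert"]
    rev <- ids[actions[idx] == "reverse"]
    add_reactions(model, unname(database[ins]), reverse = rev)
  }

  if (grows(model, config$biomass_threshold)) {
    return(list(feasible = TRUE, added = character(0),
                reversed = character(0), cost = 0))
  }

  subsets <- list(); subset_cost <- numeric(0); subset_key <- character(0)
  for (k in seq_len(min(max_size, n))) {
    combs <- utils::combn(n, k)
    for (c_i in seq_len(ncol(combs))) {
      idx <- combs[, c_i]
      subsets[[length(subsets) + 1L]] <- idx
      subset_cost <- c(subset_cost, sum(costs[idx]))
      subset_key <- c(subset_key, paste(names(actions)[idx], collapse = "|"))
    }
  }
  ord <- order(subset_cost, subset_key)
  for (k in ord) {
    idx <- subsets[[k]]
    if (grows(apply_actions(idx), config$biomass_threshold)) {
      ids <- names(actions)[idx]
      return(list(feasible = TRUE,
                  added = sort(ids[actions[idx] == "insert"]),
                  reversed = sort(ids[actions[idx] == "reverse"]),
                  cost = sum(costs[idx])))
    }
  }
  if (n && grows(apply_actions(seq_len(n)), config$biomass_threshold)) {
    stop("no enabling subset of size <= ", max_size,
         " found, but the full action set grows; increase max_size")
  }
  list(feasible = FALSE, added = character(0), reversed = character(0),
       cost = NA_real_)
}
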