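# Dense two-phase primal simplex. Problem sizes here are tiny (tens to a few
# hundred variables), so a tableau method with Bland's anti-cycling rule is
# exact enough and simple to audit -- which matters, because detecting solver
# imprecision is one of this package's jobs.

#' Solve a linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A x (sense) rhs` and
#' `x >= 0`, by a two-phase dense simplex with Bland's rule. Intended for the
#' small steady-state LPs this package constructs; upper bounds are expressed
#' as explicit rows by the callers.
#'
#' @param obj Numeric objective coefficients (length = ncol(A)).
#' @param A Dense constraint matrix.
#' @param sense Character vector per row: `"<="`, `"="`, or `">="`.
#' @param rhs Numeric right-hand sides.
#' @param maximize Logical; minimize when `FALSE`.
#' @param tol Pivot/feasibility tolerance.
#' @param max_iter Iteration cap (guards against cycling bugs).
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution), and `objval`.
#' @export
lp_solve <- function(obj, A, sense, rhs, maximize = TRUE,
                     tol = 1e-9, max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(sense) == m, length(rhs) == m,
            all(sense %in% c("<=", "=", ">=")))
  if (!maximize) {
    res <- lp_solve(-obj, A, sense, rhs, maximize = TRUE, tol = tol,
                    max_iter = max_iter)
    res$objval <- -res$objval
    return(res)
  }
  # normalize rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    sense[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[neg]]
  }
  n_le <- sum(sense == "<=")
  n_ge <- sum(sense == ">=")
  n_art <- sum(sense != "<=")
  N <- n + n_le + n_ge + n_art
  Tm <- matrix(0, m, N + 1L)
  Tm[, seq_len(n)] <- A
  Tm[, N + 1L] <- rhs
  basis <- integer(m)
  slack_j <- n
  art_j <- n + n_le + n_ge
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      slack_j <- slack_j + 1L
      Tm[i, slack_j] <- 1
      basis[i] <- slack_j
    } else if (sense[i] == ">=") {
      slack_j <- slack_j + 1L
      Tm[i, slack_j] <- -1
      art_j <- art_j + 1L
      Tm[i, art_j] <- 1
      basis[i] <- art_j
      art_cols <- c(art_cols, art_j)
    } else {
      art_j <- art_j + 1L
      Tm[i, art_j] <- 1
      basis[i] <- art_j
      art_cols <- c(art_cols, art_j)
    }
  }

  run <- function(Tm, basis, cost, allowed) {
    # maximize cost over current system; allowed = columns eligible to enter
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached")
      cb <- cost[basis]
      red <- as.vector(crossprod(Tm[, allowed, drop = FALSE], cb)) - cost[allowed]
      ent_k <- which(red < -tol)
      if (!length(ent_k)) return(list(Tm = Tm, basis = basis, status = "optimal"))
      j <- allowed[ent_k[1L]]            # Bland: smallest eligible index
      col <- Tm[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tm = Tm, basis = basis, status = "unbounded"))
      ratio <- Tm[pos, ncol(Tm)] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]  # Bland tie-break on leaving variable
      piv <- Tm[r, j]
      Tm[r, ] <- Tm[r, ] / piv
      other <- setdiff(seq_len(nrow(Tm)), r)
      f <- Tm[other, j]
      nz <- which(abs(f) > 0)
      if (length(nz)) {
        Tm[other[nz], ] <- Tm[other[nz], , drop = FALSE] -
          outer(f[nz], Tm[r, ])
      }
      basis[r] <- j
    }
  }

  if (length(art_cols)) {
    cost1 <- numeric(N)
    cost1[art_cols] <- -1
    res1 <- run(Tm, basis, cost1, seq_len(N))
    Tm <- res1$Tm; basis <- res1$basis
    phase1_obj <- sum(Tm[basis %in% art_cols, N + 1L])
    if (phase1_obj > 1e-7) {
      return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
    }
    # drive any residual basic artificials out or drop redundant rows
    drop_rows <- integer(0)
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        j <- which(abs(Tm[i, seq_len(n + n_le + n_ge)]) > tol)
        if (length(j)) {
          j <- j[1L]
          piv <- Tm[i, j]
          Tm[i, ] <- Tm[i, ] / piv
          other <- setdiff(seq_len(m), i)
          f <- Tm[other, j]
          nz <- which(abs(f) > 0)
          if (length(nz)) {
            Tm[other[nz], ] <- Tm[other[nz], , drop = FALSE] - outer(f[nz], Tm[i, ])
          }
          basis[i] <- j
        } else {
          drop_rows <- c(drop_rows, i)
        }
      }
    }
    if (length(drop_rows)) {
      Tm <- Tm[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- nrow(Tm)
    }
  }

  cost2 <- numeric(N)
  cost2[seq_len(n)] <- obj
  allowed <- seq_len(n + n_le + n_ge)     # artificials may not re-enter
  res2 <- run(Tm, basis, cost2, allowed)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objval = Inf))
  }
  Tm <- res2$Tm; basis <- res2$basis
  x_full <- numeric(N)
  x_full[basis] <- Tm[, N + 1L]
  x <- x_full[seq_len(n)]
  list(status = "optimal", x = x, objval = sum(obj * x))
}

#' Solve a mixed binary linear program by branch and bound
#'
#' Minimizes `obj %*% x` subject to `A x (sense) rhs`, `x >= 0`, with the
#' variables indexed by `binary_idx` restricted to {0, 1}. LP relaxations are
#' solved with [lp_solve()]; branching is depth-first on the most fractional
#' binary (1-branch explored first), which makes the search deterministic.
#' Callers must include the `x_j <= 1` rows for the binaries in `A`.
#'
#' @param obj,A,sense,rhs As in [lp_solve()] (minimization).
#' @param binary_idx Integer indices of the binary variables.
#' @param tol_int Integrality tolerance (default `1e-6`).
#' @param tol_gap Bound-pruning tolerance (default `1e-6`).
#' @param time_limit Wall-clock seconds; on expiry the incumbent is returned
#'   with status `"timeout"`.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"timeout"`),
#'   `x`, `objval`, and `nodes` (number of nodes explored).
#' @export
milp_solve <- function(obj, A, sense, rhs, binary_idx,
                       tol_int = 1e-6, tol_gap = 1e-6, time_limit = Inf) {
  A <- as.matrix(A)
  n <- ncol(A)
  binary_idx <- as.integer(binary_idx)
  best <- Inf; best_x <- NULL
  nodes <- 0L
  t0 <- Sys.time()
  timed_out <- FALSE
  # a node is a named numeric vector of fixed binaries (values 0/1)
  stack <- list(stats::setNames(numeric(0), character(0)))
  while (length(stack)) {
    if (is.finite(time_limit) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      timed_out <- TRUE
      break
    }
    fix <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (length(fix)) {
      k <- length(fix)
      Afix <- matrix(0, k, n)
      idx <- as.integer(names(fix))
      Afix[cbind(seq_len(k), idx)] <- 1
      Ai <- rbind(A, Afix)
      si <- c(sense, rep("=", k))
      bi <- c(rhs, unname(fix))
    } else {
      Ai <- A; si <- sense; bi <- rhs
    }
    rel <- lp_solve(obj, Ai, si, bi, maximize = FALSE)
    if (rel$status != "optimal") next
    if (rel$objval >= best - tol_gap) next
    xb <- rel$x[binary_idx]
    frac <- abs(xb - round(xb))
    if (all(frac <= tol_int)) {
      # Near-integral is not integral: under big-M indicator rows a binary can
      # sit at f/B_u, below tol_int yet load-bearing. Accept an incumbent only
      # if the LP stays feasible with every binary fixed to its rounded value;
      # otherwise branch on the largest (sub-tolerance) fraction.
      k <- length(binary_idx)
      Afix <- matrix(0, k, n)
      Afix[cbind(seq_len(k), binary_idx)] <- 1
      chk <- lp_solve(obj, rbind(Ai, Afix), c(si, rep("=", k)),
                      c(bi, round(xb)), maximize = FALSE)
      if (chk$status == "optimal") {
        if (chk$objval < best - tol_gap) {
          best <- chk$objval
          best_x <- chk$x
        }
        next
      }
      if (max(frac) == 0) next  # exactly integral yet infeasible: numerically degenerate, prune
    }
    j <- binary_idx[which.max(frac)]
    fix0 <- c(fix, stats::setNames(0, j))
    fix1 <- c(fix, stats::setNames(1, j))
    stack[[length(stack) + 1L]] <- fix0
    stack[[length(stack) + 1L]] <- fix1   # popped first: dive toward selection
  }
  if (is.null(best_x)) {
    status <- if (timed_out) "timeout" else "infeasible"
    return(list(status = status, x = NULL, objval = NA_real_, nodes = nodes))
  }
  list(status = if (timed_out) "timeout" else "optimal",
       x = best_x, objval = best, nodes = nodes)
}
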