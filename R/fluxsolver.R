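#' Default solver settings
#'
#' @param big_bound cap on unmeasured free exchanges and reversible
#'   reactions, in umol g^-1 DW week^-1.
#' @param feas_tol solver feasibility tolerance.
#' @param report_tol residual magnitude below which a constraint is reported
#'   as satisfied.
#' @param relax logical; fall back to the penalty relaxation when the hard
#'   problem is infeasible.
#' @param relax_weight quadratic penalty weight on relaxed accumulation
#'   equalities.
#' @param weights optional per-reaction objective weights (named numeric);
#'   unnamed reactions get weight 1.
#' @return list of settings.
#' @export
solver_settings <- function(big_bound = 1e4, feas_tol = 1e-9,
                            report_tol = 1e-8, relax = FALSE,
                            relax_weight = 1e6, weights = NULL) {
  list(big_bound = as.numeric(big_bound), feas_tol = as.numeric(feas_tol),
       report_tol = as.numeric(report_tol), relax = isTRUE(relax),
       relax_weight = as.numeric(relax_weight), weights = weights)
}

#' Assemble the flux-balance problem at one developmental stage
#'
#' Builds the quadratic program for one time point: pseudo-steady-state rows
#' `S v = 0` for every balanced metabolite, equality constraints pinning the
#' accumulation exchanges of measured pools to their fitted derivative value
#' (negative for net degradation, e.g. starch after its peak), and bounds
#' elsewhere: irreversible reactions have a zero lower bound, reversible ones
#' `-big_bound`, and every unmeasured exchange is capped at `big_bound`.
#'
#' @param network an `fx_network`.
#' @param constraints data.frame with columns `metabolite` and `flux`
#'   (umol g^-1 DW week^-1): the measured accumulation fluxes at this stage.
#' @param t the time (WAE) this instance represents.
#' @param settings a [solver_settings()] list.
#' @return an object of class `fx_problem`.
#' @export
assemble_problem <- function(network, constraints, t,
                             settings = solver_settings()) {
  S <- stoichiometric_matrix(network)
  rxns <- network$reactions
  n <- length(rxns)
  acc <- exchange_ids(network, roles = "accumulated")

  missing_ex <- setdiff(constraints$metabolite, names(acc))
  if (length(missing_ex)) {
    fx_error(sprintf("measured pool(s) with no accumulation exchange: %s",
                     paste(missing_ex, collapse = ", ")),
             "fx_no_exchange")
  }
  b_fix <- setNames(constraints$flux, acc[constraints$metabolite])

  rev <- vapply(rxns, function(r) r$reversible, logical(1))
  lb <- ifelse(rev, -settings$big_bound, 0)
  ub <- rep(settings$big_bound, n)
  names(lb) <- names(ub) <- names(rxns)

  structure(list(network = network, S = S, b_fix = b_fix,
                 lb = lb, ub = ub, t = t, settings = settings),
            class = "fx_problem")
}

#' Minimum-norm flux solution of an assembled problem
#'
#' Solves `min sum(w_j v_j^2)` subject to `S v = 0` on all balanced
#' metabolite rows, `v_j = b_fix[j]` for the measured accumulation
#' exchanges, and the reversibility/boundary bounds. The objective is
#' strictly convex, so the optimum is unique and deterministic up to solver
#' tolerance.
#'
#' @param problem an `fx_problem` from [assemble_problem()].
#' @param relax override the `relax` setting of the problem.
#' @return an object of class `fx_solution` with fields `v_opt` (named flux
#'   vector), `objective` (sum of squared fluxes), `steady_state_residual`,
#'   `bound_violation`, `status` (`optimal`, `relaxed` or `infeasible`) and
#'   `slack_report` (non-NULL when relaxed).
#' @export
solve_min_norm <- function(problem, relax = NULL) {
  stopifnot(inherits(problem, "fx_problem"))
  settings <- problem$settings
  if (!is.null(relax)) settings$relax <- relax
  n <- ncol(problem$S)
  rxn_ids <- colnames(problem$S)

  w <- rep(1, n)
  if (!is.null(settings$weights)) {
    idx <- match(names(settings$weights), rxn_ids)
    w[idx[!is.na(idx)]] <- settings$weights[!is.na(idx)]
  }

  fix_rows <- matrix(0, length(problem$b_fix), n,
                     dimnames = list(names(problem$b_fix), rxn_ids))
  fix_rows[cbind(seq_along(problem$b_fix),
                 match(names(problem$b_fix), rxn_ids))] <- 1
  E <- rbind(problem$S, fix_rows)
  d <- c(rep(0, nrow(problem$S)), unname(problem$b_fix))

  sol <- solve_qp_box(w = w, cvec = 0, E = E, d = d,
                      lb = problem$lb, ub = problem$ub,
                      tol = settings$feas_tol)
  if (identical(sol$status, "optimal")) {
    return(finish_solution(problem, sol$v, "optimal", slack = NULL))
  }
  if (!isTRUE(settings$relax)) {
    hint <- infeasibility_hint(problem, E, d)
    fx_error(paste0("flux problem infeasible at t = ", problem$t,
                    "; conflicting equality rows: ",
                    paste(hint, collapse = ", ")),
             "fx_infeasible", hint = hint)
  }
  relaxed <- relax_and_diagnose(problem, weight = settings$relax_weight)
  relaxed
}

# Rank the equality rows by their residual under the best bounded
# least-squares fit, to hint at which constraints conflict.
infeasibility_hint <- function(problem, E, d) {
  sol <- solve_qp_box(w = 1e-6, cvec = 0, E = problem$S,
                      d = rep(0, nrow(problem$S)),
                      lb = problem$lb, ub = problem$ub)
  v <- sol$v
  if (any(!is.finite(v))) v <- rep(0, ncol(E))
  resid <- abs(as.numeric(E %*% v) - d)
  names(resid) <- rownames(E)
  head(names(sort(resid[resid > 1e-6], decreasing = TRUE)), 5)
}

finish_solution <- function(problem, v, status, slack = NULL) {
  names(v) <- colnames(problem$S)
  ss <- max(abs(problem$S %*% v))
  bv <- max(0, max(problem$lb - v), max(v - problem$ub))
  structure(list(v_opt = v, objective = sum(v^2),
                 steady_state_residual = ss, bound_violation = bv,
                 status = status, slack_report = slack, t = problem$t),
            class = "fx_solution")
}

#' Penalty relaxation of the measured accumulation constraints
#'
#' Replaces the hard equalities on measured accumulation exchanges by
#' quadratic penalties `weight * (v_j - b_j)^2`, keeping the steady-state
#' rows and bounds hard, and reports the per-constraint slack sorted by
#' magnitude. As `weight` grows the solution converges to the hard-equality
#' solution whenever one exists.
#'
#' @param problem an `fx_problem`.
#' @param weight penalty weight (scalar or named per-constraint vector).
#' @return an `fx_solution` with `status = "relaxed"` and a `slack_report`
#'   data.frame (constraint, target, achieved, slack).
#' @export
relax_and_diagnose <- function(problem, weight = 1e6) {
  n <- ncol(problem$S)
  rxn_ids <- colnames(problem$S)
  wts <- rep(1, n)
  cvec <- rep(0, n)
  pw <- if (length(weight) == 1L) {
    setNames(rep(weight, length(problem$b_fix)), names(problem$b_fix))
  } else weight
  for (j in names(problem$b_fix)) {
    k <- match(j, rxn_ids)
    wts[k] <- wts[k] + pw[j]
    cvec[k] <- -pw[j] * problem$b_fix[j]
  }
  sol <- solve_qp_box(w = wts, cvec = cvec, E = problem$S,
                      d = rep(0, nrow(problem$S)),
                      lb = problem$lb, ub = problem$ub,
                      tol = problem$settings$feas_tol)
  if (!identical(sol$status, "optimal")) {
    fx_error("relaxed flux problem unexpectedly infeasible", "fx_infeasible")
  }
  achieved <- sol$v[match(names(problem$b_fix), rxn_ids)]
  slack <- data.frame(constraint = names(problem$b_fix),
                      target = unname(problem$b_fix),
                      achieved = achieved,
                      slack = achieved - unname(problem$b_fix))
  slack <- slack[order(-abs(slack$slack)), ]
  rownames(slack) <- NULL
  finish_solution(problem, sol$v, "relaxed", slack = slack)
}

#' Solve the flux problem along a developmental time grid
#'
#' @param network an `fx_network`.
#' @param constraint_table data.frame with columns `week`, `metabolite`,
#'   `flux`: accumulation fluxes (umol g^-1 DW week^-1) per grid point.
#' @param settings a [solver_settings()] list.
#' @return an object of class `fx_series`: list of solutions (one per week,
#'   `NULL` where a point failed) plus the grid; errors only if every point
#'   fails.
#' @export
solve_series <- function(network, constraint_table,
                         settings = solver_settings()) {
  weeks <- sort(unique(constraint_table$week))
  sols <- vector("list", length(weeks))
  names(sols) <- as.character(weeks)
  failures <- character(0)
  for (i in seq_along(weeks)) {
    ct <- constraint_table[constraint_table$week == weeks[i], ]
    res <- tryCatch(
      solve_min_norm(assemble_problem(network, ct, weeks[i], settings)),
      fx_error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      failures <- c(failures, sprintf("t=%g: %s", weeks[i], res))
    } else {
      sols[[i]] <- res
    }
  }
  if (all(vapply(sols, is.null, logical(1)))) {
    fx_error(paste("every grid point infeasible;",
                   paste(head(failures, 3), collapse = " | ")),
             "fx_all_infeasible")
  }
  structure(list(weeks = weeks, solutions = sols, failures = failures,
                 network = network), class = "fx_series")
}

#' @export
print.fx_solution <- function(x, ...) {
  cat(sprintf("Flux solution at t = %g WAE: status %s\n", x$t, x$status))
  cat(sprintf("  objective (sum v^2): %.6g\n", x$objective))
  cat(sprintf("  steady-state residual: %.3g, bound violation: %.3g\n",
              x$steady_state_residual, x$bound_violation))
  top <- sort(abs(x$v_opt), decreasing = TRUE)[1:5]
  cat("  largest |flux|:", paste(sprintf("%s=%.3g", names(top), top),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.fx_series <- function(x, ...) {
  ok <- sum(!vapply(x$solutions, is.null, logical(1)))
  cat(sprintf("Flux series over %d grid points (%d solved)\n",
              length(x$weeks), ok))
  invisible(x)
}

#' Edge table of a flux solution for map drawing
#'
#' One edge per active reaction, with the absolute flux as the arrow-width
#' column. Reversible reactions running backwards are emitted with their
#' direction flipped and a positive magnitude.
#'
#' @param solution an `fx_solution`.
#' @param network the `fx_network` it was solved on.
#' @param zero_tol fluxes of smaller magnitude are omitted.
#' @return data.frame with columns `reaction`, `from`, `to`, `flux`,
#'   `width`, `subsystem`.
#' @export
export_flux_map <- function(solution, network, zero_tol = 1e-9) {
  rows <- list()
  for (rx in network$reactions) {
    v <- solution$v_opt[[rx$id]]
    if (is.na(v) || abs(v) <= zero_tol) next
    st <- rx$stoichiometry
    if (v < 0) st <- -st
    from <- names(st)[st < 0]
    to <- names(st)[st > 0]
    rows[[rx$id]] <- data.frame(
      reaction = rx$id,
      from = if (length(from)) paste(from, collapse = "+") else "",
      to = if (length(to)) paste(to, collapse = "+") else "",
      flux = v,
      width = abs(v),
      subsystem = rx$subsystem
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(reaction = character(0), from = character(0),
                      to = character(0), flux = numeric(0),
                      width = numeric(0), subsystem = character(0))
  }
  rownames(out) <- NULL
  out
}
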