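#' Minimum-norm quadratic programming with equality and box constraints
#'
#' Solves the strictly convex quadratic program
#' \deqn{\min_v \tfrac12 v' W v + c' v \quad \textrm{s.t.} \quad E v = d,\;
#'   lb \le v \le ub}
#' where `W = diag(w)` with strictly positive weights. With `c = 0` and
#' `w = 1` this is the classical minimum-Euclidean-norm flux problem: among
#' all flux vectors satisfying the stationarity and boundary constraints the
#' one of smallest total squared flux is returned. Strict convexity makes the
#' optimum unique.
#'
#' The solver is a dual active-set method of Goldfarb-Idnani type: it starts
#' from the unconstrained minimizer, repeatedly picks the most violated
#' constraint and takes primal/dual steps that keep dual feasibility,
#' dropping blocking constraints as their multipliers hit zero, until all
#' constraints hold. Because the objective is strictly convex the method is
#' finite and needs no feasibility phase; inconsistent constraint systems are
#' detected when a violated constraint admits neither a primal nor a dual
#' step.
#'
#' @param w positive diagonal of the quadratic term (length n, recycled).
#' @param cvec linear term (length n, recycled; default 0).
#' @param E equality constraint matrix (m x n); may have redundant rows.
#' @param d equality right-hand side (length m).
#' @param lb,ub elementwise bounds; `-Inf`/`Inf` allowed.
#' @param tol feasibility tolerance (default 1e-9), scaled internally by the
#'   magnitude of the right-hand side.
#' @param max_iter iteration cap.
#'
#' @return list with elements `v` (solution), `lambda` (multipliers of the
#'   equality rows), `status` ("optimal" or "infeasible"), `kkt` (named
#'   diagnostics), `blocking` (on infeasibility, the label of the constraint
#'   that could not be satisfied), and `iterations`.
#' @keywords internal
solve_qp_box <- function(w, cvec = 0, E, d, lb, ub, tol = 1e-9,
                         max_iter = 2000L) {
  E <- as.matrix(E)
  n <- ncol(E)
  m <- nrow(E)
  w <- rep_len(as.numeric(w), n)
  cvec <- rep_len(as.numeric(cvec), n)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  d <- as.numeric(d)
  if (length(d) != m) stop("length(d) must equal nrow(E)")
  if (any(w <= 0)) stop("quadratic weights must be strictly positive")
  winv <- 1 / w

  fail <- function(blocking, kkt) {
    list(v = rep(NA_real_, n), lambda = rep(NA_real_, m),
         status = "infeasible", kkt = kkt, blocking = blocking,
         iterations = iter)
  }
  iter <- 0L
  if (any(lb > ub + tol)) {
    return(fail("bounds", c(bound_gap = max(lb - ub))))
  }

  scale_b <- max(1, abs(d), abs(lb[is.finite(lb)]), abs(ub[is.finite(ub)]))
  vtol <- tol * scale_b * 10

  x <- -cvec * winv                       # unconstrained minimizer

  # active constraints: parallel vectors describing each as (type, index,
  # sign); normals are sign * E[index, ] for "eq" and sign * e_index for
  # bounds. Multipliers u >= 0 for bounds; equalities are never dropped.
  a_type <- character(0)
  a_idx <- integer(0)
  a_sign <- numeric(0)
  u <- numeric(0)

  normal_of <- function(type, idx, sign) {
    if (type == "eq") sign * E[idx, ] else {
      v <- numeric(n); v[idx] <- sign; v
    }
  }
  active_N <- function() {
    if (!length(a_type)) return(matrix(0, n, 0))
    vapply(seq_along(a_type),
           function(k) normal_of(a_type[k], a_idx[k], a_sign[k]),
           numeric(n))
  }

  # violation report: most violated constraint, oriented so s = n'x - b < 0
  most_violated <- function() {
    viol <- -Inf; pick <- NULL
    if (m) {
      s_eq <- as.numeric(E %*% x) - d
      k <- which.max(abs(s_eq))
      if (abs(s_eq[k]) > vtol && abs(s_eq[k]) > viol) {
        viol <- abs(s_eq[k])
        pick <- list(type = "eq", idx = k, sign = if (s_eq[k] > 0) -1 else 1,
                     s = -abs(s_eq[k]),
                     b = if (s_eq[k] > 0) -d[k] else d[k])
      }
    }
    s_lo <- x - lb
    k <- which.min(s_lo)
    if (is.finite(lb[k]) && s_lo[k] < -vtol && -s_lo[k] > viol) {
      viol <- -s_lo[k]
      pick <- list(type = "lo", idx = k, sign = 1, s = s_lo[k], b = lb[k])
    }
    s_hi <- ub - x
    k <- which.min(s_hi)
    if (is.finite(ub[k]) && s_hi[k] < -vtol && -s_hi[k] > viol) {
      pick <- list(type = "hi", idx = k, sign = -1, s = s_hi[k], b = -ub[k])
    }
    pick
  }

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      return(fail("iteration-limit", c(note_iteration_limit = 1)))
    }
    p <- most_violated()
    if (is.null(p)) break
    np <- normal_of(p$type, p$idx, p$sign)
    u_p <- 0

    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(fail("iteration-limit", c(note_iteration_limit = 1)))
      }
      N <- active_N()
      q <- ncol(N)
      ginv_np <- winv * np
      if (q) {
        M <- crossprod(N, winv * N)             # N' G^-1 N, q x q
        rhs <- crossprod(N, ginv_np)
        r <- tryCatch(solve(M, rhs), error = function(e) qr.solve(M, rhs))
        r <- as.numeric(r)
        z <- ginv_np - winv * as.numeric(N %*% r)
      } else {
        r <- numeric(0)
        z <- ginv_np
      }
      znorm <- sqrt(sum(z * z))
      zTnp <- sum(np * z)

      # dual step bound from active inequality multipliers
      drop_k <- NA_integer_; t1 <- Inf
      if (q) {
        cand <- which(a_type != "eq" & r > 1e-12)
        if (length(cand)) {
          ratios <- u[cand] / r[cand]
          j <- which.min(ratios)
          t1 <- ratios[j]; drop_k <- cand[j]
        }
      }
      t2 <- if (zTnp > 1e-12 * max(1, sum(np^2) * max(winv))) -p$s / zTnp else Inf

      if (!is.finite(t1) && !is.finite(t2)) {
        lab <- if (p$type == "eq") rownames(E)[p$idx] %||% paste0("eq", p$idx)
               else paste0(p$type, "[", p$idx, "]")
        return(fail(lab, c(infeasible_violation = -p$s)))
      }
      tstep <- min(t1, t2)
      if (is.finite(t2)) x <- x + tstep * z
      if (q) u <- u - tstep * r
      u_p <- u_p + tstep

      if (tstep == t2 && is.finite(t2)) {
        # full step: constraint p becomes active
        a_type <- c(a_type, p$type)
        a_idx <- c(a_idx, p$idx)
        a_sign <- c(a_sign, p$sign)
        u <- c(u, u_p)
        break
      }
      # partial (or pure dual) step: drop the blocking constraint, retry p
      a_type <- a_type[-drop_k]; a_idx <- a_idx[-drop_k]
      a_sign <- a_sign[-drop_k]; u <- u[-drop_k]
      if (is.finite(t2)) p$s <- sum(np * x) - p$b
    }
  }

  # assemble diagnostics and equality multipliers
  lambda <- numeric(m)
  if (length(a_type)) {
    eqk <- which(a_type == "eq")
    lambda[a_idx[eqk]] <- a_sign[eqk] * u[eqk]
  }
  grad <- w * x + cvec
  if (length(a_type)) {
    N <- active_N()
    grad <- grad - as.numeric(N %*% u)
  }
  kkt <- c(
    equality_residual = if (m) max(abs(E %*% x - d)) else 0,
    bound_violation = max(0, max(lb - x), max(x - ub)),
    stationarity = max(abs(grad))
  )
  list(v = x, lambda = lambda, status = "optimal", kkt = kkt,
       blocking = NULL, iterations = iter)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
}

#' Moore-Penrose pseudoinverse via singular value decomposition
#'
#' @param A numeric matrix.
#' @param rtol relative tolerance on singular values.
#' @return the pseudoinverse of `A`.
#' @keywords internal
pinv <- function(A, rtol = 1e-12) {
  A <- as.matrix(A)
  sv <- svd(A)
  pos <- sv$d > max(dim(A)) * max(sv$d, 0) * rtol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  r <- which(pos)
  sv$v[, r, drop = FALSE] %*% (t(sv$u[, r, drop = FALSE]) / sv$d[r])
}
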