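# Independent oracles used across the suite.

# Least-norm solution of E v = d via the closed form v = E'(EE')^- d,
# computed with a pseudoinverse that is independent of the package solver.
oracle_least_norm <- function(E, d, w = 1) {
  w <- rep_len(w, ncol(E))
  Es <- E %*% diag(1 / sqrt(w), ncol(E))
  sv <- svd(Es)
  pos <- sv$d > max(dim(Es)) * max(sv$d) * 1e-12
  r <- which(pos)
  u <- sv$v[, r, drop = FALSE] %*% ((t(sv$u[, r, drop = FALSE]) %*% d) / sv$d[r])
  as.numeric(u) / sqrt(w)
}

# Brute-force solver for min 1/2||v||^2 s.t. E v = d, lb <= v <= ub by
# enumerating every subset of bound constraints as active equalities and
# keeping the feasible candidate of smallest objective. Exponential; only
# for tiny instances.
oracle_enum_box <- function(E, d, lb, ub, tol = 1e-7) {
  n <- ncol(E)
  finite_lo <- which(is.finite(lb))
  finite_hi <- which(is.finite(ub))
  cons <- rbind(
    if (length(finite_lo)) cbind(idx = finite_lo, val = lb[finite_lo]),
    if (length(finite_hi)) cbind(idx = finite_hi, val = ub[finite_hi])
  )
  ncons <- if (is.null(cons)) 0L else nrow(cons)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^ncons - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(ncons) - 1)) > 0)
    Ea <- E
    da <- d
    if (length(act)) {
      rows <- matrix(0, length(act), n)
      rows[cbind(seq_along(act), cons[act, "idx"])] <- 1
      Ea <- rbind(E, rows)
      da <- c(d, cons[act, "val"])
    }
    v <- tryCatch(oracle_least_norm(Ea, da), error = function(e) NULL)
    if (is.null(v)) next
    if (max(abs(Ea %*% v - da)) > tol) next
    if (any(v < lb - tol) || any(v > ub + tol)) next
    obj <- sum(v^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- v
    }
  }
  best
}

# Random consistent equality-only instance: d is built from a feasible point
# so the system is guaranteed consistent even when E is rank deficient.
random_eq_instance <- function(n_met, n_rxn, seed) {
  set.seed(seed)
  E <- matrix(sample(-2:2, n_met * n_rxn, replace = TRUE), n_met, n_rxn)
  v0 <- rnorm(n_rxn)
  list(E = E, d = as.numeric(E %*% v0))
}
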