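#' Fruit volume from length and circumference
#'
#' Allometric volume of a plantain fruit,
#' `V = L * C^2 * 0.0616 + 0.3537` (cm^3), with L the fruit length and C the
#' circumference, both in cm. The intercept is the floor of the formula at
#' `L * C^2 = 0`.
#'
#' @param length_cm fruit length in cm (non-negative).
#' @param circumference_cm fruit circumference in cm (non-negative).
#' @return volume in cm^3.
#' @examples
#' fruit_volume(10, 10)   # 61.9537
#' @export
fruit_volume <- function(length_cm, circumference_cm) {
  if (any(length_cm < 0, na.rm = TRUE) ||
      any(circumference_cm < 0, na.rm = TRUE)) {
    fx_error("fruit length and circumference must be non-negative",
             "fx_negative_biometry")
  }
  length_cm * circumference_cm^2 * 0.0616 + 0.3537
}

new_polyfit <- function(coefficients, r_squared, adj_r_squared, domain, n) {
  structure(list(coefficients = coefficients,
                 degree = length(coefficients) - 1L,
                 r_squared = r_squared,
                 adj_r_squared = adj_r_squared,
                 domain = domain, n = n),
            class = "fx_polyfit")
}

#' Ordinary least-squares polynomial fit of a time course
#'
#' Fits `y = a0 + a1 t + ... + ad t^d` by ordinary least squares; replicate
#' observations enter as individual points. Coefficients are stored lowest
#' degree first. When both the residual and the total sum of squares are zero
#' (constant data fitted exactly) R-squared is defined as 1.
#'
#' @param t numeric vector of times (weeks after bunch emergence).
#' @param y numeric response values.
#' @param degree polynomial degree (>= 1).
#' @return an `fx_polyfit` with fields `coefficients` (lowest first),
#'   `degree`, `r_squared`, `adj_r_squared`, `domain`, `n`.
#' @examples
#' fit <- fit_polynomial(0:5, (0:5)^2, degree = 2)
#' coef(fit)
#' @export
fit_polynomial <- function(t, y, degree) {
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  degree <- as.integer(degree)
  if (degree < 1L) fx_error("degree must be >= 1", "fx_bad_degree")
  if (length(unique(t)) <= degree) {
    fx_error(sprintf(
      "need more than %d distinct time points for a degree-%d fit",
      degree, degree), "fx_underdetermined")
  }
  X <- outer(t, 0:degree, `^`)
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  beta[is.na(beta)] <- 0
  fitted <- as.numeric(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) {
    if (rss <= .Machine$double.eps * max(1, sum(y^2))) 1 else 0
  } else 1 - rss / tss
  n <- length(y)
  p <- degree + 1L
  adj <- if (tss == 0 || n - p <= 0) r2 else 1 - (1 - r2) * (n - 1) / (n - p)
  new_polyfit(unname(beta), r2, adj, range(t), n)
}

#' Select the polynomial degree of best fit
#'
#' Walks the candidate degrees in ascending order and accepts a higher
#' degree only when it improves the fit: either it raises the adjusted
#' R-squared *and* the added terms are significant in a nested (partial)
#' F-test at `f_alpha`, or it reduces a nonzero residual to exactly zero.
#' Exact ties in fit quality therefore always resolve to the lowest degree.
#' Candidates needing more distinct time points than available are skipped.
#'
#' @param t,y as in [fit_polynomial()].
#' @param degrees candidate degrees (default 1:3).
#' @param f_alpha significance level of the nested F-test guarding against
#'   overfitting (default 0.05).
#' @return the selected `fx_polyfit`.
#' @export
select_degree <- function(t, y, degrees = 1:3, f_alpha = 0.05) {
  degrees <- sort(unique(as.integer(degrees)))
  keep <- is.finite(t) & is.finite(y)
  tt <- t[keep]; yy <- y[keep]
  rss_of <- function(fit) {
    sum((yy - eval_poly(fit$coefficients, tt))^2)
  }
  best <- NULL
  for (d in degrees) {
    f <- tryCatch(fit_polynomial(tt, yy, d),
                  fx_underdetermined = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best)) {
      best <- f
      next
    }
    rss0 <- rss_of(best)
    rss1 <- rss_of(f)
    df_extra <- f$degree - best$degree
    df_resid <- length(yy) - (f$degree + 1L)
    scale_y <- max(sum(yy^2), .Machine$double.eps)
    if (rss1 <= 1e-12 * scale_y && rss0 > 1e-12 * scale_y) {
      best <- f            # exact interpolation beats an imperfect fit
      next
    }
    if (df_resid > 0 && rss1 > 0 && f$adj_r_squared > best$adj_r_squared) {
      fstat <- ((rss0 - rss1) / df_extra) / (rss1 / df_resid)
      p <- pf(fstat, df_extra, df_resid, lower.tail = FALSE)
      if (!is.na(p) && p < f_alpha) best <- f
    }
  }
  if (is.null(best)) {
    fx_error("no admissible candidate degree for this time course",
             "fx_underdetermined")
  }
  best
}

#' @export
coef.fx_polyfit <- function(object, ...) object$coefficients

#' @export
print.fx_polyfit <- function(x, ...) {
  cat(sprintf("Polynomial fit, degree %d on [%g, %g] (n=%d)\n",
              x$degree, x$domain[1], x$domain[2], x$n))
  cat("  coefficients (lowest first):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.6f, adjusted R^2 = %.6f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Evaluate a polynomial fit
#'
#' @param object an `fx_polyfit`.
#' @param t times at which to evaluate.
#' @param warn_extrapolation warn when `t` lies outside the fitted domain.
#' @param ... unused.
#' @return fitted values at `t`.
#' @export
predict.fx_polyfit <- function(object, t, warn_extrapolation = TRUE, ...) {
  if (warn_extrapolation &&
      any(t < object$domain[1] - 1e-9 | t > object$domain[2] + 1e-9)) {
    warning("evaluating polynomial fit outside its fitted domain")
  }
  eval_poly(object$coefficients, t)
}

eval_poly <- function(coefs, t) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * t + coefs[k]
  out
}

# coefficients (lowest first) of the derivative polynomial
poly_deriv_coefs <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  coefs[-1] * seq_len(length(coefs) - 1L)
}

# coefficients (lowest first) of the antiderivative with constant 0
poly_integral_coefs <- function(coefs) {
  c(0, coefs / seq_along(coefs))
}

# product of two polynomials in coefficient form (lowest first)
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Analytic derivative of a polynomial fit
#'
#' @param fit an `fx_polyfit`.
#' @param t times at which to evaluate the derivative.
#' @param warn_extrapolation warn outside the fitted domain.
#' @return derivative values, in response units per week.
#' @examples
#' fit <- fit_polynomial(0:4, (0:4)^3, degree = 3)
#' derivative(fit, 2)   # 12
#' @export
derivative <- function(fit, t, warn_extrapolation = TRUE) {
  stopifnot(inherits(fit, "fx_polyfit"))
  if (warn_extrapolation &&
      any(t < fit$domain[1] - 1e-9 | t > fit$domain[2] + 1e-9)) {
    warning("evaluating polynomial derivative outside the fitted domain")
  }
  eval_poly(poly_deriv_coefs(fit$coefficients), t)
}

#' Per-fruit amount from a concentration and a dry-weight trajectory
#'
#' Converts a per-gram concentration into a per-fruit amount,
#' `amount = concentration x DW(t)`.
#'
#' @param conc concentration (umol per g DW).
#' @param dw_fit `fx_polyfit` of dry weight per fruit (g).
#' @param t time (WAE).
#' @return amount in umol per fruit.
#' @export
per_fruit_amount <- function(conc, dw_fit, t) {
  dw <- predict(dw_fit, t, warn_extrapolation = FALSE)
  if (any(dw < 0)) {
    fx_error("fitted dry weight is negative; refusing to convert amounts",
             "fx_negative_dw")
  }
  conc * dw
}

#' Accumulation flux on a per-gram dry weight basis
#'
#' Differentiates a fitted per-fruit amount trajectory and scales by dry
#' weight: `flux(t) = d amount/dt / DW(t)`, in umol per g DW per week.
#' Positive values are net accumulation, negative values net degradation.
#'
#' @param amount_fit `fx_polyfit` of the per-fruit amount (umol per fruit).
#' @param dw_fit `fx_polyfit` of dry weight per fruit (g).
#' @param t times (WAE).
#' @return flux in umol g^-1 DW week^-1.
#' @export
accumulation_flux <- function(amount_fit, dw_fit, t) {
  dw <- predict(dw_fit, t, warn_extrapolation = FALSE)
  if (any(dw <= 0)) {
    fx_error("dry weight must be positive to express fluxes per g DW",
             "fx_negative_dw")
  }
  derivative(amount_fit, t, warn_extrapolation = FALSE) / dw
}

#' Fruit growth rate from a fitted volume trajectory
#'
#' @param volume_fit `fx_polyfit` of fruit volume (cm^3), conventionally the
#'   cubic fit.
#' @param t times (WAE).
#' @return growth rate in cm^3 per week.
#' @export
growth_rate <- function(volume_fit, t) {
  derivative(volume_fit, t)
}

#' Onset of net starch breakdown
#'
#' For a quadratic fit `a t^2 + b t + c` of the per-fruit starch amount with
#' `a < 0`, the vertex `t* = -b / (2 a)` is the time at which net starch
#' breakdown begins (the end of maturation).
#'
#' @param starch_fit a quadratic `fx_polyfit` with negative leading
#'   coefficient.
#' @return the vertex time, in WAE.
#' @export
net_breakdown_time <- function(starch_fit) {
  stopifnot(inherits(starch_fit, "fx_polyfit"))
  if (starch_fit$degree != 2L) {
    fx_error("net_breakdown_time expects a quadratic fit", "fx_bad_degree")
  }
  a <- starch_fit$coefficients[3]
  b <- starch_fit$coefficients[2]
  if (a >= 0) {
    fx_error("quadratic has no maximum (leading coefficient >= 0)",
             "fx_no_maximum")
  }
  -b / (2 * a)
}
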