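#' Default synthetic plantain study scenario
#'
#' Ground-truth configuration emulating the design of a two-cultivar plantain
#' development study: 2 cultivars, fruits sampled 2-12 weeks after bunch
#' emergence (WAE) in 2-week steps, 5 replicate fruits per time point,
#' multiplicative log-normal replicate noise. Per-fruit dry weight follows a
#' sigmoid-shaped cubic (5 to 40 g between 2 and 12 WAE, growth rate peaking
#' near 7 WAE); each accumulated pool follows a cubic per-fruit trajectory,
#' so its ground-truth exchange flux is the quadratic derivative.
#'
#' Construction targets of the default truth: the per-fruit starch pool has
#' its maximum at exactly 9.3 WAE (cultivar AG) and 10.2 WAE (cultivar OB),
#' marking the onset of net starch breakdown; per-gram starch stays in the
#' 260-580 umol g^-1 DW range; the sucrose concentration rises after week 8;
#' and the per-gram accumulation demand is strongest at 2 WAE so that
#' glycolysis, the TCA cycle and respiration carry their highest fluxes at
#' the earliest stage and decline through development.
#'
#' @param cv coefficient of variation of the multiplicative replicate noise
#'   (default 0.15).
#' @param weeks sampling weeks (default 2,4,...,12 WAE).
#' @param replicates replicate fruits per cultivar and week (default 5).
#' @return an object of class `fx_scenario`: network, per-cultivar dry-weight
#'   and pool polynomial coefficients (lowest first, per-fruit basis),
#'   biometry curves, and sampling design.
#' @export
default_plantain_scenario <- function(cv = 0.15, weeks = seq(2, 12, by = 2),
                                      replicates = 5L) {
  network <- plantain_network()
  dw_ag <- c(3.04, -0.16, 0.63, -0.03)
  dw_ob <- 0.92 * dw_ag

  cultivars <- list(
    AG = list(
      dw_coefs = dw_ag,
      length_coefs = c(8, 2.2, -0.06),
      circumference_coefs = c(4, 1.4, -0.04),
      pool_coefs = c(
        list(
          STARCH = starch_pool_coefs(dw_ag, t_peak = 9.3, conc_start = 270,
                                     conc_at10 = 430),
          SUC = anchored_pool_coefs(dw_ag, t = c(2, 5, 9, 12),
                                    conc = c(95, 70, 110, 155)),
          GLC = anchored_pool_coefs(dw_ag, t = c(2, 6, 9, 12),
                                    conc = c(30, 6.5, 4.5, 4.2)),
          FRU = anchored_pool_coefs(dw_ag, t = c(2, 6, 9, 12),
                                    conc = c(60, 15, 10, 8))
        ),
        constant_conc_pools(dw_ag, c(G6P = 3.5, G1P = 0.2, F6P = 0.4,
                                     MAL = 30, AA = 50, PROT = 450,
                                     CW = 600, PHEN = 20))
      )
    ),
    OB = list(
      dw_coefs = dw_ob,
      length_coefs = 0.95 * c(8, 2.2, -0.06),
      circumference_coefs = 0.95 * c(4, 1.4, -0.04),
      pool_coefs = c(
        list(
          STARCH = starch_pool_coefs(dw_ob, t_peak = 10.2, conc_start = 268,
                                     conc_at10 = 440),
          SUC = anchored_pool_coefs(dw_ob, t = c(2, 5, 9, 12),
                                    conc = c(98, 75, 125, 150)),
          GLC = anchored_pool_coefs(dw_ob, t = c(2, 6, 9, 12),
                                    conc = c(21, 4.5, 4.2, 4.3)),
          FRU = anchored_pool_coefs(dw_ob, t = c(2, 6, 9, 12),
                                    conc = c(40, 10, 8, 5))
        ),
        constant_conc_pools(dw_ob, c(G6P = 3.7, G1P = 0.2, F6P = 0.4,
                                     MAL = 28, AA = 48, PROT = 460,
                                     CW = 580, PHEN = 22))
      )
    )
  )
  structure(list(network = network, cultivars = cultivars, weeks = weeks,
                 replicates = as.integer(replicates), cv = cv,
                 t_range = range(weeks)),
            class = "fx_scenario")
}

# Cubic per-fruit starch pool with stationary maximum at t_peak: the
# per-fruit accumulation flux is A'(t) = -3 g t (t - t_peak), so the pool
# rises until t_peak and declines afterwards; g is set so the per-gram
# concentration hits conc_at10 at 10 WAE, starting from conc_start at 2 WAE.
starch_pool_coefs <- function(dw_coefs, t_peak, conc_start, conc_at10) {
  a2 <- conc_start * eval_poly(dw_coefs, 2)
  shape <- function(t) (t^3 - 8) / 3 - t_peak * (t^2 - 4) / 2
  g <- (conc_at10 * eval_poly(dw_coefs, 10) - a2) / (-3 * shape(10))
  c(a2 + 8 * g - 6 * g * t_peak, 0, 3 * g * t_peak / 2, -g)
}

# Cubic per-fruit pool through per-gram concentration anchors.
anchored_pool_coefs <- function(dw_coefs, t, conc) {
  stopifnot(length(t) == 4, length(conc) == 4)
  M <- t(vapply(t, function(tt) c(1, tt, tt^2, tt^3), numeric(4)))
  as.numeric(solve(M, conc * eval_poly(dw_coefs, t)))
}

# Pools proportional to dry weight (constant per-gram concentration).
constant_conc_pools <- function(dw_coefs, conc) {
  lapply(setNames(as.list(conc), names(conc)), function(cc) cc * dw_coefs)
}

#' Ground-truth accumulation fluxes of a scenario
#'
#' Evaluates the exact exchange (accumulation) fluxes implied by the
#' scenario's per-fruit pool polynomials: `flux(t) = A'(t) / DW(t)` in
#' umol g^-1 DW week^-1.
#'
#' @param scenario an `fx_scenario`.
#' @param weeks evaluation times (WAE).
#' @return data.frame with columns `cultivar`, `week`, `metabolite`, `flux`.
#' @export
truth_constraints <- function(scenario, weeks) {
  out <- list()
  for (cv_name in names(scenario$cultivars)) {
    cu <- scenario$cultivars[[cv_name]]
    dw <- eval_poly(cu$dw_coefs, weeks)
    for (metab in names(cu$pool_coefs)) {
      dcoef <- poly_deriv_coefs(cu$pool_coefs[[metab]])
      out[[paste(cv_name, metab)]] <- data.frame(
        cultivar = cv_name, week = weeks, metabolite = metab,
        flux = eval_poly(dcoef, weeks) / dw)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic study from a scenario
#'
#' Produces replicate-level observation tables with known ground truth.
#' Per-fruit pools are the exact polynomial integrals of the ground-truth
#' exchange fluxes; per-gram concentrations are pools divided by dry weight;
#' replicate noise is multiplicative log-normal with bias-corrected mean 1
#' (`exp(sigma Z - sigma^2/2)`, `sigma^2 = log(1 + cv^2)`). The random
#' stream is split deterministically per table (concentrations, biometry) by
#' a fixed seed offset, so adding a table never perturbs existing draws;
#' regeneration with the same seed is bit-identical.
#'
#' @param scenario an `fx_scenario`, e.g. [default_plantain_scenario()].
#' @param seed integer seed.
#' @param cv override the scenario's noise coefficient of variation.
#' @return an object of class `fx_study`: `concentrations` (cultivar, week,
#'   replicate, variable, value, unit), `biometry` (cultivar, week,
#'   replicate, length_cm, circumference_cm, dw_g), `truth` (noiseless
#'   concentration and flux tables plus the polynomial coefficients), and
#'   the `scenario` echo (with `seed` and `cv` filled in).
#' @export
generate_study <- function(scenario, seed = 1L, cv = scenario$cv) {
  stopifnot(inherits(scenario, "fx_scenario"))
  if (cv < 0) fx_error("cv must be non-negative", "fx_bad_cv")
  weeks <- scenario$weeks
  reps <- scenario$replicates

  # refuse scenarios whose pools go negative inside the sampling window
  fine <- seq(min(weeks), max(weeks), by = 0.05)
  for (cv_name in names(scenario$cultivars)) {
    cu <- scenario$cultivars[[cv_name]]
    for (metab in names(cu$pool_coefs)) {
      pool <- eval_poly(cu$pool_coefs[[metab]], fine)
      if (any(pool < 0)) {
        fx_error(sprintf(
          "ground-truth pool of %s (%s) goes negative near week %.1f",
          metab, cv_name, fine[which(pool < 0)[1]]), "fx_negative_pool")
      }
    }
  }

  sigma <- sqrt(log(1 + cv^2))
  noise <- function(k) exp(sigma * rnorm(k) - sigma^2 / 2)

  truth_conc <- list()
  conc_rows <- list()
  bio_rows <- list()

  # substream 1: concentrations
  set.seed(seed_offset(seed, 1L))
  for (cv_name in names(scenario$cultivars)) {
    cu <- scenario$cultivars[[cv_name]]
    dw <- eval_poly(cu$dw_coefs, weeks)
    for (metab in names(cu$pool_coefs)) {
      conc <- eval_poly(cu$pool_coefs[[metab]], weeks) / dw
      truth_conc[[paste(cv_name, metab)]] <- data.frame(
        cultivar = cv_name, week = weeks, variable = metab, value = conc,
        unit = "umol/gDW")
      for (i in seq_along(weeks)) {
        conc_rows[[length(conc_rows) + 1L]] <- data.frame(
          cultivar = cv_name, week = weeks[i], replicate = seq_len(reps),
          variable = metab,
          value = conc[i] * (if (cv > 0) noise(reps) else rep(1, reps)),
          unit = "umol/gDW")
      }
    }
  }

  # substream 2: biometry
  set.seed(seed_offset(seed, 2L))
  for (cv_name in names(scenario$cultivars)) {
    cu <- scenario$cultivars[[cv_name]]
    for (i in seq_along(weeks)) {
      len <- eval_poly(cu$length_coefs, weeks[i])
      circ <- eval_poly(cu$circumference_coefs, weeks[i])
      dw <- eval_poly(cu$dw_coefs, weeks[i])
      mult <- function() if (cv > 0) noise(reps) else rep(1, reps)
      bio_rows[[length(bio_rows) + 1L]] <- data.frame(
        cultivar = cv_name, week = weeks[i], replicate = seq_len(reps),
        length_cm = len * mult(), circumference_cm = circ * mult(),
        dw_g = dw * mult())
    }
  }

  scenario$seed <- seed
  scenario$cv <- cv
  structure(list(
    concentrations = do.call(rbind, conc_rows),
    biometry = do.call(rbind, bio_rows),
    truth = list(concentrations = do.call(rbind, truth_conc),
                 fluxes = truth_constraints(scenario, weeks),
                 cultivars = scenario$cultivars),
    scenario = scenario
  ), class = "fx_study")
}

# deterministic per-table substream: fixed counter offsets keep streams
# independent of table generation order
seed_offset <- function(seed, k) {
  as.integer((as.numeric(seed) * 131L + k * 7919) %% .Machine$integer.max)
}

#' @export
print.fx_study <- function(x, ...) {
  cat("Synthetic study:", length(unique(x$concentrations$cultivar)),
      "cultivars x", length(unique(x$concentrations$week)), "weeks x",
      max(x$concentrations$replicate), "replicates, cv =", x$scenario$cv,
      "\n")
  cat("  ", nrow(x$concentrations), "concentration observations,",
      length(unique(x$concentrations$variable)), "measured pools\n")
  invisible(x)
}
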