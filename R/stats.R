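#' Packaged reference metabolite concentrations
#'
#' Mean concentrations (umol per g DW) of soluble sugars, hexose phosphates
#' and starch in plantain pulp of the Agbagba (AG) and Obino l'Ewai (OB)
#' cultivars from 2 to 12 weeks after bunch emergence.
#'
#' @return data.frame with columns `cultivar`, `week`, `metabolite`, `value`,
#'   `unit`.
#' @examples
#' head(plantain_pulp_concentrations())
#' @export
plantain_pulp_concentrations <- function() {
  read.csv(system.file("extdata", "plantain_pulp_means.csv",
                       package = "fruitflux", mustWork = TRUE),
           comment.char = "#", stringsAsFactors = FALSE)
}

#' Ratio of two metabolite concentrations at a given week
#'
#' In `pooled-mean` mode the per-cultivar means are averaged across cultivars
#' before dividing (the "on average across the two cultivars" convention);
#' in `per-cultivar` mode one ratio per cultivar is returned.
#'
#' @param table data.frame with columns `cultivar`, `week`, `metabolite`,
#'   `value` (means, umol per g DW).
#' @param numerator,denominator metabolite names.
#' @param week the week (WAE) at which to take the ratio.
#' @param pooling `"pooled-mean"` (default) or `"per-cultivar"`.
#' @return a single ratio, or a named vector of per-cultivar ratios.
#' @examples
#' tab <- plantain_pulp_concentrations()
#' metabolite_ratio(tab, "G6P", "G1P", week = 6)
#' @export
metabolite_ratio <- function(table, numerator, denominator, week,
                             pooling = c("pooled-mean", "per-cultivar")) {
  pooling <- match.arg(pooling)
  sel <- function(metab) table[table$week == week & table$metabolite == metab, ]
  num <- sel(numerator)
  den <- sel(denominator)
  if (!nrow(num) || !nrow(den)) {
    fx_error(sprintf("metabolite(s) not present at week %s", week),
             "fx_missing_metabolite")
  }
  if (pooling == "pooled-mean") {
    num_mean <- mean(tapply(num$value, num$cultivar, mean))
    den_mean <- mean(tapply(den$value, den$cultivar, mean))
    if (den_mean == 0) fx_error("zero denominator", "fx_zero_denominator")
    num_mean / den_mean
  } else {
    cultivars <- sort(intersect(unique(num$cultivar), unique(den$cultivar)))
    out <- vapply(cultivars, function(cv) {
      d <- mean(den$value[den$cultivar == cv])
      if (d == 0) fx_error("zero denominator", "fx_zero_denominator")
      mean(num$value[num$cultivar == cv]) / d
    }, numeric(1))
    setNames(out, cultivars)
  }
}

#' Pearson correlation screen with false-discovery-rate control
#'
#' Correlates every column of `features` with every column of `targets`,
#' computes exact two-sided p-values through the t transform
#' `t = r sqrt((n-2)/(1-r^2))`, and adjusts across all tested pairs with the
#' Benjamini-Hochberg step-up procedure. Pairs involving a zero-variance
#' vector are returned with `NA` statistics and excluded from the FDR family.
#'
#' @param features numeric matrix (observations x features).
#' @param targets numeric matrix (observations x targets).
#' @param alpha significance threshold applied to the adjusted p-value.
#' @param fdr_method method passed to [stats::p.adjust()] (default "BH").
#' @return data.frame with columns `feature`, `target`, `r`, `p`, `q`,
#'   `pass`.
#' @export
pearson_screen <- function(features, targets, alpha = 0.001,
                           fdr_method = "BH") {
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  if (nrow(features) != nrow(targets)) {
    fx_error("features and targets must have the same number of rows",
             "fx_dim_mismatch")
  }
  n <- nrow(features)
  if (n < 3) fx_error("need at least 3 paired observations", "fx_too_few_obs")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature", seq_len(ncol(features)))
  if (is.null(colnames(targets)))
    colnames(targets) <- paste0("target", seq_len(ncol(targets)))

  grid <- expand.grid(feature = colnames(features), target = colnames(targets),
                      stringsAsFactors = FALSE)
  var_f <- apply(features, 2, var)
  var_t <- apply(targets, 2, var)
  r <- mapply(function(f, g) {
    if (var_f[f] == 0 || var_t[g] == 0) return(NA_real_)
    cor(features[, f], targets[, g])
  }, grid$feature, grid$target)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(!ok)) {
    message(sum(!ok), " pair(s) with zero variance excluded from the FDR family")
  }
  q[ok] <- p.adjust(p[ok], method = fdr_method)
  data.frame(grid, r = unname(r), p = unname(p), q = q,
             pass = !is.na(q) & q < alpha)
}

#' Two-way ANOVA with Fisher LSD letter display
#'
#' Fits `value ~ week * cultivar` (both treated as factors) on replicate
#' data, reports type-II F tests for the two main effects and their
#' interaction, and compares all cell means with Fisher's least significant
#' difference procedure (pairwise t tests on the pooled residual variance,
#' unadjusted, as classically done after a significant ANOVA). Cell means
#' sharing a letter are not significantly different at `alpha`; letters are
#' assigned in ascending order of the mean, so 'A' always contains the
#' smallest mean.
#'
#' @param data data.frame with columns `week`, `cultivar`, `value` and at
#'   least 2 replicates per week x cultivar cell.
#' @param alpha significance level for both the F tests and the LSD
#'   comparisons.
#' @return list with `anova` (data.frame: term, df, sum_sq, F, p),
#'   `means` (cell means with letters), `alpha`.
#' @export
two_way_anova_lsd <- function(data, alpha = 0.05) {
  req <- c("week", "cultivar", "value")
  if (!all(req %in% names(data))) {
    fx_error("data must have columns week, cultivar, value", "fx_bad_table")
  }
  data$week <- factor(data$week)
  data$cultivar <- factor(data$cultivar)
  counts <- table(data$week, data$cultivar)
  if (any(counts < 2)) {
    fx_error("every week x cultivar cell needs at least 2 replicates",
             "fx_too_few_replicates")
  }
  if (nlevels(data$cultivar) < 2L) {
    # single-factor collapse: one-way ANOVA on week
    fit <- lm(value ~ week, data = data)
    a1 <- anova(fit)
    terms_out <- data.frame(term = "week", df = a1$Df[1],
                            sum_sq = a1$`Sum Sq`[1],
                            F = a1$`F value`[1], p = a1$`Pr(>F)`[1])
  } else {
    fit <- lm(value ~ week * cultivar, data = data)
    a2 <- car::Anova(fit, type = 2)
    terms_out <- data.frame(
      term = c("week", "cultivar", "week:cultivar"),
      df = a2$Df[1:3],
      sum_sq = a2$`Sum Sq`[1:3],
      F = a2$`F value`[1:3],
      p = a2$`Pr(>F)`[1:3]
    )
  }
  mse <- sum(fit$residuals^2) / fit$df.residual
  cells <- aggregate(value ~ week + cultivar, data = data, FUN = mean)
  ncell <- aggregate(value ~ week + cultivar, data = data, FUN = length)
  cells$n <- ncell$value
  cells$group <- paste(cells$cultivar, cells$week, sep = ":")

  k <- nrow(cells)
  notdiff <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse * (1 / cells$n[i] + 1 / cells$n[j]))
      tval <- abs(cells$value[i] - cells$value[j]) / se
      pij <- 2 * pt(-tval, df = fit$df.residual)
      notdiff[i, j] <- notdiff[j, i] <- pij >= alpha
    }
  }
  cells$letters <- letter_display(cells$value, notdiff)
  list(anova = terms_out,
       means = cells[order(cells$cultivar, cells$week),
                     c("cultivar", "week", "n", "value", "letters")],
       alpha = alpha)
}

#' Compact letter display from a non-significance matrix
#'
#' Insert-and-absorb construction: starting from a single letter holding all
#' groups, every significantly different pair splits the letters containing
#' both, and letters that become subsets of another are absorbed. The result
#' is a set of maximal cliques of the non-significance graph covering every
#' non-different pair. Letters are ordered by the smallest mean they contain,
#' so 'A' always contains the group with the smallest mean; the construction
#' is deterministic.
#'
#' @param means numeric vector of group means.
#' @param notdiff logical k x k matrix, `TRUE` when two groups are NOT
#'   significantly different.
#' @return character vector of letter strings, parallel to `means`.
#' @keywords internal
letter_display <- function(means, notdiff) {
  k <- length(means)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (notdiff[i, j]) next
      new_cols <- list()
      for (cl in cols) {
        if (i %in% cl && j %in% cl) {
          new_cols <- c(new_cols, list(setdiff(cl, i)), list(setdiff(cl, j)))
        } else {
          new_cols <- c(new_cols, list(cl))
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] && keep[b] &&
              length(new_cols[[a]]) <= length(new_cols[[b]]) &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              !(length(new_cols[[a]]) == length(new_cols[[b]]) && a < b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  first_mean <- vapply(cols, function(cl) min(means[cl]), numeric(1))
  cols <- cols[order(first_mean)]
  out <- character(k)
  for (ci in seq_along(cols)) {
    for (idx in cols[[ci]]) {
      out[idx] <- paste0(out[idx], LETTERS[ci])
    }
  }
  out
}
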