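#' Fit dry-weight and per-fruit amount trajectories of a study
#'
#' For each cultivar, fits the dry weight per fruit with a cubic (the
#' conventional sigmoid-shaped growth description) and every measured pool
#' with the best-fitting polynomial among the candidate degrees, after
#' converting concentrations to per-fruit amounts with the fitted dry
#' weight. Replicates enter the fits as individual points; a table of means
#' (one row per cultivar x week x variable) is accepted as well.
#'
#' @param concentrations data.frame with columns `cultivar`, `week`,
#'   `replicate`, `variable`, `value` (umol per g DW).
#' @param biometry data.frame with columns `cultivar`, `week`, `replicate`,
#'   `dw_g` (dry weight per fruit, g).
#' @param degrees candidate polynomial degrees for the pool fits.
#' @param dw_degree degree of the dry-weight fit (default 3).
#' @return an object of class `fx_fits`: per cultivar, the `dw_fit` and a
#'   named list `amount_fits` of per-fruit amount fits (umol per fruit).
#' @export
fit_study <- function(concentrations, biometry, degrees = 1:3,
                      dw_degree = 3L) {
  req_c <- c("cultivar", "week", "variable", "value")
  if (!all(req_c %in% names(concentrations))) {
    fx_error(paste("concentration table must have columns",
                   paste(req_c, collapse = ", ")), "fx_bad_table")
  }
  if (!all(c("cultivar", "week", "dw_g") %in% names(biometry))) {
    fx_error("biometry table must have columns cultivar, week, dw_g",
             "fx_bad_table")
  }
  fits <- list()
  for (cv_name in sort(unique(concentrations$cultivar))) {
    bio <- biometry[biometry$cultivar == cv_name, ]
    if (!nrow(bio)) {
      fx_error(sprintf("no biometry rows for cultivar %s", cv_name),
               "fx_bad_table")
    }
    dw_fit <- fit_polynomial(bio$week, bio$dw_g, dw_degree)
    conc <- concentrations[concentrations$cultivar == cv_name, ]
    amount_fits <- list()
    for (metab in sort(unique(conc$variable))) {
      rows <- conc[conc$variable == metab, ]
      amounts <- per_fruit_amount(rows$value, dw_fit, rows$week)
      amount_fits[[metab]] <- select_degree(rows$week, amounts, degrees)
    }
    fits[[cv_name]] <- list(dw_fit = dw_fit, amount_fits = amount_fits)
  }
  structure(fits, class = "fx_fits")
}

#' Accumulation-flux constraint table from fitted trajectories
#'
#' Differentiates every fitted per-fruit amount trajectory on a time grid
#' and divides by the fitted dry weight, yielding the accumulation fluxes
#' (umol g^-1 DW week^-1) that constrain the flux-balance problem. Grid
#' points where a fitted amount dips below zero are clipped: the
#' concentration is treated as zero and the flux set to 0 there, with a
#' warning.
#'
#' @param fits an `fx_fits` from [fit_study()].
#' @param weeks time grid (default: 0.5-week steps across the fitted domain
#'   plus the sampled weeks).
#' @return data.frame with columns `cultivar`, `week`, `metabolite`, `flux`,
#'   `unit`.
#' @export
flux_constraints <- function(fits, weeks = NULL) {
  out <- list()
  for (cv_name in names(fits)) {
    fit <- fits[[cv_name]]
    dom <- fit$dw_fit$domain
    grid <- if (is.null(weeks)) {
      sort(unique(c(seq(dom[1], dom[2], by = 0.5), dom)))
    } else weeks
    dw <- predict(fit$dw_fit, grid, warn_extrapolation = FALSE)
    for (metab in names(fit$amount_fits)) {
      af <- fit$amount_fits[[metab]]
      flux <- accumulation_flux(af, fit$dw_fit, grid)
      amount <- predict(af, grid, warn_extrapolation = FALSE)
      neg <- amount < 0
      if (any(neg)) {
        warning(sprintf(
          "fitted %s (%s) negative at %d grid point(s); clipped to zero",
          metab, cv_name, sum(neg)))
        flux[neg] <- 0
      }
      out[[paste(cv_name, metab)]] <- data.frame(
        cultivar = cv_name, week = grid, metabolite = metab, flux = flux,
        unit = "umol/gDW/week")
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Solve the developmental flux series for every cultivar
#'
#' @param network an `fx_network`.
#' @param constraints a constraint table from [flux_constraints()] (columns
#'   `cultivar`, `week`, `metabolite`, `flux`).
#' @param settings [solver_settings()].
#' @return named list of `fx_series`, one per cultivar.
#' @export
solve_study <- function(network, constraints, settings = solver_settings()) {
  out <- list()
  for (cv_name in sort(unique(constraints$cultivar))) {
    ct <- constraints[constraints$cultivar == cv_name, ]
    out[[cv_name]] <- solve_series(network, ct, settings)
  }
  out
}

#' Flux table of a solved series
#'
#' @param series an `fx_series`.
#' @return data.frame with columns `week`, `reaction`, `flux`,
#'   `objective_share` (fraction of the squared-flux objective).
#' @export
flux_table <- function(series) {
  rows <- list()
  for (i in seq_along(series$weeks)) {
    sol <- series$solutions[[i]]
    if (is.null(sol)) next
    rows[[i]] <- data.frame(week = series$weeks[i],
                            reaction = names(sol$v_opt),
                            flux = unname(sol$v_opt),
                            objective_share = unname(sol$v_opt^2) /
                              max(sol$objective, .Machine$double.eps))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- file-based pipeline (the command-line surface) ----------------------

#' Assemble a pipeline configuration
#'
#' @param network_reactions,network_metabolites paths to the network tables;
#'   defaults to the packaged plantain network.
#' @param concentrations,biometry paths to the observation CSVs.
#' @param output_dir directory for output tables.
#' @param degrees candidate fit degrees.
#' @param grid_step time-grid step in weeks.
#' @param settings [solver_settings()].
#' @param seed integer seed (used by fixture generation).
#' @param cv noise level for fixture generation.
#' @return a `fx_config` list.
#' @export
pipeline_config <- function(network_reactions = NULL,
                            network_metabolites = NULL,
                            concentrations = NULL, biometry = NULL,
                            output_dir = ".", degrees = 1:3,
                            grid_step = 0.5, settings = solver_settings(),
                            seed = 1L, cv = 0.15) {
  structure(list(network_reactions = network_reactions,
                 network_metabolites = network_metabolites,
                 concentrations = concentrations, biometry = biometry,
                 output_dir = output_dir, degrees = as.integer(degrees),
                 grid_step = as.numeric(grid_step), settings = settings,
                 seed = as.integer(seed), cv = as.numeric(cv)),
            class = "fx_config")
}

#' Read or write a pipeline configuration file
#'
#' Configurations serialize to a single YAML file and round-trip unchanged;
#' any key can be overridden after reading.
#'
#' @param path file path.
#' @param config an `fx_config`.
#' @return `read_pipeline_config()` returns an `fx_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    fx_error(sprintf("config file not found: %s", path), "fx_missing_file")
  }
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "settings")])
  if (!is.null(raw$settings)) {
    merged <- utils::modifyList(solver_settings(), raw$settings,
                                keep.null = TRUE)
    cfg$settings <- do.call(solver_settings, merged)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_network <- function(config) {
  if (is.null(config$network_reactions)) {
    plantain_network()
  } else {
    load_network(config$network_reactions, config$network_metabolites)
  }
}

# '#'-prefixed provenance header for every output table
provenance_header <- function(config, seed = NULL) {
  c(sprintf("# fruitflux %s",
            as.character(utils::packageVersion("fruitflux"))),
    sprintf("# config-hash %s", config_hash(config)),
    sprintf("# seed %s", if (is.null(seed)) config$seed else seed))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

read_tsv_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the fitting stage on observation files
#'
#' Reads the concentration and biometry CSVs named in the configuration,
#' fits all trajectories and writes two provenance-stamped TSVs into the
#' output directory: `fitted_coefficients.tsv` and `flux_constraints.tsv`.
#'
#' @param config an `fx_config` from [pipeline_config()].
#' @return (invisibly) list with the fits and the written paths.
#' @export
run_fit <- function(config) {
  conc <- read_study_csv(config$concentrations,
                         c("cultivar", "week", "variable", "value"))
  bio <- read_study_csv(config$biometry, c("cultivar", "week", "dw_g"))
  fits <- fit_study(conc, bio, degrees = config$degrees)

  coef_rows <- list()
  for (cv_name in names(fits)) {
    f <- fits[[cv_name]]
    all_fits <- c(list(DW = f$dw_fit), f$amount_fits)
    for (nm in names(all_fits)) {
      pf <- all_fits[[nm]]
      coef_rows[[paste(cv_name, nm)]] <- data.frame(
        cultivar = cv_name, variable = nm, degree = pf$degree,
        coefficient_order = seq_along(pf$coefficients) - 1L,
        coefficient = pf$coefficients, r_squared = pf$r_squared)
    }
  }
  coef_tab <- do.call(rbind, coef_rows)
  rownames(coef_tab) <- NULL

  dom <- fits[[1]]$dw_fit$domain
  grid <- sort(unique(c(seq(dom[1], dom[2], by = config$grid_step), dom)))
  constraints <- flux_constraints(fits, weeks = grid)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config)
  p1 <- file.path(config$output_dir, "fitted_coefficients.tsv")
  p2 <- file.path(config$output_dir, "flux_constraints.tsv")
  write_tsv_with_header(coef_tab, p1, hdr)
  write_tsv_with_header(constraints, p2, hdr)
  invisible(list(fits = fits, coefficients = p1, constraints = p2))
}

read_study_csv <- function(path, required) {
  if (is.null(path) || !file.exists(path)) {
    fx_error(sprintf("input file not found: %s", path %||% "<missing>"),
             "fx_missing_file")
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    fx_error(sprintf("%s: missing required column(s): %s", path,
                     paste(missing_cols, collapse = ", ")),
             "fx_missing_column")
  }
  df
}

#' Run the flux-solving stage
#'
#' Reads the constraint table written by [run_fit()] (or any table with the
#' same columns), solves the minimum-norm flux problem at every grid point
#' for every cultivar, and writes `fluxes_<cultivar>.tsv` plus edge tables
#' `edges_<cultivar>_w<week>.tsv` at the sampled weeks.
#'
#' @param config an `fx_config`; `config$constraints_file` may override the
#'   default location.
#' @param edge_weeks weeks at which edge tables are written (default the
#'   integer weeks 2, 6 and 12 if present on the grid).
#' @return (invisibly) list of `fx_series` per cultivar and written paths.
#' @export
run_solve <- function(config, edge_weeks = c(2, 6, 12)) {
  path <- config$constraints_file %||%
    file.path(config$output_dir, "flux_constraints.tsv")
  if (!file.exists(path)) {
    fx_error(sprintf("constraint table not found: %s", path),
             "fx_missing_file")
  }
  constraints <- read_tsv_table(path)
  network <- config_network(config)
  series <- solve_study(network, constraints, config$settings)

  hdr <- provenance_header(config)
  paths <- character(0)
  for (cv_name in names(series)) {
    ft <- flux_table(series[[cv_name]])
    p <- file.path(config$output_dir, sprintf("fluxes_%s.tsv", cv_name))
    write_tsv_with_header(ft, p, hdr)
    paths <- c(paths, p)
    for (wk in intersect(edge_weeks, series[[cv_name]]$weeks)) {
      sol <- series[[cv_name]]$solutions[[as.character(wk)]]
      if (is.null(sol)) next
      em <- export_flux_map(sol, network)
      pe <- file.path(config$output_dir,
                      sprintf("edges_%s_w%g.tsv", cv_name, wk))
      write_tsv_with_header(em, pe, hdr)
      paths <- c(paths, pe)
    }
  }
  invisible(list(series = series, paths = paths))
}

#' Materialize a synthetic study as CSV fixtures
#'
#' Writes `concentrations.csv`, `biometry.csv`, the noiseless truth tables
#' and a manifest with md5 content hashes into a directory.
#'
#' @param dir output directory.
#' @param scenario an `fx_scenario` (default [default_plantain_scenario()]).
#' @param seed integer seed.
#' @param cv noise coefficient of variation (default from scenario).
#' @param force overwrite a non-empty directory.
#' @return (invisibly) the manifest data.frame.
#' @export
make_fixtures <- function(dir, scenario = default_plantain_scenario(),
                          seed = 1L, cv = scenario$cv, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    fx_error(sprintf("output directory %s is not empty (use force = TRUE)",
                     dir), "fx_dir_not_empty")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(scenario, seed = seed, cv = cv)
  files <- c(concentrations = "concentrations.csv",
             biometry = "biometry.csv",
             truth_concentrations = "truth_concentrations.csv",
             truth_fluxes = "truth_fluxes.csv")
  tabs <- list(study$concentrations, study$biometry,
               study$truth$concentrations, study$truth$fluxes)
  for (i in seq_along(files)) {
    write.csv(tabs[[i]], file.path(dir, files[i]), row.names = FALSE,
              quote = FALSE)
  }
  manifest <- data.frame(file = unname(files),
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  write.csv(manifest, file.path(dir, "MANIFEST.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}
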