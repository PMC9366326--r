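#' @importFrom stats coef lm median pf predict pt quantile rnorm runif sd setNames var aggregate p.adjust cor
#' @importFrom utils read.delim read.csv write.table head
NULL

fx_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fx_error")))
}

#' Parse a reaction equation string
#'
#' Equations use the dialect `"2 A + B -> C"` (irreversible) or
#' `"A <-> B"` (reversible). Coefficients may be rational ("1/2") or decimal;
#' a missing coefficient means 1. One side may be empty, which denotes an
#' exchange with the system boundary (e.g. `"-> SUC_EXT"` imports,
#' `"CO2 ->"` exports).
#'
#' @param equation character scalar.
#' @return list with `stoichiometry` (named numeric, negative = consumed)
#'   and `reversible` (logical).
#' @keywords internal
parse_equation <- function(equation) {
  eq <- trimws(equation)
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- if (rev) strsplit(eq, "<->", fixed = TRUE)[[1]] else
    strsplit(eq, "->", fixed = TRUE)[[1]]
  if (!rev && !grepl("->", eq, fixed = TRUE) || length(sides) > 2) {
    fx_error(sprintf("malformed reaction equation: '%s'", equation),
             "fx_malformed_equation")
  }
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    if (grepl("^\\+|\\+$", side)) {
      fx_error(sprintf("malformed reaction equation: '%s'", equation),
               "fx_malformed_equation")
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      if (term == "") {
        fx_error(sprintf("malformed reaction equation: '%s'", equation),
                 "fx_malformed_equation")
      }
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coefv <- 1
        met <- parts[1]
      } else if (length(parts) == 2L) {
        coefv <- if (grepl("/", parts[1], fixed = TRUE)) {
          frac <- as.numeric(strsplit(parts[1], "/", fixed = TRUE)[[1]])
          frac[1] / frac[2]
        } else suppressWarnings(as.numeric(parts[1]))
        met <- parts[2]
      } else {
        fx_error(sprintf("malformed term '%s' in equation '%s'", term, equation),
                 "fx_malformed_equation")
      }
      if (is.na(coefv) || coefv == 0) {
        fx_error(sprintf("malformed coefficient in term '%s' of '%s'",
                         term, equation), "fx_malformed_equation")
      }
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coefv
      if (is.na(out[met])) out[met] <- sign * coefv
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (metab in names(rhs)) {
    st[metab] <- (if (metab %in% names(st)) st[metab] else 0) + rhs[metab]
  }
  st <- st[st != 0]
  list(stoichiometry = st, reversible = rev)
}

new_network <- function(metabolites, reactions) {
  structure(list(metabolites = metabolites, reactions = reactions),
            class = "fx_network")
}

#' Load a stoichiometric network from reaction and metabolite tables
#'
#' Reads the tab-delimited network description used throughout the package.
#' The reaction table must have columns `id`, `equation`, `kind`
#' (`interconversion` or `exchange`) and `subsystem`; an optional logical
#' column `carbon_exempt` marks reactions excluded from the carbon-balance
#' check. Reversibility is read from the arrow in the equation (`->`
#' irreversible, `<->` reversible). The metabolite table must have columns
#' `id`, `name`, `carbon_count` and `role` (`internal`, `accumulated` or
#' `nutrient`). Lines beginning with `#` are ignored in both files.
#'
#' Internal metabolites are strictly balanced at pseudo-steady state;
#' accumulated metabolites and nutrients are balanced too, but carry an
#' exchange reaction through which material enters or leaves the system, so
#' their net accumulation is explicit in the flux vector.
#'
#' @param reaction_file path to the reaction table (TSV).
#' @param metabolite_file path to the metabolite table (TSV).
#' @return an object of class `fx_network`.
#' @examples
#' net <- plantain_network()
#' net
#' @export
load_network <- function(reaction_file, metabolite_file) {
  mets <- read.delim(metabolite_file, comment.char = "#",
                     stringsAsFactors = FALSE)
  rxns <- read.delim(reaction_file, comment.char = "#",
                     stringsAsFactors = FALSE)
  req_m <- c("id", "name", "carbon_count", "role")
  req_r <- c("id", "equation", "kind", "subsystem")
  if (!all(req_m %in% names(mets))) {
    fx_error(paste("metabolite table must have columns",
                   paste(req_m, collapse = ", ")), "fx_bad_table")
  }
  if (!all(req_r %in% names(rxns))) {
    fx_error(paste("reaction table must have columns",
                   paste(req_r, collapse = ", ")), "fx_bad_table")
  }
  if (anyDuplicated(mets$id)) {
    fx_error("duplicate metabolite id in metabolite table",
             "fx_duplicate_metabolite")
  }
  if (anyDuplicated(rxns$id)) {
    fx_error(sprintf("duplicate reaction id: %s",
                     paste(unique(rxns$id[duplicated(rxns$id)]),
                           collapse = ", ")),
             "fx_duplicate_reaction")
  }
  if (!all(mets$role %in% c("internal", "accumulated", "nutrient"))) {
    fx_error("metabolite role must be internal, accumulated or nutrient",
             "fx_bad_role")
  }
  if (any(!is.finite(mets$carbon_count)) || any(mets$carbon_count < 0)) {
    fx_error("carbon_count must be a non-negative number", "fx_bad_carbon")
  }
  if (!"carbon_exempt" %in% names(rxns)) rxns$carbon_exempt <- FALSE
  rxns$carbon_exempt <- as.logical(rxns$carbon_exempt)

  reactions <- vector("list", nrow(rxns))
  for (i in seq_len(nrow(rxns))) {
    parsed <- parse_equation(rxns$equation[i])
    unknown <- setdiff(names(parsed$stoichiometry), mets$id)
    if (length(unknown)) {
      fx_error(sprintf("reaction '%s' references unknown metabolite(s): %s",
                       rxns$id[i], paste(unknown, collapse = ", ")),
               "fx_unknown_metabolite")
    }
    reactions[[i]] <- list(
      id = rxns$id[i],
      name = if ("name" %in% names(rxns)) rxns$name[i] else rxns$id[i],
      stoichiometry = parsed$stoichiometry,
      reversible = parsed$reversible,
      kind = rxns$kind[i],
      subsystem = rxns$subsystem[i],
      carbon_exempt = isTRUE(rxns$carbon_exempt[i])
    )
  }
  names(reactions) <- rxns$id
  net <- new_network(mets, reactions)
  validate_network(net)
  net
}

#' Validate a stoichiometric network
#'
#' Checks the structural invariants: every referenced metabolite is declared,
#' reaction kinds are valid, each exchange reaction touches exactly one
#' non-internal metabolite, interconversion reactions touch at least two
#' metabolites, and every internal metabolite takes part in at least two
#' reactions (a metabolite seen by a single reaction can never be balanced).
#'
#' @param network an `fx_network`.
#' @return the network, invisibly, if valid; otherwise an error.
#' @export
validate_network <- function(network) {
  mets <- network$metabolites
  role <- setNames(mets$role, mets$id)
  use_count <- setNames(integer(nrow(mets)), mets$id)
  for (rx in network$reactions) {
    if (!rx$kind %in% c("interconversion", "exchange")) {
      fx_error(sprintf("reaction '%s' has invalid kind '%s'", rx$id, rx$kind),
               "fx_bad_kind")
    }
    touched <- names(rx$stoichiometry)
    use_count[touched] <- use_count[touched] + 1L
    if (rx$kind == "exchange") {
      non_int <- touched[role[touched] != "internal"]
      if (length(touched) != 1L || length(non_int) != 1L) {
        fx_error(sprintf(
          "exchange reaction '%s' must touch exactly one non-internal metabolite",
          rx$id), "fx_bad_exchange")
      }
    } else if (length(touched) < 2L) {
      fx_error(sprintf("interconversion reaction '%s' touches < 2 metabolites",
                       rx$id), "fx_bad_interconversion")
    }
  }
  internal <- mets$id[mets$role == "internal"]
  lonely <- internal[use_count[internal] < 2L]
  if (length(lonely)) {
    fx_error(sprintf("internal metabolite(s) in fewer than 2 reactions: %s",
                     paste(lonely, collapse = ", ")), "fx_unbalanced_internal")
  }
  orphan <- mets$id[use_count == 0L]
  if (length(orphan)) {
    fx_error(sprintf("metabolite(s) not used by any reaction: %s",
                     paste(orphan, collapse = ", ")), "fx_orphan_metabolite")
  }
  invisible(network)
}

#' Stoichiometric matrix of a network
#'
#' @param network an `fx_network`.
#' @return numeric matrix S with one row per metabolite (in declaration
#'   order) and one column per reaction (in declaration order);
#'   `S[i, j]` is the signed coefficient of metabolite i in reaction j.
#' @examples
#' S <- stoichiometric_matrix(plantain_network())
#' dim(S)
#' @export
stoichiometric_matrix <- function(network) {
  mets <- network$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = length(network$reactions),
              dimnames = list(mets, names(network$reactions)))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Carbon balance report
#'
#' For every interconversion reaction not flagged `carbon_exempt`, computes
#' the net carbon Sum(coefficient x carbon_count); exchange reactions are
#' one-sided by construction and are skipped. A non-zero net carbon flags a
#' stoichiometry error.
#'
#' @param network an `fx_network`.
#' @param tol numeric tolerance on the carbon sum.
#' @return data.frame with columns `reaction`, `net_carbon`, `balanced`.
#' @examples
#' rep <- check_carbon_balance(plantain_network())
#' all(rep$balanced)
#' @export
check_carbon_balance <- function(network, tol = 1e-9) {
  carbon <- setNames(network$metabolites$carbon_count,
                     network$metabolites$id)
  rows <- list()
  for (rx in network$reactions) {
    if (rx$kind != "interconversion" || isTRUE(rx$carbon_exempt)) next
    mets <- names(rx$stoichiometry)
    if (any(is.na(carbon[mets]))) {
      fx_error(sprintf("missing carbon_count for metabolite(s) %s in '%s'",
                       paste(mets[is.na(carbon[mets])], collapse = ", "),
                       rx$id), "fx_missing_carbon")
    }
    net_c <- sum(rx$stoichiometry * carbon[mets])
    rows[[rx$id]] <- data.frame(reaction = rx$id, net_carbon = net_c,
                                balanced = abs(net_c) <= tol)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The packaged plantain central-metabolism network
#'
#' A curated non-compartmented network of central carbon and polyphenol
#' metabolism in plantain (Musa) fruit pulp: sucrose import and cleavage by
#' both the sucrose synthase and invertase routes, the hexose-phosphate pool,
#' starch synthesis plus phosphorolytic and hydrolytic breakdown, glycolysis,
#' the TCA cycle, the oxidative pentose phosphate pathway, oxidative
#' phosphorylation with a P/O-style ATP yield of 2.5 per NADH, a maintenance
#' ATPase, and accumulation sinks for every measured biomass component
#' (sugars, hexose phosphates, starch, malate, free amino acids, protein,
#' cell wall and polyphenols). ATP/ADP, NAD(P)H/NAD(P)+ and phosphate are
#' internal, i.e. strictly balanced, so the network is constrained through
#' its redox and energy status as well as through carbon.
#'
#' @return an `fx_network`.
#' @export
plantain_network <- function() {
  load_network(
    system.file("extdata", "plantain_reactions.tsv", package = "fruitflux",
                mustWork = TRUE),
    system.file("extdata", "plantain_metabolites.tsv", package = "fruitflux",
                mustWork = TRUE)
  )
}

#' @export
print.fx_network <- function(x, ...) {
  roles <- table(x$metabolites$role)
  kinds <- vapply(x$reactions, function(r) r$kind, character(1))
  cat("Stoichiometric network:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "),
      "\n")
  cat("  reactions:", sum(kinds == "interconversion"), "interconversion,",
      sum(kinds == "exchange"), "exchange\n")
  cat("  subsystems:", paste(sort(unique(vapply(x$reactions,
      function(r) r$subsystem, character(1)))), collapse = ", "), "\n")
  invisible(x)
}

# ids of exchange reactions attached to a given metabolite role
exchange_ids <- function(network, roles = c("accumulated", "nutrient")) {
  out <- character(0)
  role <- setNames(network$metabolites$role, network$metabolites$id)
  for (rx in network$reactions) {
    if (rx$kind != "exchange") next
    metab <- names(rx$stoichiometry)
    if (role[metab] %in% roles) out[metab] <- rx$id
  }
  out
}
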