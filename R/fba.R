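## Flux balance analysis and the nutrient-essentiality screen.
##
## Growth simulation solves
##     maximize v_b  subject to  S v = 0,  v_min <= v <= v_max
## with the biomass flux v_b read as the growth rate (1/h). Media act purely
## on exchange-reaction bounds: a maximal uptake of u becomes a lower bound
## of -u (uptake is negative flux under the "1 M_ext -> nothing" exchange
## convention), and removing a metabolite from the medium forces both bounds
## of its exchange reaction to zero. The single-removal screen marks a
## nutrient essential when the growth optimum falls below the cutoff
## (default 0.05 1/h, an estimate of gut microbial doubling requirements;
## uptake limit default 10 mmol/gDW/h).

#' Screen configuration
#'
#' @param uptake_limit maximal uptake per exchange reaction, mmol/gDW/h.
#' @param essentiality_cutoff growth rate (1/h) below which a removal marks
#'   the nutrient essential.
#' @param feasibility_tolerance componentwise tolerance on `S v = 0`.
#' @param removal `"both"` closes uptake and secretion of the removed
#'   metabolite (the literal protocol); `"uptake_only"` zeroes only the
#'   uptake direction.
#' @export
screen_config <- function(uptake_limit = 10, essentiality_cutoff = 0.05,
                          feasibility_tolerance = 1e-9,
                          removal = c("both", "uptake_only")) {
  removal <- match.arg(removal)
  stopifnot(is_number(uptake_limit), uptake_limit > 0,
            is_number(essentiality_cutoff), essentiality_cutoff > 0,
            is_number(feasibility_tolerance), feasibility_tolerance > 0)
  structure(list(uptake_limit = uptake_limit,
                 essentiality_cutoff = essentiality_cutoff,
                 feasibility_tolerance = feasibility_tolerance,
                 removal = removal),
            class = "screen_config")
}

## growth values within this absolute band are considered equal before the
## essentiality cutoff is applied
GROWTH_TOL <- 1e-6

#' Construct a growth medium
#'
#' @param max_uptake named nonnegative numeric: exchange reaction id ->
#'   maximal uptake (mmol/gDW/h).
#' @param closed exchange reaction ids whose flux is forced to zero.
#' @param removal closure mode inherited by [remove_metabolite()], see
#'   [screen_config()].
#' @export
medium <- function(max_uptake = numeric(), closed = character(),
                   removal = "both") {
  stopifnot(all(max_uptake >= 0))
  both <- intersect(names(max_uptake)[max_uptake > 0], closed)
  if (length(both))
    stop_validation("exchange(s) %s cannot be both open and closed",
                    paste(both, collapse = ", "))
  structure(list(max_uptake = max_uptake, closed = unique(closed),
                 removal = removal),
            class = "medium")
}

check_medium <- function(med, model) {
  ex <- exchange_ids(model)
  unknown <- setdiff(c(names(med$max_uptake), med$closed), ex)
  if (length(unknown))
    stop_validation("medium references non-exchange reaction(s): %s",
                    paste(unknown, collapse = ", "))
  invisible(med)
}

#' Rich medium: every exchange reaction open at the uptake limit
#'
#' @param model a valid `metabolic_model`.
#' @param config a [screen_config()].
#' @export
rich_medium <- function(model, config = screen_config()) {
  assert_valid_model(model)
  ex <- exchange_ids(model)
  medium(stats::setNames(rep(config$uptake_limit, length(ex)), ex),
         removal = config$removal)
}

#' Remove one metabolite from a medium
#'
#' Simulates the absence of a nutrient by closing its exchange reaction
#' (both bounds to zero by default). Returns a new medium; idempotent.
#'
#' @param med a [medium()].
#' @param model the target model.
#' @param metabolite_id id of an exchanged (extracellular) metabolite.
#' @export
remove_metabolite <- function(med, model, metabolite_id) {
  ex <- exchange_for_metabolite(model, metabolite_id)
  if (is.na(ex))
    stop_validation("metabolite '%s' has no exchange reaction in model '%s'",
                    metabolite_id, model$organism_id)
  mu <- med$max_uptake
  mu <- mu[setdiff(names(mu), ex)]
  medium(mu, closed = union(med$closed, ex), removal = med$removal)
}

## Apply a medium to model bounds. Exchange reactions named in max_uptake
## get lower bound -max_uptake; closed exchanges get [0, 0] ("both") or a
## zero lower bound ("uptake_only"); all other bounds come from the model.
apply_medium <- function(model, med) {
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  for (rid in names(med$max_uptake)) lb[rid] <- -med$max_uptake[[rid]]
  for (rid in med$closed) {
    lb[rid] <- 0
    if (!identical(med$removal, "uptake_only")) ub[rid] <- 0
  }
  list(lb = lb, ub = ub)
}

## Dead-end pruning: a metabolite appearing in a single reaction can never
## be balanced at nonzero flux, so that reaction is fixed to zero and
## dropped; zero-span reactions ([0,0]) are dropped likewise. Iterating to a
## fixed point removes entire dead branches before the LP is built, which
## keeps screen LPs small.
prune_network <- function(S, lb, ub) {
  keep <- rep(TRUE, ncol(S))
  repeat {
    active <- which(keep)
    if (length(active) == 0L) break
    drop_zero <- active[lb[active] == 0 & ub[active] == 0]
    nz <- S[, active, drop = FALSE] != 0
    use_count <- rowSums(nz)
    dead_mets <- which(use_count == 1L)
    drop_dead <- integer()
    if (length(dead_mets))
      drop_dead <- active[colSums(nz[dead_mets, , drop = FALSE]) > 0]
    drop <- union(drop_zero, drop_dead)
    if (length(drop) == 0L) break
    keep[drop] <- FALSE
  }
  keep
}

#' Solve the growth-maximization flux balance problem
#'
#' @param model a valid `metabolic_model`.
#' @param med a [medium()]; defaults to the rich medium.
#' @param config a [screen_config()].
#' @return a `flux_result`: `status`, `growth_rate` (the LP optimum, the
#'   only quantity stable under degenerate optima), and a full named flux
#'   vector (one of possibly many optimal vertices).
#' @export
solve_fba <- function(model, med = rich_medium(model, config),
                      config = screen_config()) {
  assert_valid_model(model)
  check_medium(med, model)
  S <- s_matrix(model)
  bounds <- apply_medium(model, med)
  lb <- bounds$lb; ub <- bounds$ub
  rids <- colnames(S)
  bio <- model$biomass_reaction_id

  keep <- prune_network(S, lb, ub)
  fluxes <- stats::setNames(rep(0, length(rids)), rids)
  if (any(!keep & lb > 0))
    ## a structurally blocked reaction with a strictly positive lower bound
    ## cannot carry its required flux
    return(structure(list(status = "infeasible", growth_rate = NA_real_,
                          fluxes = NULL), class = "flux_result"))
  if (!keep[match(bio, rids)]) {
    ## the biomass reaction itself is blocked: the optimum is 0
    return(structure(list(status = "optimal", growth_rate = 0,
                          fluxes = fluxes), class = "flux_result"))
  }

  Sr <- S[, keep, drop = FALSE]
  Sr <- Sr[rowSums(Sr != 0) > 0, , drop = FALSE]
  obj <- as.numeric(colnames(Sr) == bio)
  sol <- lp_bounded(obj, Sr, rep(0, nrow(Sr)), lb[keep], ub[keep],
                    maximize = TRUE)
  if (sol$status != "optimal")
    return(structure(list(status = sol$status, growth_rate = NA_real_,
                          fluxes = NULL), class = "flux_result"))

  fluxes[colnames(Sr)] <- sol$x
  res <- max(abs(S %*% fluxes))
  if (res > max(config$feasibility_tolerance, 1e-7))
    stop_runtime("FBA solution violates mass balance (|S v| = %g) for model '%s'",
                 res, model$organism_id)
  structure(list(status = "optimal",
                 growth_rate = fluxes[[bio]],
                 fluxes = fluxes),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> status = %s, growth_rate = %s\n", x$status,
              if (is.na(x$growth_rate)) "NA" else sprintf("%.6g", x$growth_rate)))
  invisible(x)
}

#' Single-removal nutrient essentiality screen
#'
#' Each exchanged metabolite is removed individually from the rich medium
#' and growth re-optimized; a nutrient is essential when growth falls below
#' the cutoff. An infeasible removal problem counts as growth 0.
#'
#' @param model a valid `metabolic_model` that grows on the rich medium
#'   (otherwise the screen is meaningless and an error is raised).
#' @param config a [screen_config()].
#' @return list with `essential` (sorted metabolite ids), `growth` (named
#'   growth rate per screened metabolite), and `baseline` (rich-medium
#'   growth rate).
#' @export
essential_nutrients <- function(model, config = screen_config()) {
  rich <- rich_medium(model, config)
  base <- solve_fba(model, rich, config)
  if (base$status != "optimal" ||
      base$growth_rate + GROWTH_TOL < config$essentiality_cutoff)
    stop_runtime(
      "baseline infeasible: model '%s' does not grow on the rich medium (growth %s < cutoff %g)",
      model$organism_id,
      if (base$status == "optimal") sprintf("%.4g", base$growth_rate) else base$status,
      config$essentiality_cutoff)

  mets <- sort(vapply(exchange_ids(model),
                      function(rid) exchanged_metabolite(model, rid),
                      character(1)))
  growth <- stats::setNames(numeric(length(mets)), mets)
  for (met in mets) {
    res <- solve_fba(model, remove_metabolite(rich, model, met), config)
    growth[[met]] <- if (res$status == "optimal") res$growth_rate else 0
  }
  essential <- names(growth)[growth + GROWTH_TOL < config$essentiality_cutoff]
  list(essential = essential, growth = growth, baseline = base$growth_rate)
}

#' Can the model grow without oxygen?
#'
#' Rich-medium growth with the oxygen exchange closed; a model with no
#' oxygen exchange at all is screened on the plain rich medium.
#'
#' @param model a valid `metabolic_model`.
#' @param oxygen_metabolite_id extracellular oxygen id (if any).
#' @param config a [screen_config()].
#' @return list with `capable` (logical) and `growth_rate`.
#' @export
check_anaerobic_growth <- function(model, oxygen_metabolite_id = "o2_e",
                                   config = screen_config()) {
  assert_valid_model(model)
  med <- rich_medium(model, config)
  if (!is.na(exchange_for_metabolite(model, oxygen_metabolite_id)))
    med <- remove_metabolite(med, model, oxygen_metabolite_id)
  res <- solve_fba(model, med, config)
  g <- if (res$status == "optimal") res$growth_rate else 0
  list(capable = g + GROWTH_TOL >= config$essentiality_cutoff, growth_rate = g)
}

#' Write a medium as TSV (exchange_id, max_uptake or "closed")
#' @export
write_medium_tsv <- function(med, path) {
  df <- rbind(
    data.frame(exchange_id = names(med$max_uptake),
               max_uptake = as.character(fmt_num(unname(med$max_uptake)))),
    data.frame(exchange_id = med$closed,
               max_uptake = rep("closed", length(med$closed))))
  df <- df[order(df$exchange_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a medium TSV written by [write_medium_tsv()]
#' @export
read_medium_tsv <- function(path) {
  df <- read_tsv_plain(path)
  closed <- df$exchange_id[df$max_uptake == "closed"]
  open <- df[df$max_uptake != "closed", , drop = FALSE]
  medium(stats::setNames(as.numeric(open$max_uptake), open$exchange_id),
         closed = closed)
}
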