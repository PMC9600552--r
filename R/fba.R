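#' Environment-limited uptake bounds
#'
#' Converts the metabolite amounts at one lattice site into per-unit flux
#' upper bounds for a population of `B` bacteria: `F_ub(i) = amount(i) /
#' (B / U)` with `U = 1e10` bacteria per population unit, so the summed
#' uptake of the whole population over one timestep can never exceed the
#' amount present. Water is available in unlimited quantity.
#'
#' @param local_amounts named numeric, umol of each metabolite at the site
#'   (base BiGG-style ids, e.g. `lcts`, `ac`, `o2`)
#' @param B population size in bacteria
#' @return named numeric of uptake bounds, umol per timestep per population
#'   unit, with `h2o = Inf`
#' @export
uptake_bounds <- function(local_amounts, B) {
  stopifnot(is.numeric(B), length(B) == 1L, B > 0)
  if (length(local_amounts) && any(local_amounts < -1e-12, na.rm = TRUE))
    stop("negative metabolite amounts at site")
  units <- B / POP_UNIT
  out <- pmax(local_amounts, 0) / units
  out[["h2o"]] <- Inf
  out
}

#' Default solver options
#'
#' The enzymatic constraint caps the sum over all reaction fluxes,
#' including exchange and objective columns. Both inclusions can be
#' switched off to audit their effect.
#'
#' @param sum_include_exchange include exchange columns in the summed-flux
#'   cap
#' @param sum_include_objective include the objective column in the cap
#' @return list of options for [solve_step()]
#' @export
fba_options <- function(sum_include_exchange = TRUE,
                        sum_include_objective = TRUE) {
  list(sum_include_exchange = sum_include_exchange,
       sum_include_objective = sum_include_objective)
}

#' Solve one FBA step for a population
#'
#' Maximizes flux through the ATP-production objective subject to internal
#' steady state (`S f = 0`, all fluxes >= 0 after the irreversible split),
#' the environment-limited uptake bounds, and the enzymatic constraint
#' `sum(f) <= a`. Among alternate optima the solution with minimal total
#' flux is returned, making secretion profiles deterministic.
#'
#' @param model a [compile_model()] object
#' @param B population size in bacteria (> 0)
#' @param bounds named uptake bounds from [uptake_bounds()]; metabolites
#'   absent from `bounds` are unavailable (bound 0) except water
#' @param a enzymatic constraint, umol flux per timestep per population
#'   unit (default 2 per 1e10 bacteria); `Inf` disables it
#' @param blocked_cols integer vector of compiled columns forced to zero
#'   (knockouts and exchange blocks; see [resolve_overrides()])
#' @param options see [fba_options()]
#' @return an object of class `gs_fba_result`: per-unit flux vector, net
#'   per-reaction fluxes, `growth_atp` (umol ATP per timestep per unit),
#'   `F_in`/`F_out` per extracellular metabolite, `sum_flux` and `status`
#' @export
solve_step <- function(model, B, bounds, a = 2, blocked_cols = integer(0),
                       options = fba_options()) {
  stopifnot(inherits(model, "gs_model"), B > 0, a > 0)
  ub <- model$col_ub
  ex <- model$exch
  up <- ex$direction == "in"
  avail <- rep(0, sum(up))
  met_in <- ex$met[up]
  hit <- match(met_in, names(bounds))
  avail[!is.na(hit)] <- unlist(bounds)[hit[!is.na(hit)]]
  avail[met_in == "h2o"] <- Inf
  ub[ex$col[up]] <- pmin(ub[ex$col[up]], avail / ex$coef[up])
  if (length(blocked_cols)) ub[blocked_cols] <- 0

  mask <- rep(1, ncol(model$S))
  if (!options$sum_include_exchange) mask[model$cols$kind == "exchange"] <- 0
  if (!options$sum_include_objective) mask[model$obj_col] <- 0

  sol <- fba_solve_cpp(model$S, ub, a, mask, model$obj_col)
  flux <- sol$flux
  if (sol$status != 0) {
    flux <- rep(0, ncol(model$S))
    warning("LP solve failed (status ", sol$status, ") for ",
            model$species_id, "; treating as zero growth")
  }
  fin <- fout <- numeric(0)
  if (!is.null(ex)) {
    v <- flux[ex$col] * ex$coef
    fin <- tapply(ifelse(ex$direction == "in", v, 0), ex$met, sum)
    fout <- tapply(ifelse(ex$direction == "out", v, 0), ex$met, sum)
    fin <- setNames(as.numeric(fin), names(fin))
    fout <- setNames(as.numeric(fout), names(fout))
  }
  structure(list(species_id = model$species_id,
                 flux = flux,
                 net = net_fluxes(model, flux),
                 growth_atp = if (sol$status == 0) sol$objective else 0,
                 F_in = fin, F_out = fout,
                 sum_flux = if (sol$status == 0) sol$sum_flux else 0,
                 status = if (sol$status == 0) "optimal" else "failed"),
            class = "gs_fba_result")
}

#' @export
print.gs_fba_result <- function(x, ...) {
  cat("<gs_fba_result> ", x$species_id, ": growth ",
      signif(x$growth_atp, 6), " umol ATP/step/unit, sum flux ",
      signif(x$sum_flux, 6), " (", x$status, ")\n", sep = "")
  net <- x$F_out - x$F_in[names(x$F_out)]
  net <- net[abs(net) > 1e-9]
  if (length(net)) {
    cat("  net exchange (umol/step/unit):\n")
    for (m in names(net)) cat(sprintf("    %-8s %+.4f\n", m, net[m]))
  }
  invisible(x)
}

#' Dose-response of growth and secretion to one metabolite
#'
#' Runs [solve_step()] on an isolated lattice site (0.05 mL by default)
#' across a concentration grid of one metabolite, holding any co-substrate
#' amounts fixed. Reports whole-population growth and net secretion per
#' timestep, the setting used for single-population concentration sweeps.
#'
#' @param model a [compile_model()] object
#' @param metabolite base id of the metabolite to sweep
#' @param grid non-negative, ascending concentrations in umol/mL
#' @param B population size in bacteria (default 5e9)
#' @param context named umol amounts of co-substrates at the site
#' @param a enzymatic constraint (umol/step/unit)
#' @param site_volume_ml site volume used to convert concentration to
#'   amount
#' @param options see [fba_options()]
#' @return data.frame with one row per concentration: `concentration`,
#'   `growth_atp` (umol/step, whole population), `growth_bacteria`
#'   (at 1e9 bacteria per umol ATP), and net secretion (umol/step,
#'   positive = secreted) for each extracellular metabolite
#' @export
dose_response <- function(model, metabolite, grid, B = 5e9,
                          context = numeric(0), a = 2,
                          site_volume_ml = 0.05,
                          options = fba_options()) {
  stopifnot(all(grid >= 0), !is.unsorted(grid))
  mets <- sort(unique(model$exch$met))
  out <- data.frame(concentration = numeric(0), growth_atp = numeric(0),
                    growth_bacteria = numeric(0))
  for (m in mets) out[[m]] <- numeric(0)
  units <- B / POP_UNIT
  for (conc in grid) {
    amounts <- c(context)[setdiff(names(context), metabolite)]
    if (is.null(amounts)) amounts <- numeric(0)
    amounts[metabolite] <- conc * site_volume_ml
    res <- solve_step(model, B, uptake_bounds(amounts, B), a = a,
                      options = options)
    row <- data.frame(concentration = conc,
                      growth_atp = res$growth_atp * units,
                      growth_bacteria = res$growth_atp * units * 1e9)
    for (m in mets)
      row[[m]] <- (res$F_out[[m]] - res$F_in[[m]]) * units
    out <- rbind(out, row)
  }
  out
}
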