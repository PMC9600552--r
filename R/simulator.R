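#' Simulation configuration
#'
#' Collects all model parameters with the standard defaults: 3-minute
#' timesteps (480 per day), a 225 x 8 lattice of 2 mm sites, 211 umol
#' lactose fed to the six proximal columns every 60 steps, metabolite
#' diffusion 4.4e-5 cm^2/s with one-column-per-step advection, an
#' enzymatic constraint of 2 umol flux per step per 1e10 bacteria, growth
#' of 1e9 bacteria per umol ATP, death probability 0.0075 per population
#' per step, colonization probability 5e-5 per empty site per step, and
#' initial seeding probability 0.3 at 5e7 bacteria per population.
#'
#' On rescaled lattices (`n != 1`) mixing sweeps are scaled by `1/n^2`
#' (constant population diffusion) and the seeding/colonization
#' probabilities by `n^2` (constant expected events per physical area).
#'
#' @param width,height,n lattice geometry (see [lattice_geometry()])
#' @param horizon number of timesteps (default 10080 = 21 days)
#' @param seed RNG seed for the run
#' @param feed a [feeding_schedule()]
#' @param oxygen an [oxygen_regime()]
#' @param roster named list of compiled models (default: the toy roster)
#' @param overrides list of override entries (see [resolve_overrides()])
#' @param a enzymatic constraint (umol flux/step/unit)
#' @param diffusion_D metabolite diffusion constant (cm^2/s)
#' @param yield bacteria per umol ATP
#' @param B0 initial/colonizer population size (bacteria)
#' @param div_threshold division threshold (bacteria)
#' @param max_B metabolism-suspension cap (bacteria)
#' @param death_prob,colonize_prob,init_prob stochastic rates
#' @param colonize_first_col_only,colonize_first_col_prob restrict
#'   colonization to the proximal column at a raised probability
#' @param mix_sweeps,mix_neighborhood,full_mix mixing controls
#' @param energies Gibbs formation energies (J/mol) for the in-run audit;
#'   defaults to the toy table when the toy roster is used
#' @param audit run the per-solve mass/energy audits
#' @param record_fluxes record per-step per-species exchange totals
#' @param record_spatial_every snapshot interval (steps); 0 disables
#' @param options see [fba_options()]
#' @return object of class `gs_config`
#' @export
sim_config <- function(width = NULL, height = NULL, n = 1,
                       horizon = 10080, seed = 1,
                       feed = feeding_schedule(),
                       oxygen = oxygen_regime("none"),
                       roster = NULL, overrides = list(),
                       a = 2, diffusion_D = 4.4e-5,
                       yield = 1e9, B0 = 5e7,
                       div_threshold = 1e10, max_B = 2e10,
                       death_prob = 0.0075, colonize_prob = 5e-5,
                       init_prob = 0.3,
                       colonize_first_col_only = FALSE,
                       colonize_first_col_prob = 0.01125,
                       mix_sweeps = 1,
                       mix_neighborhood = "neighbors8",
                       full_mix = FALSE,
                       energies = NULL, audit = TRUE,
                       record_fluxes = TRUE, record_spatial_every = 60,
                       options = fba_options()) {
  stopifnot(horizon >= 0, death_prob >= 0, death_prob <= 1,
            colonize_prob >= 0, colonize_prob <= 1,
            init_prob >= 0, init_prob <= 1, a > 0)
  structure(as.list(environment()), class = "gs_config")
}

#' @export
print.gs_config <- function(x, ...) {
  g <- lattice_geometry(x$width, x$height, x$n)
  cat("<gs_config> ", g$width, "x", g$height, " lattice, horizon ",
      x$horizon, " steps, seed ", x$seed, ", oxygen mode '",
      x$oxygen$mode, "', ", length(x$overrides), " override(s)\n", sep = "")
  invisible(x)
}

#' Resolve overrides to compiled-model columns
#'
#' An override entry is a list with fields `species` (character vector of
#' species ids or one of `"all"`, `"bifid"`, `"non_bifid"`,
#' `"facultative"`), optional `reactions` (ids whose columns are forced to
#' zero), optional `exchange` (data.frame with `met`, `direction`
#' "in"/"out"), and optional `from_step` (activation step, default 0).
#' "bifid" selects species carrying the phosphoketolase chain
#' (`R_F6PE4PL`); "facultative" selects non-bifid species with an oxygen
#' uptake exchange. Overrides only tighten bounds (to zero); reactions a
#' species does not have are skipped.
#'
#' @param models named list of compiled models
#' @param overrides list of override entries
#' @return per-species list of `(from_step, cols)` blocks
#' @export
resolve_overrides <- function(models, overrides) {
  is_bifid <- vapply(models, function(m) "R_F6PE4PL" %in% m$cols$rxn_id,
                     TRUE)
  has_o2_in <- vapply(models, function(m)
    !is.null(m$exch) && any(m$exch$met == "o2" & m$exch$direction == "in"),
    TRUE)
  out <- lapply(models, function(m) list())
  for (ov in overrides) {
    sel <- ov$species
    if (is.null(sel)) sel <- "all"
    ids <- names(models)
    keep <- if (identical(sel, "all")) ids
      else if (identical(sel, "bifid")) ids[is_bifid]
      else if (identical(sel, "non_bifid")) ids[!is_bifid]
      else if (identical(sel, "facultative")) ids[has_o2_in & !is_bifid]
      else intersect(sel, ids)
    for (id in keep) {
      m <- models[[id]]
      cols <- integer(0)
      if (!is.null(ov$reactions))
        cols <- c(cols, m$cols$col[m$cols$rxn_id %in% ov$reactions])
      if (!is.null(ov$exchange) && !is.null(m$exch)) {
        for (i in seq_len(nrow(ov$exchange)))
          cols <- c(cols, m$exch$col[
            m$exch$met == ov$exchange$met[i] &
            m$exch$direction == ov$exchange$direction[i]])
      }
      if (length(cols))
        out[[id]] <- c(out[[id]], list(list(
          from_step = if (is.null(ov$from_step)) 0 else ov$from_step,
          cols = sort(unique(cols)))))
    }
  }
  out
}

#' Install a named experiment into a configuration
#'
#' Supported experiments: `"bifid_shunt_ko"` (delete the phosphoketolase
#' reactions `R_PKL` and `R_F6PE4PL`), `"lactate_uptake_block"` (block
#' lactate uptake; `who` = "all" or "bifid"), `"lactate_production_block"`
#' (block lactate secretion by bifid species),
#' `"lactose_uptake_block_non_bifido"` (block lactose uptake by non-bifid
#' species from `from_step`, default 5040 = 10.5 days), and
#' `"o2_uptake_ko"` (block oxygen uptake by the facultative anaerobe).
#'
#' @param config a [sim_config()]
#' @param experiment experiment name
#' @param who species selector where applicable
#' @param from_step activation step for time-triggered blocks
#' @return the configuration with overrides installed
#' @export
apply_experiment <- function(config, experiment, who = NULL,
                             from_step = NULL) {
  ov <- switch(experiment,
    bifid_shunt_ko = list(species = "all",
                          reactions = c("R_PKL", "R_F6PE4PL")),
    lactate_uptake_block = list(
      species = if (is.null(who)) "all" else who,
      exchange = data.frame(met = c("lac_L", "lac_D"),
                            direction = "in", stringsAsFactors = FALSE)),
    lactate_production_block = list(
      species = if (is.null(who)) "bifid" else who,
      exchange = data.frame(met = c("lac_L", "lac_D"),
                            direction = "out", stringsAsFactors = FALSE)),
    lactose_uptake_block_non_bifido = list(
      species = "non_bifid",
      exchange = data.frame(met = "lcts", direction = "in",
                            stringsAsFactors = FALSE),
      from_step = if (is.null(from_step)) 5040 else from_step),
    o2_uptake_ko = list(
      species = if (is.null(who)) "facultative" else who,
      exchange = data.frame(met = "o2", direction = "in",
                            stringsAsFactors = FALSE)),
    stop("unknown experiment: ", experiment))
  if (!is.null(from_step) && is.null(ov$from_step)) ov$from_step <- from_step
  config$overrides <- c(config$overrides, list(ov))
  config
}

# per-species solver preparation (exchange index maps into the field rows)
.prep_species <- function(model, met_ids, energies) {
  ex <- model$exch
  up <- which(ex$direction == "in")
  dn <- which(ex$direction == "out")
  fm <- ext_formulas(model)
  fm[is.na(fm)] <- 0
  emet <- sort(unique(ex$met))
  # net exchange matrix: rows = this model's extracellular mets, cols = exch cols
  net_mat <- matrix(0, nrow = length(emet), ncol = nrow(ex),
                    dimnames = list(emet, NULL))
  for (i in seq_len(nrow(ex)))
    net_mat[ex$met[i], i] <- if (ex$direction[i] == "out") ex$coef[i]
                             else -ex$coef[i]
  evec <- rep(0, length(emet))
  hit <- match(emet, names(energies))
  evec[!is.na(hit)] <- energies[hit[!is.na(hit)]]
  have_e <- !is.na(hit)
  list(model = model,
       S = model$S, base_ub = model$col_ub, obj_col = model$obj_col,
       exch_cols = ex$col,
       in_cols = ex$col[up], in_coef = ex$coef[up],
       in_field_row = match(ex$met[up], met_ids),  # NA = water
       net_mat = net_mat,
       field_rows = match(emet, met_ids),
       elemT = t(fm[emet, , drop = FALSE]),
       evec = evec, have_e = have_e)
}

#' Run a full simulation
#'
#' Executes the per-timestep loop: feeding and oxygen input, one FBA
#' solve and growth update per population (sites hold at most one
#' population, so solves are independent), division, death/washout/
#' colonization, swap mixing, metabolite diffusion, and advection with
#' distal outflow recording. Deterministic given the seed.
#'
#' @param config a [sim_config()]
#' @return object of class `gs_run` with the configuration, species and
#'   metabolite ids, per-step abundance matrix, outflow matrix, optional
#'   per-step per-species exchange arrays (`flux_in`, `flux_out`),
#'   spatial snapshots, the population bookkeeping ledger, audit summary
#'   and mass-balance accumulators
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "gs_config"))
  set.seed(config$seed)
  geom <- lattice_geometry(config$width, config$height, config$n)
  models <- config$roster
  if (is.null(models)) models <- build_toy_models()
  n_sp <- length(models)
  sp_ids <- names(models)
  energies <- config$energies
  if (is.null(energies)) energies <- toy_gibbs_energies()

  met_ids <- sort(setdiff(unique(unlist(
    lapply(models, function(m) m$exch$met))), "h2o"))
  field <- new_field(geom, met_ids)
  nmet <- length(met_ids)

  prep <- lapply(models, .prep_species, met_ids = met_ids,
                 energies = energies)
  blocks <- resolve_overrides(models, config$overrides)

  scale2 <- geom$n^2
  diff_substeps <- floor(4 * config$diffusion_D * geom$dt_s /
                           geom$dx_cm^2) + 1L
  adv_per_step <- 1 / geom$n  # one default-size site per step
  adv_carry <- 0
  init_p <- min(1, config$init_prob * scale2)
  colonize_p <- if (config$colonize_first_col_only)
    min(1, config$colonize_first_col_prob * scale2)
    else min(1, config$colonize_prob * scale2)
  sweeps <- config$mix_sweeps / scale2
  offsets <- mix_offsets(config$mix_neighborhood)

  pop <- initialize_lattice(new_populations(geom), geom, n_sp,
                            p = init_p, B0 = config$B0)

  H <- config$horizon
  abundance <- matrix(0, nrow = H + 1, ncol = n_sp,
                      dimnames = list(NULL, sp_ids))
  abundance[1, ] <- vapply(seq_len(n_sp), function(k)
    sum(pop$biomass[which(pop$species == k)]), 0)
  outflow <- matrix(0, nrow = max(H, 1), ncol = nmet,
                    dimnames = list(NULL, met_ids))[seq_len(H), , drop = FALSE]
  rec_flux <- isTRUE(config$record_fluxes)
  if (rec_flux) {
    flux_in <- array(0, dim = c(H, n_sp, nmet),
                     dimnames = list(NULL, sp_ids, met_ids))
    flux_out <- flux_in
  }
  pop_ledger <- matrix(0, nrow = H, ncol = 5,
    dimnames = list(NULL, c("growth_B", "died_B", "washed_B",
                            "colonized_n", "colonized_B")))
  snapshots <- list()
  audit_on <- isTRUE(config$audit)
  audit <- list(n_solves = 0L, n_elem_viol = 0L, max_elem = 0,
                n_energy_viol = 0L, energy_viol_growth_max = 0,
                n_failed = 0L)
  fed_total <- setNames(numeric(nmet), met_ids)
  o2_added <- 0
  net_exchange_total <- setNames(numeric(nmet), met_ids)
  outflow_total <- setNames(numeric(nmet), met_ids)

  for (t in seq_len(H) - 1L) {
    before_feed <- if (config$feed$metabolite %in% met_ids)
      sum(field$amounts[config$feed$metabolite, ]) else 0
    field <- feed(field, config$feed, t)
    if (config$feed$metabolite %in% met_ids)
      fed_total[config$feed$metabolite] <-
        fed_total[config$feed$metabolite] +
        (sum(field$amounts[config$feed$metabolite, ]) - before_feed)
    if (config$oxygen$mode != "none" && "o2" %in% met_ids) {
      b <- sum(field$amounts["o2", ])
      field <- apply_oxygen(field, config$oxygen, t)
      o2_added <- o2_added + sum(field$amounts["o2", ]) - b
    }

    occ <- which(!is.na(pop$species))
    if (length(occ) > 1) occ <- occ[sample.int(length(occ))]
    for (s in occ) {
      B <- pop$biomass[s]
      if (B >= config$max_B) next  # ceased metabolism
      k <- pop$species[s]
      pr <- prep[[k]]
      units <- B / POP_UNIT
      ub <- pr$base_ub
      avail <- rep(Inf, length(pr$in_cols))
      fr <- pr$in_field_row
      avail[!is.na(fr)] <- field$amounts[fr[!is.na(fr)], s]
      ub[pr$in_cols] <- pmin(ub[pr$in_cols], avail / units / pr$in_coef)
      for (blk in blocks[[k]]) if (t >= blk$from_step) ub[blk$cols] <- 0
      sol <- fba_solve_cpp(pr$S, ub, config$a, rep(1, ncol(pr$S)),
                           pr$obj_col)
      if (sol$status != 0) { audit$n_failed <- audit$n_failed + 1L; next }
      fl <- sol$flux[pr$exch_cols]
      net <- drop(pr$net_mat %*% fl)  # per-unit, this model's ext mets
      rows_ok <- !is.na(pr$field_rows)
      delta <- net[rows_ok] * units
      fr2 <- pr$field_rows[rows_ok]
      old <- field$amounts[fr2, s]
      newv <- old + delta
      newv[newv < 0] <- 0  # clip LP rounding residue
      field$amounts[fr2, s] <- newv
      net_exchange_total[fr2] <- net_exchange_total[fr2] + (newv - old)
      if (rec_flux) {
        pos <- pmax(delta, 0); neg <- pmax(-delta, 0)
        flux_out[t + 1L, k, fr2] <- flux_out[t + 1L, k, fr2] + pos
        flux_in[t + 1L, k, fr2] <- flux_in[t + 1L, k, fr2] + neg
      }
      if (audit_on) {
        audit$n_solves <- audit$n_solves + 1L
        elem <- drop(pr$elemT %*% net)
        me <- max(abs(elem))
        if (me > audit$max_elem) {
          audit$max_elem <- me
          audit$worst_solve <- list(step = t, species = sp_ids[k], B = B,
                                    amounts = setNames(avail, names(pr$in_cols)),
                                    ub = ub, elem = elem)
        }
        if (me > 1e-8) audit$n_elem_viol <- audit$n_elem_viol + 1L
        l <- sum(net[pr$have_e] * pr$evec[pr$have_e])
        if (l > 1e-6 || (l > -1e-6 && sol$objective > 1e-9)) {
          audit$n_energy_viol <- audit$n_energy_viol + 1L
          audit$energy_viol_growth_max <-
            max(audit$energy_viol_growth_max, sol$objective)
        }
      }
      newB <- grow(B, sol$objective, config$yield, config$max_B)
      pop_ledger[t + 1L, "growth_B"] <- pop_ledger[t + 1L, "growth_B"] +
        (newB - B)
      pop$biomass[s] <- newB
    }

    pop <- divide_populations(pop, geom, config$div_threshold)
    kc <- kill_and_colonize(pop, geom, n_sp,
                            death_p = config$death_prob,
                            colonize_p = colonize_p, B0 = config$B0,
                            first_col_only = config$colonize_first_col_only)
    pop <- kc$pop
    pop_ledger[t + 1L, "died_B"] <- kc$died_biomass
    pop_ledger[t + 1L, "washed_B"] <- kc$washed_biomass
    pop_ledger[t + 1L, "colonized_n"] <- kc$n_colonized
    pop_ledger[t + 1L, "colonized_B"] <- kc$n_colonized * config$B0

    pop <- mix_populations(pop, geom, sweeps, offsets,
                           full = config$full_mix)$pop
    field <- diffuse(field, config$diffusion_D, diff_substeps)
    adv_carry <- adv_carry + adv_per_step
    adv <- advect(field, floor(adv_carry))
    adv_carry <- adv_carry - floor(adv_carry)
    field <- adv$field
    outflow[t + 1L, ] <- adv$outflow
    outflow_total <- outflow_total + adv$outflow

    for (k in seq_len(n_sp))
      abundance[t + 2L, k] <- sum(pop$biomass[which(pop$species == k)])
    if (config$record_spatial_every > 0 &&
        (t + 1L) %% config$record_spatial_every == 0) {
      colidx <- rep(seq_len(geom$width), each = geom$height)
      bm <- matrix(0, nrow = n_sp, ncol = geom$width,
                   dimnames = list(sp_ids, NULL))
      occ <- which(!is.na(pop$species))
      for (s in occ)
        bm[pop$species[s], colidx[s]] <- bm[pop$species[s], colidx[s]] +
          pop$biomass[s]
      fld <- t(rowsum(t(field$amounts), colidx))
      snapshots[[length(snapshots) + 1L]] <-
        list(step = t + 1L, biomass_by_col = bm, field_by_col = fld)
    }
  }

  structure(list(
    config = config, geom = geom, species = sp_ids, met_ids = met_ids,
    abundance = abundance, outflow = outflow,
    flux_in = if (rec_flux) flux_in else NULL,
    flux_out = if (rec_flux) flux_out else NULL,
    snapshots = snapshots, pop_ledger = pop_ledger,
    audit = audit,
    mass = list(fed = fed_total, o2_added = o2_added,
                outflow = outflow_total,
                net_exchange = net_exchange_total,
                field_final = rowSums(field$amounts)),
    final = list(populations = pop, field = field)),
    class = "gs_run")
}

#' @export
print.gs_run <- function(x, ...) {
  H <- nrow(x$abundance) - 1
  cat("<gs_run> ", x$geom$width, "x", x$geom$height, " lattice, ", H,
      " steps, seed ", x$config$seed, "\n", sep = "")
  ab <- x$abundance[H + 1, ]
  cat("  final abundance (bacteria):\n")
  for (s in names(sort(ab, decreasing = TRUE)))
    cat(sprintf("    %-10s %.3g\n", s, ab[[s]]))
  if (!is.null(x$audit) && x$audit$n_solves > 0)
    cat("  audit: ", x$audit$n_solves, " solves, ",
        x$audit$n_elem_viol, " element violations (max |net| ",
        signif(x$audit$max_elem, 3), " umol), ",
        x$audit$n_energy_viol, " energy violations\n", sep = "")
  invisible(x)
}

#' Per-metabolite mass balance of a run
#'
#' Checks `fed + released - outflow - delta(lattice) + net bacterial
#' exchange = 0` for every tracked metabolite (water is symbolic and
#' excluded). Residuals should be at solver-tolerance scale.
#'
#' @param record a [run_simulation()] result
#' @return data.frame with inputs, outputs and the residual per metabolite
#' @export
mass_balance_report <- function(record) {
  m <- record$mass
  inputs <- m$fed
  if ("o2" %in% names(inputs)) inputs[["o2"]] <- inputs[["o2"]] + m$o2_added
  residual <- inputs + m$net_exchange - m$outflow - m$field_final
  data.frame(metabolite = names(inputs),
             input_umol = as.numeric(inputs),
             net_exchange_umol = as.numeric(m$net_exchange),
             outflow_umol = as.numeric(m$outflow),
             lattice_final_umol = as.numeric(m$field_final),
             residual_umol = as.numeric(residual),
             stringsAsFactors = FALSE)
}

#' Run replicate simulations
#'
#' Replicates differ only by seed (`base_seed + 0:(n_rep-1)`).
#'
#' @param config a [sim_config()]
#' @param n_rep number of replicates
#' @param base_seed first seed (default: the config seed)
#' @return list of `gs_run` records
#' @export
run_replicates <- function(config, n_rep, base_seed = NULL) {
  if (is.null(base_seed)) base_seed <- config$seed
  lapply(seq_len(n_rep), function(i) {
    cfg <- config
    cfg$seed <- base_seed + i - 1L
    run_simulation(cfg)
  })
}
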