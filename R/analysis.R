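# Summary artifacts derived from run records: fecal output composition,
# cross-feeding networks, spatial profiles, population diffusion and
# replicate dominance statistics.

#' Fecal output composition
#'
#' Aggregates the distal outflow over the last `window` timesteps
#' (default 960 = 2 days) into molar fractions and concentrations. The
#' concentration assumes each of the `height` exiting sites carries its
#' site volume (0.05 mL) of water per step, so mM = umol / (height *
#' site_volume * window).
#'
#' @param record a [run_simulation()] result
#' @param window number of trailing steps to aggregate
#' @param pool_lactate report d- and l-lactate as one `lac` row
#' @return data.frame with `metabolite`, `amount_umol`, `fraction`, `mM`
#' @export
fecal_composition <- function(record, window = 960, pool_lactate = TRUE) {
  H <- nrow(record$outflow)
  if (window > H) stop("run shorter than requested window")
  if (window == 0 || H == 0)
    return(data.frame(metabolite = character(0), amount_umol = numeric(0),
                      fraction = numeric(0), mM = numeric(0)))
  rows <- seq.int(H - window + 1L, H)
  amt <- colSums(record$outflow[rows, , drop = FALSE])
  if (pool_lactate && any(names(amt) %in% c("lac_L", "lac_D"))) {
    lac <- sum(amt[names(amt) %in% c("lac_L", "lac_D")])
    amt <- amt[!names(amt) %in% c("lac_L", "lac_D")]
    amt <- c(amt, lac = lac)
  }
  vol_ml <- record$geom$height * record$geom$site_volume_ml * window
  total <- sum(amt)
  data.frame(metabolite = names(amt),
             amount_umol = as.numeric(amt),
             fraction = if (total > 0) as.numeric(amt) / total
                        else rep(0, length(amt)),
             mM = as.numeric(amt) / vol_ml,
             stringsAsFactors = FALSE)
}

#' Cross-feeding network over a time window
#'
#' Sums each species' production and consumption of each metabolite over
#' the window and keeps edges at or above the display threshold (0.5 umol,
#' no normalization). Production edges run species -> metabolite,
#' consumption edges metabolite -> species.
#'
#' @param record a [run_simulation()] result with `record_fluxes = TRUE`
#' @param window integer vector of steps (default: all recorded steps)
#' @param threshold minimum edge weight in umol
#' @return data.frame with `from`, `to`, `species`, `metabolite`, `type`,
#'   `weight`
#' @export
crossfeeding_network <- function(record, window = NULL, threshold = 0.5) {
  if (is.null(record$flux_out))
    stop("run was recorded without fluxes; set record_fluxes = TRUE")
  H <- dim(record$flux_out)[1]
  if (is.null(window)) window <- seq_len(H)
  stopifnot(all(window >= 1), all(window <= H))
  edges <- data.frame(from = character(0), to = character(0),
                      species = character(0), metabolite = character(0),
                      type = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  prod <- apply(record$flux_out[window, , , drop = FALSE], c(2, 3), sum)
  cons <- apply(record$flux_in[window, , , drop = FALSE], c(2, 3), sum)
  for (sp in rownames(prod)) for (m in colnames(prod)) {
    if (prod[sp, m] >= threshold)
      edges <- rbind(edges, data.frame(
        from = sp, to = m, species = sp, metabolite = m,
        type = "production", weight = prod[sp, m],
        stringsAsFactors = FALSE))
    if (cons[sp, m] >= threshold)
      edges <- rbind(edges, data.frame(
        from = m, to = sp, species = sp, metabolite = m,
        type = "consumption", weight = cons[sp, m],
        stringsAsFactors = FALSE))
  }
  rownames(edges) <- NULL
  edges
}

#' Spatial profiles of metabolites and species
#'
#' Per-column means and standard deviations over the spatial snapshots
#' falling inside the window.
#'
#' @param record a [run_simulation()] result
#' @param window integer step range (default: all snapshots)
#' @return data.frame with `kind` ("species"/"metabolite"), `id`,
#'   `column`, `mean`, `sd`
#' @export
spatial_profiles <- function(record, window = NULL) {
  snaps <- record$snapshots
  if (!is.null(window))
    snaps <- Filter(function(s) s$step >= min(window) &&
                                s$step <= max(window), snaps)
  if (!length(snaps)) stop("no spatial snapshots in window")
  out <- NULL
  agg <- function(kind, mats) {
    ids <- rownames(mats[[1]])
    for (i in seq_along(ids)) {
      v <- vapply(mats, function(m) m[i, ], numeric(ncol(mats[[1]])))
      v <- matrix(v, ncol = length(mats))
      out <<- rbind(out, data.frame(
        kind = kind, id = ids[i], column = seq_len(nrow(v)),
        mean = rowMeans(v),
        sd = if (ncol(v) > 1) apply(v, 1, sd) else rep(0, nrow(v)),
        stringsAsFactors = FALSE))
    }
  }
  agg("species", lapply(snaps, `[[`, "biomass_by_col"))
  agg("metabolite", lapply(snaps, `[[`, "field_by_col"))
  rownames(out) <- NULL
  out
}

#' Estimate a diffusion constant from tracer trajectories
#'
#' Fits mean squared displacement against `2 * k * D * t` (k = number of
#' axes used) through the origin. On the elongated default lattice the
#' short transverse axis saturates within a few sweeps, so the proximal-
#' distal axis alone (`axes = "x"`) gives the unbiased estimate.
#'
#' @param tracks a [run_tracer()] result
#' @param axes which displacement axes to use ("x", "y", or c("x","y"))
#' @return diffusion constant in cm^2/s
#' @export
estimate_diffusion <- function(tracks, axes = "x") {
  steps <- nrow(tracks$x) - 1L
  if (steps < 2) stop("trajectory too short to fit a diffusion constant")
  geom <- tracks$geom
  msd <- numeric(steps)
  for (t in seq_len(steps)) {
    s <- 0
    if ("x" %in% axes)
      s <- s + mean((tracks$x[t + 1L, ] - tracks$x[1L, ])^2)
    if ("y" %in% axes)
      s <- s + mean((tracks$y[t + 1L, ] - tracks$y[1L, ])^2)
    msd[t] <- s * geom$dx_cm^2
  }
  k <- length(axes)
  tt <- seq_len(steps) * geom$dt_s
  unname(coef(lm(msd ~ 0 + I(2 * k * tt)))[1])
}

#' Dominance summary over replicates
#'
#' Counts, per species (or species group), the replicates in which it is
#' the most abundant at the end of the run, and collects the final
#' abundances for distribution inspection.
#'
#' @param records list of [run_simulation()] results
#' @param groups optional named character vector mapping species id ->
#'   group label (species sharing a label are pooled)
#' @return list with `counts` (named integer) and `final_abundance`
#'   (replicates x groups matrix)
#' @export
dominance_summary <- function(records, groups = NULL) {
  stopifnot(length(records) >= 1)
  sp <- records[[1]]$species
  if (is.null(groups)) groups <- setNames(sp, sp)
  glab <- unique(unname(groups[sp]))
  fin <- t(vapply(records, function(r) {
    ab <- r$abundance[nrow(r$abundance), ]
    vapply(glab, function(g) sum(ab[names(groups)[groups == g]]), 0)
  }, numeric(length(glab))))
  colnames(fin) <- glab
  winners <- glab[apply(fin, 1, which.max)]
  counts <- setNames(integer(length(glab)), glab)
  for (w in winners) counts[w] <- counts[w] + 1L
  list(counts = counts, final_abundance = fin)
}
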