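#' Lattice geometry
#'
#' The default geometry discretizes a 450 mm x 16 mm infant colon into
#' 225 x 8 sites of 2 mm side, 0.05 mL each (90 mL total). The scaling
#' factor `n` multiplies the site side length; width and height are then
#' re-derived from the physical dimensions and dependent stochastic rates
#' are scaled by `1/n^2` elsewhere. Explicit `width`/`height` override the
#' physical dimensions for reduced desk-scale runs.
#'
#' @param width,height lattice size in sites (proximal -> distal is the
#'   width axis)
#' @param n scaling factor of the site side length
#' @param dx_mm site side length before scaling
#' @param dt_s timestep in seconds
#' @return list with fields `width`, `height`, `n`, `dx_cm`, `dt_s`,
#'   `site_volume_ml`, `n_sites`
#' @export
lattice_geometry <- function(width = NULL, height = NULL, n = 1,
                             dx_mm = 2, dt_s = 180) {
  dx <- dx_mm * n
  if (is.null(width)) width <- max(1L, as.integer(round(450 / dx)))
  if (is.null(height)) height <- max(1L, as.integer(round(16 / dx)))
  list(width = as.integer(width), height = as.integer(height), n = n,
       dx_cm = dx / 10, dt_s = dt_s,
       site_volume_ml = 0.05 * n^2,
       n_sites = as.integer(width) * as.integer(height))
}

site_index <- function(geom, x, y) (x - 1L) * geom$height + y
site_xy <- function(geom, s) {
  cbind(x = (s - 1L) %/% geom$height + 1L, y = (s - 1L) %% geom$height + 1L)
}

#' Create an empty metabolite field
#'
#' Amounts are umol per site. Water is treated symbolically (always
#' unlimited) and is not part of the field. Oxygen diffuses but does not
#' advect.
#'
#' @param geom a [lattice_geometry()]
#' @param met_ids base metabolite ids tracked on the lattice
#' @return object of class `gs_field`: amounts matrix (metabolites x
#'   sites), advection flags, geometry
#' @export
new_field <- function(geom, met_ids) {
  met_ids <- setdiff(met_ids, "h2o")
  structure(list(
    geom = geom,
    met_ids = met_ids,
    advecting = setNames(met_ids != "o2", met_ids),
    amounts = matrix(0, nrow = length(met_ids), ncol = geom$n_sites,
                     dimnames = list(met_ids, NULL))),
    class = "gs_field")
}

#' Feeding schedule
#'
#' A pulse of `amount` umol of `metabolite` is split equally over the
#' sites of the `columns` most proximal lattice columns every `period`
#' timesteps (defaults: 211 umol lactose every 60 steps = 3 h into the
#' first 6 columns).
#'
#' @param metabolite base id of the fed metabolite
#' @param amount umol per pulse
#' @param period timesteps between pulses
#' @param columns number of proximal target columns at the default site
#'   size (rescaled with geometry so the fed region keeps its physical
#'   length)
#' @return feeding schedule list
#' @export
feeding_schedule <- function(metabolite = "lcts", amount = 211,
                             period = 60, columns = 6) {
  list(metabolite = metabolite, amount = amount, period = period,
       columns = columns)
}

#' Apply the feeding pulse for timestep `t`
#'
#' @param field a `gs_field`
#' @param schedule a [feeding_schedule()]
#' @param t timestep (0-based; the first pulse lands at t = 0)
#' @return the updated field
#' @export
feed <- function(field, schedule, t) {
  stopifnot(t >= 0)
  if (t %% schedule$period != 0) return(field)
  geom <- field$geom
  ncols <- max(1L, min(geom$width, as.integer(round(schedule$columns / geom$n))))
  sites <- as.vector(outer(seq_len(geom$height),
                           (seq_len(ncols) - 1L) * geom$height, `+`))
  per_site <- schedule$amount / length(sites)
  field$amounts[schedule$metabolite, sites] <-
    field$amounts[schedule$metabolite, sites] + per_site
  field
}

#' One forward-Euler diffusion step
#'
#' Five-point Laplacian with no-flux (reflecting) walls; all metabolites
#' share one diffusion constant. Total amount is conserved to machine
#' precision. The scheme requires `4 D dt / dx^2 < 1` (0.792 at default
#' parameters).
#'
#' @param field a `gs_field`
#' @param D diffusion constant in cm^2/s (default 4.4e-5)
#' @param substeps number of Euler substeps; the stability condition is
#'   enforced per substep ([run_simulation()] picks the smallest stable
#'   count automatically, which is 1 at default geometry)
#' @return the updated field
#' @export
diffuse <- function(field, D = 4.4e-5, substeps = 1) {
  geom <- field$geom
  coef <- D * (geom$dt_s / substeps) / geom$dx_cm^2
  if (4 * coef >= 1)
    stop("diffusion step unstable: 4*D*dt/dx^2 = ", signif(4 * coef, 4),
         " >= 1; reduce D, refine the timestep or add substeps")
  h <- geom$height; w <- geom$width
  for (s in seq_len(substeps)) {
    for (k in seq_len(nrow(field$amounts))) {
      m <- matrix(field$amounts[k, ], nrow = h)
      up    <- rbind(m[1, , drop = FALSE], m[-h, , drop = FALSE])
      down  <- rbind(m[-1, , drop = FALSE], m[h, , drop = FALSE])
      left  <- cbind(m[, 1, drop = FALSE], m[, -w, drop = FALSE])
      right <- cbind(m[, -1, drop = FALSE], m[, w, drop = FALSE])
      field$amounts[k, ] <-
        as.vector(m + coef * (up + down + left + right - 4 * m))
    }
  }
  field
}

#' One advection step with distal outflow
#'
#' All advecting metabolites move one column toward the distal end; the
#' content of the last column leaves the system and is returned as the
#' outflow record. Oxygen (and any other non-advecting metabolite) stays
#' in place. The proximal column is refilled with zeros.
#'
#' @param field a `gs_field`
#' @param columns number of columns to shift this step (rescaled lattices
#'   preserve the physical advection speed of one default site per step)
#' @return list with the updated `field` and `outflow`, a named numeric of
#'   umol removed per metabolite
#' @export
advect <- function(field, columns = 1) {
  geom <- field$geom
  h <- geom$height; w <- geom$width
  outflow <- setNames(numeric(length(field$met_ids)), field$met_ids)
  if (columns < 1) return(list(field = field, outflow = outflow))
  k_shift <- min(as.integer(columns), w)
  for (k in which(field$advecting)) {
    m <- matrix(field$amounts[k, ], nrow = h)
    outflow[k] <- sum(m[, seq.int(w - k_shift + 1L, w)])
    field$amounts[k, ] <- as.vector(cbind(
      matrix(0, h, k_shift), m[, seq_len(w - k_shift), drop = FALSE]))
  }
  list(field = field, outflow = outflow)
}

#' Oxygen regime
#'
#' Either a one-off uniform deposition at t = 0 (`initial_uniform`, amount
#' in umol per site), or a continuous release split over the top and
#' bottom lattice rows (`boundary_release`, total umol per step, optionally
#' stopping at `stop_step`), or `none`.
#'
#' @param mode one of `"none"`, `"initial_uniform"`, `"boundary_release"`
#' @param amount umol per site (`initial_uniform`) or total umol per step
#'   (`boundary_release`)
#' @param stop_step first step at which a boundary release no longer
#'   occurs (`Inf` = never stops)
#' @return oxygen regime list
#' @export
oxygen_regime <- function(mode = c("none", "initial_uniform",
                                   "boundary_release"),
                          amount = 0, stop_step = Inf) {
  mode <- match.arg(mode)
  list(mode = mode, amount = amount, stop_step = stop_step)
}

#' Apply the oxygen regime at timestep `t`
#'
#' @param field a `gs_field`
#' @param regime an [oxygen_regime()]
#' @param t timestep (0-based)
#' @return the updated field
#' @export
apply_oxygen <- function(field, regime, t) {
  if (regime$mode == "none" || !"o2" %in% field$met_ids) return(field)
  if (regime$mode == "initial_uniform") {
    if (t == 0) field$amounts["o2", ] <- field$amounts["o2", ] + regime$amount
  } else if (regime$mode == "boundary_release") {
    if (t < regime$stop_step) {
      geom <- field$geom
      top <- site_index(geom, seq_len(geom$width), 1L)
      bottom <- site_index(geom, seq_len(geom$width), geom$height)
      sites <- unique(c(top, bottom))
      field$amounts["o2", sites] <- field$amounts["o2", sites] +
        regime$amount / (2 * geom$width)
    }
  }
  field
}
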