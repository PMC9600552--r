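# Population layer: one population per lattice site, stored as two parallel
# vectors over sites (species index, NA = empty; biomass in bacteria).

#' Create an empty population layer
#' @param geom a [lattice_geometry()]
#' @return list with `species` (integer, NA = empty) and `biomass`
#' @export
new_populations <- function(geom) {
  list(species = rep(NA_integer_, geom$n_sites),
       biomass = rep(0, geom$n_sites))
}

#' Seed initial populations
#'
#' Each site independently acquires a population of a uniformly random
#' roster species with probability `p` (default 0.3, i.e. an average of
#' 540 populations on the default 225 x 8 lattice, a total load of about
#' 2.7e10 bacteria at 5e7 per population).
#'
#' @param pop a [new_populations()] layer
#' @param geom lattice geometry
#' @param n_species roster size
#' @param p per-site seeding probability
#' @param B0 initial population size in bacteria
#' @return the seeded layer
#' @export
initialize_lattice <- function(pop, geom, n_species, p = 0.3, B0 = 5e7) {
  stopifnot(n_species >= 1, p >= 0, p <= 1)
  hit <- runif(geom$n_sites) < p
  pop$species[hit] <- sample.int(n_species, sum(hit), replace = TRUE)
  pop$biomass[hit] <- B0
  pop
}

#' Grow a population by its FBA outcome
#'
#' Whole-population ATP production is the per-unit objective value times
#' the population size in units of 1e10 bacteria; growth converts it at
#' `yield` bacteria per umol ATP (default 1e9, i.e. 10 umol ATP per 1e10
#' bacteria). Growth is capped at `max_B`.
#'
#' @param B population size in bacteria
#' @param growth_atp per-unit objective value (umol ATP/step/unit)
#' @param yield bacteria per umol ATP
#' @param max_B hard cap (division-starved populations stop at 2e10)
#' @return new population size
#' @export
grow <- function(B, growth_atp, yield = 1e9, max_B = 2e10) {
  min(B + growth_atp * (B / POP_UNIT) * yield, max_B)
}

#' Division sweep
#'
#' Every population at or above the division threshold (200x the initial
#' size, i.e. 1e10 bacteria) that has at least one empty von Neumann
#' neighbor transfers half of its size to a uniformly chosen empty
#' neighbor. Total biomass is preserved exactly. Populations that cannot
#' divide keep growing until the 2e10 cap, beyond which their metabolism
#' is suspended (handled by the caller skipping the FBA solve).
#'
#' @param pop population layer
#' @param geom lattice geometry
#' @param threshold division threshold in bacteria
#' @return updated layer
#' @export
divide_populations <- function(pop, geom, threshold = 1e10) {
  ready <- which(!is.na(pop$species) & pop$biomass >= threshold)
  if (!length(ready)) return(pop)
  ready <- ready[sample.int(length(ready))]
  h <- geom$height; w <- geom$width
  for (s in ready) {
    x <- (s - 1L) %/% h + 1L; y <- (s - 1L) %% h + 1L
    nb <- c(if (x > 1L) s - h, if (x < w) s + h,
            if (y > 1L) s - 1L, if (y < h) s + 1L)
    nb <- nb[is.na(pop$species[nb])]
    if (!length(nb)) next
    tgt <- nb[sample.int(length(nb), 1L)]
    half <- pop$biomass[s] / 2
    pop$biomass[s] <- half
    pop$species[tgt] <- pop$species[s]
    pop$biomass[tgt] <- half
  }
  pop
}

#' Death, distal washout and colonization
#'
#' Each population is removed with probability `death_p` per step;
#' populations in the most distal column are always deleted. Each empty
#' site then acquires, with probability `colonize_p` (scaled by `1/n^2`
#' on rescaled lattices by the caller), a new population of a uniformly
#' random roster species at size `B0`. With `first_col_only = TRUE`
#' colonization is restricted to the first column (with a correspondingly
#' raised probability, 0.01125 at default geometry).
#'
#' @param pop population layer
#' @param geom lattice geometry
#' @param n_species roster size
#' @param death_p per-population death probability per step
#' @param colonize_p per-empty-site colonization probability per step
#' @param B0 colonizer size in bacteria
#' @param first_col_only restrict colonization to the proximal column
#' @return list: updated `pop`, `died_biomass`, `washed_biomass`,
#'   `n_colonized`
#' @export
kill_and_colonize <- function(pop, geom, n_species, death_p = 0.0075,
                              colonize_p = 5e-5, B0 = 5e7,
                              first_col_only = FALSE) {
  occ <- which(!is.na(pop$species))
  died <- occ[runif(length(occ)) < death_p]
  died_biomass <- sum(pop$biomass[died])
  pop$species[died] <- NA_integer_
  pop$biomass[died] <- 0

  distal <- site_index(geom, geom$width, seq_len(geom$height))
  washed <- distal[!is.na(pop$species[distal])]
  washed_biomass <- sum(pop$biomass[washed])
  pop$species[washed] <- NA_integer_
  pop$biomass[washed] <- 0

  empty <- which(is.na(pop$species))
  if (first_col_only)
    empty <- empty[empty <= geom$height]
  newborn <- empty[runif(length(empty)) < colonize_p]
  if (length(newborn)) {
    pop$species[newborn] <- sample.int(n_species, length(newborn),
                                       replace = TRUE)
    pop$biomass[newborn] <- B0
  }
  list(pop = pop, died_biomass = died_biomass,
       washed_biomass = washed_biomass, n_colonized = length(newborn))
}

#' Neighborhood offsets for the mixing scheme
#'
#' `"neighbors8"` is the default: the four first-order (von Neumann) plus
#' four second-order (diagonal) neighbors; its measured population
#' diffusion constant at default geometry is 5.7e-5 cm^2/s, 1.3x the
#' metabolite diffusion. `"manhattan2"` (Manhattan distance <= 2) and
#' `"block24"` (5 x 5 minus center) are provided for sensitivity checks.
#'
#' @param neighborhood one of `"neighbors8"`, `"manhattan2"`, `"block24"`
#' @return integer matrix of (dx, dy) offsets
#' @export
mix_offsets <- function(neighborhood = c("neighbors8", "manhattan2",
                                         "block24")) {
  neighborhood <- match.arg(neighborhood)
  g <- expand.grid(dx = -2:2, dy = -2:2)
  keep <- switch(neighborhood,
    neighbors8 = abs(g$dx) <= 1 & abs(g$dy) <= 1 & !(g$dx == 0 & g$dy == 0),
    manhattan2 = (abs(g$dx) + abs(g$dy)) %in% c(1, 2),
    block24 = !(g$dx == 0 & g$dy == 0))
  as.matrix(g[keep, c("dx", "dy")])
}

#' Swap-based mixing of the population layer
#'
#' Performs `sweeps` swap sweeps inspired by Kawasaki dynamics: in random
#' order each not-yet-swapped site picks a partner uniformly from itself
#' and its in-lattice neighborhood and exchanges population contents if
#' the partner has not yet swapped. Metabolites do not move. Fractional
#' sweep counts attempt the corresponding fraction of sites;
#' `sweeps = 0` is the identity. `full` reassigns every population to a
#' random non-overlapping site (the fully mixed limit).
#'
#' @param pop population layer
#' @param geom lattice geometry
#' @param sweeps number of sweeps this step (scaled by `1/n^2` on
#'   rescaled lattices by the caller)
#' @param offsets neighborhood offsets from [mix_offsets()]
#' @param full fully mix instead of swapping
#' @return list: updated `pop` and `perm`, the composed site permutation
#' @export
mix_populations <- function(pop, geom, sweeps = 1,
                            offsets = mix_offsets(), full = FALSE) {
  n <- geom$n_sites
  if (full) {
    perm <- sample.int(n)
  } else {
    perm <- seq_len(n)
    s <- sweeps
    while (s > 1e-12) {
      frac <- min(s, 1)
      p1 <- mix_sweep_perm(geom$width, geom$height, offsets, frac)
      perm <- perm[p1]
      s <- s - frac
    }
  }
  pop$species <- pop$species[perm]
  pop$biomass <- pop$biomass[perm]
  list(pop = pop, perm = perm)
}

#' Tracer run of the mixing scheme
#'
#' Applies the swap scheme alone (no growth, death or metabolism) and
#' records every site's trajectory, for estimating the population
#' diffusion constant from mean squared displacement.
#'
#' @param geom lattice geometry
#' @param steps number of timesteps
#' @param sweeps sweeps per step
#' @param offsets neighborhood offsets
#' @param full fully mixed limit
#' @return list with `x`, `y`: (steps + 1) x n_sites integer matrices of
#'   tracer coordinates, and the geometry
#' @export
run_tracer <- function(geom, steps, sweeps = 1, offsets = mix_offsets(),
                       full = FALSE) {
  n <- geom$n_sites
  loc <- seq_len(n)  # loc[tracer] = current site
  xs <- matrix(0L, nrow = steps + 1L, ncol = n)
  ys <- matrix(0L, nrow = steps + 1L, ncol = n)
  xy <- site_xy(geom, loc)
  xs[1, ] <- xy[, "x"]; ys[1, ] <- xy[, "y"]
  dummy <- list(species = seq_len(n), biomass = rep(1, n))
  for (t in seq_len(steps)) {
    res <- mix_populations(dummy, geom, sweeps, offsets, full)
    # res$perm: new_content[site] = old_content[perm[site]]
    inv <- integer(n); inv[res$perm] <- seq_len(n)
    loc <- inv[loc]
    xy <- site_xy(geom, loc)
    xs[t + 1L, ] <- xy[, "x"]; ys[t + 1L, ] <- xy[, "y"]
  }
  list(x = xs, y = ys, geom = geom)
}
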