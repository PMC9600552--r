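# Analysis artifacts: fecal composition, cross-feeding networks, spatial
# profiles, diffusion estimation, dominance summaries.

fake_run <- function(outflow, geom = lattice_geometry(width = 20, height = 8)) {
  structure(list(geom = geom, outflow = outflow), class = "gs_run")
}

test_that("fecal composition arithmetic matches the hand-built ledger", {
  # 960 steps of exactly 1 umol acetate per step
  out <- matrix(0, nrow = 960, ncol = 2,
                dimnames = list(NULL, c("ac", "lac_L")))
  out[, "ac"] <- 1
  r <- fake_run(out, lattice_geometry())  # height 8, 0.05 mL sites
  fc <- fecal_composition(r, window = 960)
  ac <- fc[fc$metabolite == "ac", ]
  expect_equal(ac$amount_umol, 960)
  expect_equal(ac$fraction, 1)
  # 1 umol / (8 * 0.05 mL) per step-equivalent volume = 2.5 mM
  expect_equal(ac$mM, 1 / (8 * 0.05))
  # lactate pooling renames lac_L -> lac
  expect_true("lac" %in% fc$metabolite)
  expect_false("lac_L" %in% fc$metabolite)
})

test_that("fecal fractions sum to one and degenerate inputs are handled", {
  set.seed(20)
  out <- matrix(runif(50 * 3), nrow = 50,
                dimnames = list(NULL, c("ac", "for", "etoh")))
  fc <- fecal_composition(fake_run(out), window = 50)
  expect_equal(sum(fc$fraction), 1)
  # all-zero outflow
  fc0 <- fecal_composition(fake_run(out * 0), window = 50)
  expect_true(all(fc0$fraction == 0))
  # window longer than the run is an error
  expect_error(fecal_composition(fake_run(out), window = 51), "shorter")
})

test_that("cross-feeding networks threshold and orient edges correctly", {
  fin <- array(0, dim = c(4, 2, 2),
               dimnames = list(NULL, c("A", "B"), c("lcts", "lac_L")))
  fout <- fin
  fout[, "A", "lac_L"] <- c(0.2, 0.2, 0.2, 0.2)  # A produces 0.8 lactate
  fin[, "B", "lac_L"] <- c(0.3, 0.3, 0, 0)       # B consumes 0.6
  fin[, "A", "lcts"] <- 0.1                      # 0.4, below threshold
  rec <- structure(list(flux_in = fin, flux_out = fout,
                        species = c("A", "B")), class = "gs_run")
  net <- crossfeeding_network(rec, threshold = 0.5)
  expect_equal(nrow(net), 2L)
  prod <- net[net$type == "production", ]
  expect_equal(prod$from, "A"); expect_equal(prod$to, "lac_L")
  expect_equal(prod$weight, 0.8)
  cons <- net[net$type == "consumption", ]
  expect_equal(cons$from, "lac_L"); expect_equal(cons$to, "B")
  expect_equal(cons$weight, 0.6)
  # windowing drops the early consumption below threshold
  net2 <- crossfeeding_network(rec, window = 3:4, threshold = 0.3)
  expect_false(any(net2$type == "consumption"))
  # empty ledger, empty network
  net0 <- crossfeeding_network(rec, threshold = 10)
  expect_equal(nrow(net0), 0L)
})

test_that("a toy run produces the expected lactose and product edges", {
  cfg <- sim_config(width = 20, height = 4, horizon = 240, seed = 21,
                    roster = toy_models["BifidToy"],
                    record_fluxes = TRUE, record_spatial_every = 0,
                    audit = FALSE)
  r <- run_simulation(cfg)
  net <- crossfeeding_network(r, threshold = 0.5)
  cons <- net$metabolite[net$type == "consumption"]
  prod <- net$metabolite[net$type == "production"]
  expect_true("lcts" %in% cons)
  expect_true(all(c("ac", "lac_L") %in% prod))
})

test_that("spatial profiles are flat for uniform fields and sd 0 for one snapshot", {
  snap <- function(step, val) list(
    step = step,
    biomass_by_col = matrix(val, nrow = 1, ncol = 5,
                            dimnames = list("A", NULL)),
    field_by_col = matrix(2 * val, nrow = 1, ncol = 5,
                          dimnames = list("lcts", NULL)))
  rec <- structure(list(snapshots = list(snap(10, 1), snap(20, 3))),
                   class = "gs_run")
  sp <- spatial_profiles(rec)
  expect_equal(unique(sp$mean[sp$kind == "species"]), 2)
  expect_equal(unique(sp$sd[sp$kind == "metabolite"]), sd(c(2, 6)))
  sp1 <- spatial_profiles(rec, window = c(1, 15))
  expect_equal(unique(sp1$sd), 0)
  expect_error(spatial_profiles(rec, window = c(100, 200)), "no spatial")
})

test_that("diffusion estimation recovers a known constant", {
  # synthetic isotropic lattice random walk with known D
  set.seed(22)
  g <- lattice_geometry(width = 400, height = 400)
  steps <- 50; ntr <- 800
  p_move <- 0.6  # per-axis displacement variance p_move per step
  D_true <- p_move * g$dx_cm^2 / (2 * g$dt_s)
  xs <- matrix(0L, steps + 1, ntr); ys <- matrix(0L, steps + 1, ntr)
  xs[1, ] <- 200L; ys[1, ] <- 200L
  for (t in 1:steps) {
    dx <- sample(c(-1L, 0L, 1L), ntr, TRUE,
                 prob = c(p_move / 2, 1 - p_move, p_move / 2))
    dy <- sample(c(-1L, 0L, 1L), ntr, TRUE,
                 prob = c(p_move / 2, 1 - p_move, p_move / 2))
    xs[t + 1, ] <- xs[t, ] + dx
    ys[t + 1, ] <- ys[t, ] + dy
  }
  D_hat <- estimate_diffusion(list(x = xs, y = ys, geom = g),
                              axes = c("x", "y"))
  expect_equal(D_hat, D_true, tolerance = 0.15)
  # mixing disabled: no displacement, D ~ 0
  tr0 <- run_tracer(lattice_geometry(width = 30, height = 8), steps = 10,
                    sweeps = 0)
  expect_equal(estimate_diffusion(tr0, axes = "x"), 0)
  # full mixing saturates the lattice scale immediately
  set.seed(23)
  trf <- run_tracer(lattice_geometry(width = 30, height = 8), steps = 3,
                    full = TRUE)
  msd1 <- mean((trf$x[2, ] - trf$x[1, ])^2)
  expect_gt(msd1, 30^2 / 12)  # already at lattice variance after one step
})

test_that("dominance summaries count winners and pool groups", {
  mk <- function(fin) structure(list(
    species = names(fin),
    abundance = rbind(rep(0, length(fin)), fin)), class = "gs_run")
  recs <- list(mk(c(A = 5, B = 1, C = 0)),
               mk(c(A = 3, B = 4, C = 0)),
               mk(c(A = 9, B = 1, C = 1)))
  ds <- dominance_summary(recs)
  expect_equal(unname(ds$counts[c("A", "B", "C")]), c(2L, 1L, 0L))
  expect_equal(dim(ds$final_abundance), c(3L, 3L))
  # grouping pools abundances before ranking
  ds2 <- dominance_summary(recs, groups = c(A = "one", B = "two", C = "two"))
  expect_equal(unname(ds2$counts["two"]), 1L)
  expect_equal(unname(ds2$final_abundance[2, "two"]), 4)
})
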