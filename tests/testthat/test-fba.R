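# The FBA engine: uptake bounds, the enzymatic constraint, the metabolic
# switch, and its invariants.

test_that("uptake bounds implement amount/(B/U) with unlimited water", {
  b <- uptake_bounds(c(lcts = 1), 1e10)
  expect_equal(b[["lcts"]], 1)          # U cancels at one population unit
  expect_equal(b[["h2o"]], Inf)
  # halving B doubles the per-unit bound; total possible uptake unchanged
  b2 <- uptake_bounds(c(lcts = 1), 5e9)
  expect_equal(b2[["lcts"]], 2)
  expect_equal(b2[["lcts"]] * (5e9 / 1e10), b[["lcts"]] * 1)
  expect_error(uptake_bounds(c(lcts = -1), 1e10), "negative")
})

test_that("no substrate means exactly zero growth", {
  for (m in toy_models) {
    r <- solve_step(m, 1e10, uptake_bounds(c(), 1e10))
    expect_equal(r$growth_atp, 0)
    expect_equal(unname(r$sum_flux), 0)
  }
})

test_that("bifid shunt yields switch between high- and low-yield branches", {
  # abundant lactose, constraint binding: 5 ATP, 2 lactate, 3 acetate per
  # lactose, acetate:lactate secretion 3:2
  r <- abundant(toy_models$BifidToy)
  up <- r$F_in[["lcts"]]
  expect_gt(up, 0)
  expect_equal(r$growth_atp / up, 5, tolerance = 1e-7)
  expect_equal((r$F_out[["lac_L"]] - r$F_in[["lac_L"]]) / up, 2,
               tolerance = 1e-7)
  expect_equal(r$F_out[["ac"]] / up, 3, tolerance = 1e-7)
  expect_equal(r$sum_flux, 2, tolerance = 1e-7)  # cap binds
  # scarce lactose, uptake binding: acetate:ethanol:formate 4:1:2, 6 ATP
  r2 <- solve_step(toy_models$BifidToy, 5e9,
                   uptake_bounds(c(lcts = 0.01), 5e9))
  up2 <- r2$F_in[["lcts"]]
  expect_equal(r2$F_out[["ac"]] / up2, 4, tolerance = 1e-7)
  expect_equal(r2$F_out[["etoh"]] / up2, 1, tolerance = 1e-7)
  expect_equal(r2$F_out[["for"]] / up2, 2, tolerance = 1e-7)
  expect_equal(r2$growth_atp / up2, 6, tolerance = 1e-7)
})

test_that("dose response shows the metabolic switch and growth saturation", {
  dr <- dose_response(toy_models$BifidToy, "lcts",
                      grid = seq(0, 1.5, by = 0.05))
  # growth non-decreasing and saturated at high concentration
  expect_true(all(diff(dr$growth_atp) > -1e-9))
  expect_equal(dr$growth_atp[nrow(dr)], dr$growth_atp[nrow(dr) - 2],
               tolerance = 1e-7)
  # a switch concentration exists: lactate off then on, ethanol/formate
  # produced at low concentration and gone at high concentration
  lac <- dr$lac_L; eth <- dr$etoh
  expect_true(any(lac[dr$concentration > 0] < 1e-9))
  expect_gt(lac[nrow(dr)], 0)
  expect_gt(max(eth), 0)
  expect_lt(eth[nrow(dr)], 1e-9)
  sw <- min(which(lac > 1e-9))
  expect_true(all(eth[seq(sw, nrow(dr))] <= eth[sw] + 1e-9))
  # empty grid gives an empty table
  expect_equal(nrow(dose_response(toy_models$BifidToy, "lcts",
                                  numeric(0))), 0L)
})

test_that("without the enzymatic constraint the low-substrate profile persists", {
  dr <- dose_response(toy_models$BifidToy, "lcts",
                      grid = c(0.1, 0.5, 1, 2), a = Inf)
  expect_true(all(dr$lac_L < 1e-6))       # never switches to lactate
  expect_true(all(dr$etoh[dr$concentration > 0] > 0))
  # growth scales linearly with substrate (no cap to saturate it)
  expect_equal(dr$growth_atp[4] / dr$growth_atp[2], 4, tolerance = 1e-6)
})

test_that("oxygen strictly increases facultative-anaerobe growth", {
  m <- toy_models$FacAnToy
  with_o2 <- solve_step(m, 5e9, uptake_bounds(c(lcts = 100, o2 = 100), 5e9))
  no_o2 <- solve_step(m, 5e9, uptake_bounds(c(lcts = 100), 5e9))
  expect_gt(with_o2$growth_atp, no_o2$growth_atp)
  blocked <- solve_step(m, 5e9, uptake_bounds(c(lcts = 100, o2 = 100), 5e9),
                        blocked_cols = m$exch$col[m$exch$met == "o2" &
                                                  m$exch$direction == "in"])
  expect_equal(blocked$growth_atp, no_o2$growth_atp, tolerance = 1e-7)
})

test_that("growth is monotone in uptake bounds and in the constraint", {
  set.seed(42)
  for (nm in names(toy_models)) {
    m <- toy_models[[nm]]
    base <- c(lcts = 0.02, lac_L = 0.02, o2 = 0.02)
    g0 <- solve_step(m, 1e10, uptake_bounds(base, 1e10), a = 1)$growth_atp
    for (rep in 1:5) {
      more <- base + runif(3, 0, 0.05)
      g1 <- solve_step(m, 1e10, uptake_bounds(more, 1e10), a = 1)$growth_atp
      expect_gte(g1, g0 - 1e-9)
      g2 <- solve_step(m, 1e10, uptake_bounds(more, 1e10),
                       a = 1 + runif(1, 0, 2))$growth_atp
      expect_gte(g2, g1 - 1e-9)
    }
  }
})

test_that("per-unit results are invariant to population size", {
  m <- toy_models$BifidToy
  bounds <- c(lcts = 0.05, lac_L = 0.01)
  r1 <- solve_step(m, 1e9, setNames(as.list(bounds), names(bounds)))
  r2 <- solve_step(m, 2e10, setNames(as.list(bounds), names(bounds)))
  expect_equal(r1$growth_atp, r2$growth_atp, tolerance = 1e-7)
  expect_equal(r1$F_out, r2$F_out, tolerance = 1e-7)
})

test_that("every solution conserves C, H, O and N to 1e-8 umol", {
  set.seed(99)
  for (nm in names(toy_models)) {
    m <- toy_models[[nm]]
    fm <- ext_formulas(m)
    for (rep in 1:10) {
      amounts <- setNames(runif(4, 0, 0.5), c("lcts", "lac_L", "o2", "ac"))
      r <- solve_step(m, 1e10, uptake_bounds(amounts, 1e10))
      el <- atom_balance(r, fm)
      expect_lt(max(abs(el)), 1e-8)
    }
  }
})

test_that("the lexicographic solve is deterministic", {
  m <- toy_models$FacAnToy
  b <- uptake_bounds(c(lcts = 0.04, o2 = 0.03, lac_L = 0.02), 1e10)
  r1 <- solve_step(m, 1e10, b)
  r2 <- solve_step(m, 1e10, b)
  expect_identical(r1$flux, r2$flux)
})
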