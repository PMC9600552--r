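# SBML ingestion, curation edits, the ATP objective and compilation.

test_that("SBML round trip preserves the draft", {
  dir <- withr::local_tempdir()
  for (d in toy_model_drafts()) {
    p <- file.path(dir, paste0(d$species_id, ".xml"))
    write_sbml(d, p)
    d2 <- load_sbml(p)
    expect_equal(d2$species_id, d$species_id)
    expect_equal(nrow(d2$metabolites), nrow(d$metabolites))
    expect_setequal(names(d2$reactions), names(d$reactions))
    expect_equal(d2$metabolites$formula[match(d$metabolites$id,
                                              d2$metabolites$id)],
                 d$metabolites$formula)
    for (rid in names(d$reactions)) {
      a <- d$reactions[[rid]]; b <- d2$reactions[[rid]]
      expect_equal(b$reversible, a$reversible, label = rid)
      expect_equal(sort(names(b$stoich)), sort(names(a$stoich)), label = rid)
      expect_equal(b$stoich[sort(names(b$stoich))],
                   a$stoich[sort(names(a$stoich))], label = rid)
      expect_equal(b$kind, a$kind, label = rid)
    }
  }
})

test_that("a minimal SBML file with one exchange loads", {
  dir <- withr::local_tempdir()
  mets <- data.frame(id = "x_e", base_id = "x", compartment = "e",
                     extracellular = TRUE, formula = "C1",
                     name = "x", stringsAsFactors = FALSE)
  d <- new_model_draft("Mini", mets,
                       list(list(id = "R_EX_x_e", stoich = c(x_e = -1),
                                 reversible = TRUE, kind = "exchange",
                                 lb = -Inf, ub = Inf)))
  p <- file.path(dir, "mini.xml")
  write_sbml(d, p)
  d2 <- load_sbml(p)
  expect_equal(length(d2$reactions), 1L)
  expect_equal(d2$reactions[[1]]$kind, "exchange")
})

test_that("unknown metabolites and unreadable files are fatal", {
  expect_error(load_sbml(tempfile(fileext = ".xml")))
  mets <- toy_model_drafts()$CrossToy$metabolites
  expect_error(new_model_draft("X", mets, list(
    list(id = "R_BAD", stoich = c(nosuchmet_c = 1), reversible = FALSE,
         kind = "internal", lb = 0, ub = Inf))), "unknown metabolites")
})

test_that("compilation splits reversible reactions into two columns", {
  for (d in toy_model_drafts()) {
    d <- set_atp_objective(d)
    m <- compile_model(d)
    n_rev <- sum(vapply(d$reactions, function(r) r$reversible || r$lb < 0,
                        TRUE))
    expect_equal(ncol(m$S), length(d$reactions) + n_rev)
    expect_true(all(m$col_ub >= 0))
    # every exchange column touches exactly one extracellular row
    extrows <- which(m$mets$extracellular)
    for (j in m$cols$col[m$cols$kind == "exchange"])
      expect_equal(sum(m$S[extrows, j] != 0), 1L)
    # recompilation is exact
    expect_identical(m$S, compile_model(d)$S)
  }
})

test_that("the ATP objective is mass neutral and idempotent", {
  d <- set_atp_objective(toy_model_drafts()$BifidToy)
  expect_equal(d$objective, "R_ATP_DRAIN")
  d2 <- set_atp_objective(d)
  expect_equal(length(d2$reactions), length(d$reactions))
  expect_equal(d2$objective, "R_ATP_DRAIN")
  # formula-weighted column sum oracle: net C,H,O,N of the objective is 0
  m <- compile_model(d)
  fm <- parse_formula(m$mets$formula)
  net <- drop(t(fm) %*% m$S[, m$obj_col])
  expect_equal(unname(net), c(0, 0, 0, 0))
  # a draft lacking ATP species is rejected
  mini <- toy_model_drafts()$CrossToy
  mini$metabolites <- mini$metabolites[mini$metabolites$base_id != "atp", ]
  mini$reactions <- Filter(function(r) !"atp_c" %in% names(r$stoich),
                           mini$reactions)
  mini <- new_model_draft("NoATP", mini$metabolites, mini$reactions)
  expect_error(set_atp_objective(mini), "ATP")
})

test_that("curation edits apply in order, log, and validate references", {
  d <- toy_model_drafts()$BifidToy
  edits <- data.frame(
    model_id = "BifidToy",
    action = c("delete_reaction", "delete_reaction"),
    reaction_id = c("R_PKL", "R_F6PE4PL"),
    payload = "", stringsAsFactors = FALSE)
  d2 <- apply_curation_edits(d, edits)
  expect_false(any(c("R_PKL", "R_F6PE4PL") %in% names(d2$reactions)))
  expect_equal(attr(d2, "edit_log"),
               c("delete_reaction R_PKL", "delete_reaction R_F6PE4PL"))
  # phosphoketolase deletion makes lactose metabolism impossible
  m <- compile_model(set_atp_objective(d2))
  r <- solve_step(m, 1e10, uptake_bounds(c(lcts = 10), 1e10))
  expect_equal(r$growth_atp, 0)
  # but lactate catabolism survives
  r2 <- solve_step(m, 1e10, uptake_bounds(c(lac_L = 10), 1e10))
  expect_gt(r2$growth_atp, 0)

  # dangling reference and duplicate add are fatal
  expect_error(apply_curation_edits(d, data.frame(
    model_id = "BifidToy", action = "delete_reaction",
    reaction_id = "R_NOPE", payload = "", stringsAsFactors = FALSE)),
    "not found")
  expect_error(apply_curation_edits(d, data.frame(
    model_id = "BifidToy", action = "add_reaction",
    reaction_id = "R_PKL", payload = "{}", stringsAsFactors = FALSE)),
    "already exists")

  # empty edit table is the identity
  d3 <- apply_curation_edits(d, edits[0, ])
  expect_equal(names(d3$reactions), names(d$reactions))

  # set actions are idempotent
  e <- data.frame(model_id = "BifidToy", action = "set_bounds",
                  reaction_id = "R_EX_lcts_e",
                  payload = '{"lb":0,"ub":0}', stringsAsFactors = FALSE)
  d4 <- apply_curation_edits(apply_curation_edits(d, e), e)
  expect_equal(d4$reactions$R_EX_lcts_e$ub, 0)
  m4 <- compile_model(set_atp_objective(d4))
  r4 <- solve_step(m4, 1e10, uptake_bounds(c(lcts = 10), 1e10))
  expect_equal(r4$growth_atp, 0)  # lactose exchange fully closed
})

test_that("set_reversible compiles both directions", {
  d <- toy_model_drafts()$FacAnToy
  e <- data.frame(model_id = "FacAnToy", action = "set_reversible",
                  reaction_id = "R_LCTSt",
                  payload = '{"reversible":true}', stringsAsFactors = FALSE)
  d2 <- apply_curation_edits(d, e)
  m <- compile_model(set_atp_objective(d2))
  expect_equal(sum(m$cols$rxn_id == "R_LCTSt"), 2L)
})

test_that("edits for other models are ignored", {
  d <- toy_model_drafts()$CrossToy
  e <- data.frame(model_id = "BifidToy", action = "delete_reaction",
                  reaction_id = "R_PKL", payload = "",
                  stringsAsFactors = FALSE)
  d2 <- apply_curation_edits(d, e)
  expect_equal(names(d2$reactions), names(d$reactions))
})
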