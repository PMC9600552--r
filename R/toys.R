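# Hand-written toy networks emulating the three ecological archetypes of the
# early infant gut: a bifid-shunt primary fermenter with a yield/rate switch,
# a facultative anaerobe with aerobic respiration, and an anaerobic lactate
# cross-feeder. Stoichiometries are lumped but elementally balanced (C,H,O,N)
# with real formulas, so every flux solution passes the mass audit, and the
# pathway flux costs are arranged so the documented yields emerge from the
# LP rather than being hard-coded:
#
# * low-yield bifid shunt: 1 lactose -> 3 acetate + 2 lactate + 5 ATP
#   (highest ATP per unit summed flux; wins when the enzymatic constraint
#   binds, i.e. abundant substrate)
# * high-yield branch: 1 lactose -> 4 acetate + 1 ethanol + 2 formate +
#   6 ATP (highest ATP per mol lactose; wins when uptake binds, i.e.
#   scarce substrate)
# * aerobic respiration: 1 lactose + 12 O2 -> 12 CO2, 32 ATP (beats every
#   fermentation per lactose and per summed flux while oxygen lasts)

.toy_formulas <- c(
  lcts = "C12H22O11", ac = "C2H4O2", lac_L = "C3H6O3", etoh = "C2H6O",
  "for" = "CH2O2", h2o = "H2O", o2 = "O2", co2 = "CO2",
  bsi1 = "C12H22O11", bsi2 = "C12H22O11",
  atp = "C10H16N5O13P3", adp = "C10H15N5O10P2", pi = "H3PO4")

.toy_names <- c(
  lcts = "Lactose", ac = "Acetate", lac_L = "L-Lactate", etoh = "Ethanol",
  "for" = "Formate", h2o = "Water", o2 = "Oxygen", co2 = "Carbon dioxide",
  bsi1 = "Bifid shunt intermediate 1", bsi2 = "Bifid shunt intermediate 2",
  atp = "ATP", adp = "ADP", pi = "Phosphate")

.toy_mets <- function(ext, intra) {
  rows <- rbind(
    data.frame(base_id = ext, compartment = "e", stringsAsFactors = FALSE),
    data.frame(base_id = intra, compartment = "c", stringsAsFactors = FALSE))
  data.frame(id = paste0(rows$base_id, "_", rows$compartment),
             base_id = rows$base_id, compartment = rows$compartment,
             extracellular = rows$compartment == "e",
             formula = unname(.toy_formulas[rows$base_id]),
             name = unname(.toy_names[rows$base_id]),
             stringsAsFactors = FALSE)
}

.rx <- function(id, stoich, reversible = FALSE, kind = "internal") {
  list(id = id, stoich = stoich, reversible = reversible, kind = kind,
       lb = if (reversible) -Inf else 0, ub = Inf)
}

.exchanges <- function(ext) {
  lapply(ext, function(m)
    .rx(paste0("R_EX_", m, "_e"), setNames(-1, paste0(m, "_e")),
        reversible = TRUE, kind = "exchange"))
}

#' Toy model drafts
#'
#' Returns the editable drafts of the bundled toy networks: `BifidToy`
#' (bifid-shunt fermenter, lactose in via the phosphoketolase chain
#' `R_PKL` -> `R_F6PE4PL`, low-yield acetate+lactate and high-yield
#' acetate+ethanol+formate branches, lactate re-uptake via a lactate
#' dehydrogenase route), `FacAnToy` (facultative anaerobe: mixed-acid
#' lactose fermentation, aerobic respiration of lactose and lactate with
#' much higher ATP yield, weak anaerobic lactate use) and `CrossToy`
#' (anaerobic cross-feeder growing on lactate and weakly on lactose).
#'
#' @return named list of [new_model_draft()] objects
#' @export
toy_model_drafts <- function() {
  drafts <- list()

  # --- BifidToy ------------------------------------------------------------
  ext <- c("lcts", "ac", "lac_L", "etoh", "for", "h2o")
  intra <- c("lcts", "bsi1", "bsi2", "ac", "lac_L", "etoh", "for", "h2o",
             "atp", "adp", "pi")
  rxns <- c(.exchanges(ext), list(
    .rx("R_LCTSt", c(lcts_e = -1, lcts_c = 1)),
    .rx("R_PKL", c(lcts_c = -1, bsi1_c = 1)),
    .rx("R_F6PE4PL", c(bsi1_c = -1, bsi2_c = 1)),
    .rx("R_BSLY", c(bsi2_c = -1, adp_c = -5, pi_c = -5,
                    ac_c = 3, lac_L_c = 2, atp_c = 5, h2o_c = 4)),
    .rx("R_BSHY", c(bsi2_c = -1, adp_c = -6, pi_c = -6,
                    ac_c = 4, etoh_c = 1, for_c = 2, atp_c = 6, h2o_c = 4)),
    .rx("R_LDHCAT", c(lac_L_c = -2, adp_c = -1, pi_c = -1,
                      ac_c = 1, etoh_c = 1, for_c = 2, atp_c = 1)),
    .rx("R_ACt", c(ac_c = -1, ac_e = 1)),
    .rx("R_LACt", c(lac_L_e = -1, lac_L_c = 1), reversible = TRUE),
    .rx("R_ETOHt", c(etoh_c = -1, etoh_e = 1)),
    .rx("R_FORt", c(for_c = -1, for_e = 1)),
    .rx("R_H2Ot", c(h2o_e = -1, h2o_c = 1), reversible = TRUE),
    .rx("R_ATP_DRAIN", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1))))
  drafts$BifidToy <- new_model_draft("BifidToy", .toy_mets(ext, intra), rxns)

  # --- FacAnToy ------------------------------------------------------------
  ext <- c("lcts", "ac", "lac_L", "etoh", "for", "h2o", "o2", "co2")
  intra <- c("lcts", "ac", "lac_L", "etoh", "for", "h2o", "o2", "co2",
             "atp", "adp", "pi")
  rxns <- c(.exchanges(ext), list(
    .rx("R_LCTSt", c(lcts_e = -1, lcts_c = 1)),
    .rx("R_FERM", c(lcts_c = -1, adp_c = -4, pi_c = -4,
                    ac_c = 2, etoh_c = 2, for_c = 4, atp_c = 4, h2o_c = 1)),
    .rx("R_RESP", c(lcts_c = -1, o2_c = -12, adp_c = -32, pi_c = -32,
                    co2_c = 12, h2o_c = 43, atp_c = 32)),
    .rx("R_LACFERM", c(lac_L_c = -2, adp_c = -1, pi_c = -1,
                       ac_c = 1, etoh_c = 1, for_c = 2, atp_c = 1)),
    .rx("R_LACRESP", c(lac_L_c = -1, o2_c = -3, adp_c = -12, pi_c = -12,
                       co2_c = 3, h2o_c = 15, atp_c = 12)),
    .rx("R_ACt", c(ac_c = -1, ac_e = 1)),
    .rx("R_LACt", c(lac_L_e = -1, lac_L_c = 1), reversible = TRUE),
    .rx("R_ETOHt", c(etoh_c = -1, etoh_e = 1)),
    .rx("R_FORt", c(for_c = -1, for_e = 1)),
    .rx("R_H2Ot", c(h2o_e = -1, h2o_c = 1), reversible = TRUE),
    .rx("R_O2t", c(o2_e = -1, o2_c = 1)),
    .rx("R_CO2t", c(co2_c = -1, co2_e = 1)),
    .rx("R_ATP_DRAIN", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1))))
  drafts$FacAnToy <- new_model_draft("FacAnToy", .toy_mets(ext, intra), rxns)

  # --- CrossToy ------------------------------------------------------------
  ext <- c("lcts", "ac", "lac_L", "etoh", "for", "h2o")
  intra <- c("lcts", "ac", "lac_L", "etoh", "for", "h2o", "atp", "adp", "pi")
  rxns <- c(.exchanges(ext), list(
    .rx("R_LCTSt", c(lcts_e = -1, lcts_c = 1)),
    .rx("R_FERMW", c(lcts_c = -1, h2o_c = -1, adp_c = -2, pi_c = -2,
                     ac_c = 2, etoh_c = 2, for_c = 4, atp_c = 2)),
    .rx("R_LACCAT", c(lac_L_c = -2, adp_c = -2, pi_c = -2,
                      ac_c = 1, etoh_c = 1, for_c = 2, h2o_c = 1, atp_c = 2)),
    .rx("R_ACt", c(ac_c = -1, ac_e = 1)),
    .rx("R_LACt", c(lac_L_e = -1, lac_L_c = 1), reversible = TRUE),
    .rx("R_ETOHt", c(etoh_c = -1, etoh_e = 1)),
    .rx("R_FORt", c(for_c = -1, for_e = 1)),
    .rx("R_H2Ot", c(h2o_e = -1, h2o_c = 1), reversible = TRUE),
    .rx("R_ATP_DRAIN", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1))))
  drafts$CrossToy <- new_model_draft("CrossToy", .toy_mets(ext, intra), rxns)

  drafts
}

#' Negative-control draft with a deliberate carbon imbalance
#'
#' A copy of `CrossToy` whose lactose fermentation creates one extra
#' acetate out of nothing. Used to verify that the mass audit detects
#' broken stoichiometry; never part of the default roster.
#'
#' @return a [new_model_draft()] object with species id `BadToy`
#' @export
toy_negative_control <- function() {
  d <- toy_model_drafts()$CrossToy
  d$species_id <- "BadToy"
  d$reactions$R_FERMW$stoich["ac_c"] <- 3  # +1 acetate unaccounted for
  new_model_draft("BadToy", d$metabolites, d$reactions)
}

.toy_cache <- new.env(parent = emptyenv())

#' Build the compiled toy models
#'
#' Writes the toy drafts as SBML to a scratch directory, reads them back
#' through [load_sbml()] (so the SBML path is exercised end to end), sets
#' the ATP-production objective and compiles. Results are cached per
#' session.
#'
#' @param dir directory for the intermediate SBML files (default: tempdir)
#' @param via_sbml set `FALSE` to compile the in-memory drafts directly
#' @return named list of [compile_model()] objects
#' @export
build_toy_models <- function(dir = NULL, via_sbml = TRUE) {
  key <- paste0("models_", via_sbml)
  if (is.null(dir) && !is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  drafts <- toy_model_drafts()
  if (via_sbml) {
    if (is.null(dir)) dir <- file.path(tempdir(), "gutsim_toys")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    drafts <- lapply(drafts, function(d) {
      p <- file.path(dir, paste0(tolower(d$species_id), ".xml"))
      write_sbml(d, p)
      load_sbml(p)
    })
  }
  models <- lapply(drafts, function(d) compile_model(set_atp_objective(d)))
  .toy_cache[[key]] <- models
  models
}

#' Gibbs formation energies for the toy metabolites
#'
#' Transformed formation energies (J/mol) at pH 7, ionic strength 0.1 M
#' for the exchanged toy metabolites, in the style of the standard
#' biochemical tables.
#'
#' @return named numeric vector (J/mol)
#' @export
toy_gibbs_energies <- function() {
  c(h2o = -157280, o2 = 16400, co2 = -386020, lcts = -687000,
    ac = -249460, lac_L = -316940, etoh = 58100, "for" = -311040)
}
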