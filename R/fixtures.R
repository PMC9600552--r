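# Deterministic fixture bundle: toy SBML files, formula and Gibbs-energy
# tables, a curation-edit table exercising every edit action, and canned
# desk-scale configurations. Everything regenerates bit-identically, so
# tests and examples never require a download.

#' Write the fixture bundle
#'
#' Writes, into `dir`: the three toy models and the mass-imbalanced
#' negative control as SBML (`bifidtoy.xml`, `facantoy.xml`,
#' `crosstoy.xml`, `badtoy_synthetic.xml`), `formulas.csv`,
#' `gibbs_energies.csv`, `curation_edits.csv` (one row per supported edit
#' action), and canned configurations (`config_anaerobic_desk.json`,
#' `config_oxygen_desk.json`, `config_tracer.json`). Output depends only
#' on the package version, so two calls with the same seed produce
#' identical files; the seed is recorded in the manifest.
#'
#' @param dir output directory (created if needed)
#' @param seed seed recorded in the manifest and canned configs
#' @return invisibly, the manifest data.frame (file, bytes)
#' @export
write_fixture_bundle <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drafts <- toy_model_drafts()
  files <- character(0)
  for (d in drafts) {
    p <- file.path(dir, paste0(tolower(d$species_id), ".xml"))
    write_sbml(d, p)
    files <- c(files, p)
  }
  p <- file.path(dir, "badtoy_synthetic.xml")
  write_sbml(toy_negative_control(), p)
  files <- c(files, p)

  fm <- .toy_formulas
  p <- file.path(dir, "formulas.csv")
  write.csv(data.frame(id = names(fm), formula = unname(fm),
                       name = unname(.toy_names[names(fm)]),
                       stringsAsFactors = FALSE),
            p, row.names = FALSE, quote = FALSE)
  files <- c(files, p)

  en <- toy_gibbs_energies()
  p <- file.path(dir, "gibbs_energies.csv")
  write.csv(data.frame(id = names(en), dG_J_per_mol = unname(en),
                       stringsAsFactors = FALSE),
            p, row.names = FALSE, quote = FALSE)
  files <- c(files, p)

  # one row per supported curation action
  edits <- data.frame(
    model_id = c("BifidToy", "BifidToy", "CrossToy", "FacAnToy", "FacAnToy"),
    action = c("delete_reaction", "set_objective", "add_reaction",
               "set_bounds", "set_reversible"),
    reaction_id = c("R_PKL", "R_ATP_DRAIN", "R_ACLEAK", "R_EX_o2_e",
                    "R_LACFERM"),
    payload = c(
      "",
      "",
      "{\"stoich\":{\"ac_c\":-1,\"ac_e\":1},\"reversible\":false}",
      "{\"lb\":0,\"ub\":0}",
      "{\"reversible\":true}"),
    stringsAsFactors = FALSE)
  p <- file.path(dir, "curation_edits.csv")
  write.csv(edits, p, row.names = FALSE)
  files <- c(files, p)

  cfgs <- list(
    config_anaerobic_desk = list(width = 60, height = 4, horizon = 960,
                                 seed = seed, oxygen = list(mode = "none")),
    config_oxygen_desk = list(width = 60, height = 4, horizon = 960,
                              seed = seed,
                              oxygen = list(mode = "initial_uniform",
                                            amount = 0.1)),
    config_tracer = list(steps = 60, sweeps = 1,
                         neighborhood = "neighbors8", seed = seed))
  for (nm in names(cfgs)) {
    p <- file.path(dir, paste0(nm, ".json"))
    writeLines(jsonlite::toJSON(cfgs[[nm]], auto_unbox = TRUE,
                                pretty = TRUE), p)
    files <- c(files, p)
  }

  manifest <- data.frame(file = basename(files),
                         bytes = file.size(files),
                         stringsAsFactors = FALSE)
  write.csv(cbind(manifest, seed = seed),
            file.path(dir, "MANIFEST.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a canned desk-scale configuration
#'
#' Reads one of the bundled JSON configurations into a [sim_config()].
#'
#' @param path JSON file from [write_fixture_bundle()]
#' @return a `gs_config`
#' @export
read_config_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  ox <- if (!is.null(j$oxygen))
    oxygen_regime(j$oxygen$mode,
                  amount = if (is.null(j$oxygen$amount)) 0 else j$oxygen$amount,
                  stop_step = if (is.null(j$oxygen$stop_step)) Inf
                              else j$oxygen$stop_step)
    else oxygen_regime("none")
  sim_config(width = j$width, height = j$height,
             horizon = j$horizon, seed = j$seed, oxygen = ox)
}
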