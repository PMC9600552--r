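#' Create a metabolic model draft
#'
#' A draft is the editable, pre-compilation form of a species' metabolic
#' network: a metabolite table, a reaction list and (optionally) an
#' objective reaction. Drafts are produced by [load_sbml()] or built
#' programmatically, curated with [apply_curation_edits()], given an
#' ATP-production objective with [set_atp_objective()] and finally turned
#' into an LP-ready form by [compile_model()].
#'
#' @param species_id identifier for the species
#' @param metabolites data.frame with columns `id`, `base_id`,
#'   `compartment`, `extracellular` (logical), `formula` (NA allowed),
#'   `name`
#' @param reactions named list; each element a list with fields `id`,
#'   `stoich` (named numeric, metabolite id -> signed coefficient),
#'   `reversible`, `kind` ("internal" or "exchange"), `lb`, `ub`
#' @param objective id of the objective reaction or `NULL`
#' @return an object of class `gs_draft`
#' @export
new_model_draft <- function(species_id, metabolites, reactions,
                            objective = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  need <- c("id", "base_id", "compartment", "extracellular", "formula", "name")
  stopifnot(all(need %in% names(metabolites)))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids in model ", species_id)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(names(reactions)))
    stop("duplicate reaction ids in model ", species_id)
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), metabolites$id)
    if (length(unknown))
      stop("reaction ", r$id, " references unknown metabolites: ",
           paste(unknown, collapse = ", "))
    if (r$kind == "exchange") {
      ext <- metabolites$extracellular[match(names(r$stoich), metabolites$id)]
      if (sum(ext) != 1L)
        stop("exchange reaction ", r$id,
             " must touch exactly one extracellular metabolite")
    }
  }
  structure(list(species_id = species_id,
                 metabolites = metabolites,
                 reactions = reactions,
                 objective = objective),
            class = "gs_draft")
}

#' @export
print.gs_draft <- function(x, ...) {
  cat("<gs_draft> ", x$species_id, ": ",
      nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, objective = ",
      if (is.null(x$objective)) "<unset>" else x$objective, "\n", sep = "")
  invisible(x)
}

#' Read a curation-edit table
#'
#' Edits are stored as CSV with columns `model_id`, `action`,
#' `reaction_id` and `payload` (a JSON object with action-specific
#' fields). Supported actions: `delete_reaction`, `add_reaction`,
#' `set_reversible`, `set_bounds`, `set_objective`.
#'
#' @param path CSV file path
#' @return data.frame of edits (payload kept as JSON text)
#' @export
read_curation_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("model_id", "action", "reaction_id", "payload") %in% names(df)))
  ok <- c("delete_reaction", "add_reaction", "set_reversible",
          "set_bounds", "set_objective")
  bad <- setdiff(df$action, ok)
  if (length(bad)) stop("unknown curation actions: ", paste(bad, collapse = ", "))
  df
}

#' Apply curation edits to a model draft
#'
#' Edits are applied in listed order; rows whose `model_id` does not match
#' the draft are ignored, so one table can curate a whole roster. A log of
#' applied edits is attached as attribute `"edit_log"`.
#'
#' @param draft a [new_model_draft()] object
#' @param edits data.frame as returned by [read_curation_csv()]
#' @return the edited draft
#' @export
apply_curation_edits <- function(draft, edits) {
  stopifnot(inherits(draft, "gs_draft"))
  edits <- edits[edits$model_id == draft$species_id, , drop = FALSE]
  log <- character(0)
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    payload <- if (is.na(e$payload) || !nzchar(e$payload)) list()
               else jsonlite::fromJSON(e$payload)
    rid <- e$reaction_id
    if (e$action == "add_reaction") {
      if (rid %in% names(draft$reactions))
        stop("add_reaction: reaction ", rid, " already exists in ",
             draft$species_id)
      stoich <- unlist(payload$stoich)
      rx <- list(id = rid, stoich = stoich,
                 reversible = isTRUE(payload$reversible),
                 kind = if (!is.null(payload$kind)) payload$kind else "internal",
                 lb = if (!is.null(payload$lb)) payload$lb else
                   if (isTRUE(payload$reversible)) -Inf else 0,
                 ub = if (!is.null(payload$ub)) payload$ub else Inf)
      draft <- new_model_draft(draft$species_id, draft$metabolites,
                               c(draft$reactions, list(rx)), draft$objective)
    } else {
      if (!rid %in% names(draft$reactions))
        stop(e$action, ": reaction ", rid, " not found in ", draft$species_id)
      if (e$action == "delete_reaction") {
        draft$reactions[[rid]] <- NULL
        if (identical(draft$objective, rid)) draft$objective <- NULL
      } else if (e$action == "set_reversible") {
        rev <- isTRUE(payload$reversible)
        draft$reactions[[rid]]$reversible <- rev
        if (rev && draft$reactions[[rid]]$lb == 0)
          draft$reactions[[rid]]$lb <- -Inf
        if (!rev) draft$reactions[[rid]]$lb <-
          max(draft$reactions[[rid]]$lb, 0)
      } else if (e$action == "set_bounds") {
        if (!is.null(payload$lb)) draft$reactions[[rid]]$lb <- payload$lb
        if (!is.null(payload$ub)) draft$reactions[[rid]]$ub <- payload$ub
      } else if (e$action == "set_objective") {
        draft$objective <- rid
      }
    }
    log <- c(log, paste(e$action, rid))
  }
  attr(draft, "edit_log") <- c(attr(draft, "edit_log"), log)
  draft
}

#' Set an ATP-production objective
#'
#' Replaces the model objective with an ATP drain (ATP + H2O -> ADP + Pi,
#' plus a proton where the species definitions require it for elemental
#' neutrality). The drain only cycles the energy currency, so it removes no
#' atoms from the medium: growth is measured as moles of ATP regenerated
#' per timestep per population unit. If a reaction with exactly this
#' stoichiometry already exists it is reused, making the operation
#' idempotent.
#'
#' @param draft a model draft containing ATP, ADP and phosphate species
#' @param compartment compartment of the currency metabolites
#' @return the draft with `objective` set (reaction id `R_ATP_DRAIN` if
#'   newly created)
#' @export
set_atp_objective <- function(draft, compartment = "c") {
  stopifnot(inherits(draft, "gs_draft"))
  mid <- function(base) {
    i <- which(draft$metabolites$base_id == base &
               draft$metabolites$compartment == compartment)
    if (length(i)) draft$metabolites$id[i[1]] else NA_character_
  }
  atp <- mid("atp"); adp <- mid("adp"); pi <- mid("pi"); h2o <- mid("h2o")
  if (is.na(atp) || is.na(adp) || is.na(pi) || is.na(h2o))
    stop("model ", draft$species_id,
         " lacks ATP/ADP/Pi/H2O species; cannot set ATP objective")
  h <- mid("h")
  base <- c(-1, -1, 1, 1)
  names(base) <- c(atp, h2o, adp, pi)
  cand <- list(base)
  if (!is.na(h)) cand <- c(cand, list(c(base, setNames(1, h))))
  # choose the variant that is elementally neutral under the species formulas
  fm <- parse_formula(draft$metabolites$formula)
  rownames(fm) <- draft$metabolites$id
  pick <- NULL
  for (st in cand) {
    f <- fm[names(st), , drop = FALSE]
    if (anyNA(f)) { if (is.null(pick)) pick <- st; next }
    net <- colSums(f * st)
    if (all(abs(net) < 1e-9)) { pick <- st; break }
  }
  if (is.null(pick))
    stop("no elementally neutral ATP drain found for ", draft$species_id)
  # reuse an identical existing reaction
  for (r in draft$reactions) {
    s <- r$stoich[order(names(r$stoich))]
    p <- pick[order(names(pick))]
    if (length(s) == length(p) && all(names(s) == names(p)) &&
        all(s == p) && !r$reversible) {
      draft$objective <- r$id
      return(draft)
    }
  }
  rx <- list(id = "R_ATP_DRAIN", stoich = pick, reversible = FALSE,
             kind = "internal", lb = 0, ub = Inf)
  draft <- new_model_draft(draft$species_id, draft$metabolites,
                           c(draft$reactions, list(rx)), "R_ATP_DRAIN")
  draft
}

#' Compile a draft to an LP-ready model
#'
#' Converts every reversible reaction into two irreversible columns so all
#' fluxes are nonnegative, assembles the stoichiometric matrix, and builds
#' the exchange index linking columns to extracellular metabolites. Flux
#' units are umol per timestep per population unit (1e10 bacteria).
#'
#' @param draft a curated draft with the objective set
#' @return an object of class `gs_model` with elements `species_id`, `S`
#'   (metabolites x columns), `cols` (column metadata incl. reaction id and
#'   direction), `col_ub` (static upper bounds), `obj_col`, `exch`
#'   (exchange column index: column, metabolite base id, direction), `mets`
#'   (metabolite table) and `formulas`
#' @export
compile_model <- function(draft) {
  stopifnot(inherits(draft, "gs_draft"))
  if (is.null(draft$objective))
    stop("draft ", draft$species_id, " has no objective; see set_atp_objective()")
  mets <- draft$metabolites
  nr <- length(draft$reactions)
  ids <- character(0); dir <- integer(0); ub <- numeric(0); kind <- character(0)
  for (r in draft$reactions) {
    ids <- c(ids, r$id); dir <- c(dir, 1L)
    ub <- c(ub, max(r$ub, 0)); kind <- c(kind, r$kind)
    if (r$reversible || r$lb < 0) {
      ids <- c(ids, r$id); dir <- c(dir, -1L)
      ub <- c(ub, if (r$lb == -Inf) Inf else -r$lb); kind <- c(kind, r$kind)
    }
  }
  S <- matrix(0, nrow = nrow(mets), ncol = length(ids),
              dimnames = list(mets$id, NULL))
  for (j in seq_along(ids)) {
    st <- draft$reactions[[ids[j]]]$stoich
    S[names(st), j] <- S[names(st), j] + st * dir[j]
  }
  cols <- data.frame(col = seq_along(ids), rxn_id = ids, dir = dir,
                     kind = kind, stringsAsFactors = FALSE)
  obj_col <- which(ids == draft$objective & dir == 1L)[1]
  if (is.na(obj_col)) stop("objective reaction not compiled")
  # exchange index: effect of each exchange column on its extracellular row
  exch <- NULL
  for (j in which(kind == "exchange")) {
    st <- draft$reactions[[ids[j]]]$stoich
    ext <- names(st)[mets$extracellular[match(names(st), mets$id)]]
    eff <- st[ext] * dir[j]
    exch <- rbind(exch, data.frame(
      col = j, met = mets$base_id[match(ext, mets$id)],
      coef = abs(unname(eff)),
      direction = if (eff > 0) "in" else "out", stringsAsFactors = FALSE))
  }
  fm <- parse_formula(mets$formula)
  rownames(fm) <- mets$id
  structure(list(species_id = draft$species_id, S = S, cols = cols,
                 col_ub = ub, obj_col = obj_col, exch = exch, mets = mets,
                 formulas = fm, objective = draft$objective),
            class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cat("<gs_model> ", x$species_id, ": ", nrow(x$S), " metabolites x ",
      ncol(x$S), " irreversible columns, ",
      sum(x$cols$kind == "exchange" & x$cols$dir == 1), " exchange reactions\n",
      sep = "")
  invisible(x)
}

#' Net reaction fluxes from a compiled-model flux vector
#'
#' Folds the split irreversible columns back to signed per-reaction fluxes.
#'
#' @param model a `gs_model`
#' @param flux per-column flux vector
#' @return named numeric vector of net fluxes per reaction id
#' @export
net_fluxes <- function(model, flux) {
  v <- flux * model$cols$dir
  tapply(v, model$cols$rxn_id, sum)[unique(model$cols$rxn_id)]
}
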