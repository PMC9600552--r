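#' Load a metabolic model from SBML
#'
#' Reads an SBML Level 3 file with FBC-style flux bounds (parameter-valued
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` attributes, with `INF`
#' sentinels) and returns a model draft. Reactions identified as exchange,
#' sink or demand (id prefixes `EX_`, `DM_`, `SK_`, `sink_`, optionally
#' after an `R_` prefix, or any reaction touching a single species) are
#' marked `kind = "exchange"`; these are the reactions through which the
#' model trades metabolites with the lattice environment.
#'
#' @param path SBML file
#' @param species_id optional species identifier; defaults to the SBML
#'   model id
#' @return a [new_model_draft()] object
#' @export
load_sbml <- function(path, species_id = NULL) {
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing")) stop("no <model> element in ", path)
  if (is.null(species_id)) {
    species_id <- xml2::xml_attr(model, "id")
    if (is.na(species_id)) species_id <- basename(path)
  }

  num <- function(x) {
    ifelse(x == "INF", Inf, ifelse(x == "-INF", -Inf,
           suppressWarnings(as.numeric(x))))
  }
  pars <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- setNames(num(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))

  attr_ns <- function(node, name) {
    a <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", name, "$"), names(a))
    if (length(hit)) a[[hit[1]]] else NA_character_
  }

  sp <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp)) stop("no species in SBML model ", path)
  sid <- xml2::xml_attr(sp, "id")
  comp <- xml2::xml_attr(sp, "compartment")
  nm <- xml2::xml_attr(sp, "name")
  formula <- vapply(sp, attr_ns, "", name = "chemicalFormula")
  id <- sub("^M_", "", sid)
  base_id <- mapply(function(i, cc) sub(paste0("_", cc, "$"), "", i),
                    id, comp, USE.NAMES = FALSE)
  mets <- data.frame(id = id, base_id = base_id, compartment = comp,
                     extracellular = comp == "e",
                     formula = ifelse(is.na(formula) | formula == "",
                                      NA_character_, formula),
                     name = ifelse(is.na(nm), id, nm),
                     stringsAsFactors = FALSE)

  rxn_nodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- list()
  for (rn in rxn_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(rn, paste0(
        "./*[local-name()='", tag, "']/*[local-name()='speciesReference']"))
      if (!length(refs)) return(numeric(0))
      s <- xml2::xml_attr(refs, "stoichiometry")
      s[is.na(s)] <- "1"
      setNames(sign * as.numeric(s), sub("^M_", "", xml2::xml_attr(refs, "species")))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", +1))
    st <- tapply(st, names(st), sum)
    st <- setNames(as.numeric(st), names(st))
    lbp <- attr_ns(rn, "lowerFluxBound")
    ubp <- attr_ns(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else
      if (rev) -Inf else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else Inf
    is_exch <- grepl("^(R_)?(EX|DM|SK|sink)_", rid) || length(st) == 1L
    reactions[[rid]] <- list(id = rid, stoich = st, reversible = rev,
                             kind = if (is_exch) "exchange" else "internal",
                             lb = lb, ub = ub)
  }
  if (!length(reactions)) stop("no reactions in SBML model ", path)
  new_model_draft(species_id, mets, reactions)
}

#' Write a model draft as SBML
#'
#' Emits SBML Level 3 Version 1 with FBC v2 flux-bound parameters and
#' `fbc:chemicalFormula` annotations, the dialect [load_sbml()] reads.
#' Output is deterministic (reactions and species in draft order).
#'
#' @param draft a [new_model_draft()] object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sbml <- function(draft, path) {
  stopifnot(inherits(draft, "gs_draft"))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  fmtnum <- function(x) {
    if (x == Inf) "INF" else if (x == -Inf) "-INF"
    else format(x, scientific = FALSE, digits = 12)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="false">', esc(draft$species_id)),
    '    <listOfCompartments>')
  for (cc in unique(draft$metabolites$compartment))
    lines <- c(lines, sprintf(
      '      <compartment id="%s" constant="true"/>', cc))
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(draft$metabolites))) {
    m <- draft$metabolites[i, ]
    f <- if (is.na(m$formula)) "" else
      sprintf(' fbc:chemicalFormula="%s"', m$formula)
    lines <- c(lines, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"%s/>'),
      m$id, esc(m$name), m$compartment, f))
  }
  lines <- c(lines, '    </listOfSpecies>')

  # collect distinct bounds as parameters
  bvals <- unique(c(vapply(draft$reactions, function(r) r$lb, 0),
                    vapply(draft$reactions, function(r) r$ub, 0)))
  bid <- function(v) {
    if (v == Inf) "b_inf" else if (v == -Inf) "b_neginf"
    else paste0("b_", gsub("[^0-9a-zA-Z]", "_", fmtnum(v)))
  }
  lines <- c(lines, '    <listOfParameters>')
  for (v in bvals)
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      bid(v), fmtnum(v)))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in draft$reactions) {
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      r$id, if (r$reversible) "true" else "false", bid(r$lb), bid(r$ub)))
    neg <- r$stoich[r$stoich < 0]; pos <- r$stoich[r$stoich > 0]
    if (length(neg)) {
      lines <- c(lines, '        <listOfReactants>')
      for (k in seq_along(neg))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="M_%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          names(neg)[k], fmtnum(-neg[[k]])))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(pos)) {
      lines <- c(lines, '        <listOfProducts>')
      for (k in seq_along(pos))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="M_%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          names(pos)[k], fmtnum(pos[[k]])))
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
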