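# Biochemical and thermodynamic plausibility audits applied to every FBA
# solution: no atoms may be created or destroyed by the exchanged fluxes,
# and the free energy of the outputs may not exceed that of the inputs.

#' Extracellular formula matrix of a compiled model
#'
#' @param model a [compile_model()] object
#' @return numeric matrix (extracellular base ids x C,H,O,N)
#' @export
ext_formulas <- function(model) {
  m <- model$mets[model$mets$extracellular, ]
  fm <- parse_formula(m$formula)
  rownames(fm) <- m$base_id
  fm
}

#' Net elemental exchange of an FBA solution
#'
#' Computes `sum_i (F_out(i) - F_in(i)) * formula(i)` for C, H, O and N
#' over the exchanged metabolites. A valid solution leaves the medium's
#' atom counts unchanged to within 1e-8 umol.
#'
#' @param result a [solve_step()] result
#' @param formulas matrix with rows named by base metabolite id and
#'   columns C,H,O,N (see [ext_formulas()]), or a named character vector
#'   of formulas
#' @return numeric vector of net element exchange (umol of atoms) with
#'   names C,H,O,N
#' @export
atom_balance <- function(result, formulas) {
  if (is.character(formulas)) formulas <- parse_formula(formulas)
  net <- result$F_out - result$F_in[names(result$F_out)]
  act <- names(net)[abs(net) > 0]
  missing <- setdiff(act, rownames(formulas))
  bad <- act[act %in% rownames(formulas)][
    apply(is.na(formulas[intersect(act, rownames(formulas)), , drop = FALSE]),
          1, any)]
  if (length(missing) || length(bad))
    stop("no formula for exchanged metabolite(s): ",
         paste(unique(c(missing, bad)), collapse = ", "))
  if (!length(act)) return(c(C = 0, H = 0, O = 0, N = 0))
  drop(net[act] %*% formulas[act, , drop = FALSE])
}

#' Gibbs free-energy audit of an FBA solution
#'
#' Computes the free-energy change of the exchanged matter,
#' `l = sum_i F_net_out(i) * E(i)`, with `E` the transformed formation
#' energies (J/mol, pH 7, ionic strength 0.1 M) and net outputs positive:
#' `l` is then the free energy of the outputs minus that of the inputs
#' (units: 1e-6 J per population unit, since fluxes are in umol). A
#' thermodynamically admissible solve has `l <= 0`; `l = 0` is accepted
#' only at (near-)zero growth. Metabolites without an energy entry are
#' excluded with a warning and the audit is marked partial.
#'
#' @param result a [solve_step()] result
#' @param energies named numeric of formation energies in J/mol (see
#'   [read_gibbs_csv()], [toy_gibbs_energies()])
#' @param tol absolute tolerance on `l` (1e-6 J umol/mol)
#' @param growth_eps growth below which zero energy change is admissible
#' @return list: `l` (energy change, outputs minus inputs), `admissible`,
#'   `partial` (TRUE if metabolites were skipped)
#' @export
gibbs_audit <- function(result, energies, tol = 1e-6, growth_eps = 1e-9) {
  net <- result$F_out - result$F_in[names(result$F_out)]
  act <- names(net)[abs(net) > 0]
  have <- act %in% names(energies)
  partial <- FALSE
  if (any(!have)) {
    warning("no Gibbs energy for: ", paste(act[!have], collapse = ", "),
            "; audit is partial")
    partial <- TRUE
    act <- act[have]
  }
  l <- if (length(act)) sum(net[act] * energies[act]) else 0
  admissible <- (l < -tol) || (abs(l) <= tol && result$growth_atp <= growth_eps)
  list(l = l, admissible = admissible, partial = partial)
}

#' Validity checks for a compiled model
#'
#' Reproduces the three per-model plausibility tests: (a) positive growth
#' on a lactose-only medium, (b) positive growth on a lactate-only medium
#' (the niche of obligate lactate consumers), and (c) exactly zero growth
#' when every uptake bound except water is zero.
#'
#' @param model a [compile_model()] object
#' @param amount substrate amount (umol) offered in tests (a) and (b)
#' @param B test population size
#' @param a enzymatic constraint
#' @return list with growth values `on_lactose`, `on_lactate`,
#'   `no_substrate` and logical flags `grows_on_lactose`,
#'   `grows_on_lactate`, `no_spurious_growth`
#' @export
model_checks <- function(model, amount = 10, B = POP_UNIT, a = 2) {
  g <- function(amounts)
    solve_step(model, B, uptake_bounds(amounts, B), a = a)$growth_atp
  on_lactose <- g(c(lcts = amount))
  on_lactate <- g(c(lac_L = amount))
  no_substrate <- g(c())
  list(on_lactose = on_lactose, on_lactate = on_lactate,
       no_substrate = no_substrate,
       grows_on_lactose = on_lactose > 1e-9,
       grows_on_lactate = on_lactate > 1e-9,
       no_spurious_growth = abs(no_substrate) <= 1e-12)
}
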