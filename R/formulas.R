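#' Parse an elemental formula into C/H/O/N counts
#'
#' Only carbon, hydrogen, oxygen and nitrogen are audited; other elements
#' (e.g. P in nucleotides) are parsed but dropped. In the simulated medium
#' only water, oxygen and lactose are ever introduced, so these four
#' elements suffice for the mass audit.
#'
#' @param formula character vector of formulas such as `"C12H22O11"`
#' @return numeric matrix with one row per formula and columns C, H, O, N
#' @examples
#' parse_formula(c("C12H22O11", "H2O", "O2"))
#' @export
parse_formula <- function(formula) {
  out <- matrix(0, nrow = length(formula), ncol = 4,
                dimnames = list(formula, c("C", "H", "O", "N")))
  for (i in seq_along(formula)) {
    f <- formula[i]
    if (is.na(f) || !nzchar(f)) {
      out[i, ] <- NA_real_
      next
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    if (m[1] == -1L) stop("cannot parse formula: ", f)
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (nchar(paste(toks, collapse = "")) != nchar(f))
      stop("cannot parse formula: ", f)
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      ct <- sub("^[A-Za-z]+", "", tok)
      ct <- if (nzchar(ct)) as.numeric(ct) else 1
      if (ct < 0) stop("negative element count in formula: ", f)
      if (el %in% colnames(out)) out[i, el] <- out[i, el] + ct
    }
  }
  out
}

#' Read a metabolite formula table
#'
#' Expected columns: `id`, `formula` (optionally `name`).
#'
#' @param path CSV file path
#' @return data.frame with parsed element counts attached as columns C,H,O,N
#' @export
read_formula_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "formula") %in% names(df)))
  cbind(df, parse_formula(df$formula))
}

#' Read a Gibbs free energy table
#'
#' Transformed formation energies at pH 7 and ionic strength 0.1 M, in
#' J/mol. Expected columns: `id`, `dG_J_per_mol`.
#'
#' @param path CSV file path
#' @return named numeric vector of energies (J/mol) keyed by metabolite id
#' @export
read_gibbs_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "dG_J_per_mol") %in% names(df)))
  setNames(df$dG_J_per_mol, df$id)
}
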