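# Shared fixtures: compiled toy models (cached per session) and small
# helpers used across test files.

toy_models <- build_toy_models()
toy_E <- toy_gibbs_energies()

desk_cfg <- function(seed, horizon = 960, ...) {
  sim_config(width = 60, height = 4, horizon = horizon, seed = seed,
             record_fluxes = FALSE, record_spatial_every = 0,
             audit = FALSE, ...)
}

# Independent LP oracle: scipy.optimize.linprog (HiGHS) driven through
# the system python. Solves min c'x s.t. A_ub x <= b_ub, A_eq x = b_eq,
# lb <= x <= ub. Infinities are encoded as +/-1e9 (far beyond any flux
# scale in these problems).
oracle_linprog <- function(c, Aub = NULL, bub = NULL, Aeq = NULL,
                           beq = NULL, lb = NULL, ub = NULL) {
  n <- length(c)
  if (is.null(lb)) lb <- rep(0, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  cap <- function(v) pmax(pmin(v, 1e9), -1e9)
  inp <- list(c = as.numeric(c), lb = cap(lb), ub = cap(ub))
  if (!is.null(Aub)) { inp$Aub <- unname(as.matrix(Aub)); inp$bub <- as.numeric(bub) }
  if (!is.null(Aeq)) { inp$Aeq <- unname(as.matrix(Aeq)); inp$beq <- as.numeric(beq) }
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(inp, digits = NA), fin)
  code <- paste(
    "import json, sys",
    "from scipy.optimize import linprog",
    "d = json.load(open(sys.argv[1]))",
    "res = linprog(c=d['c'], A_ub=d.get('Aub'), b_ub=d.get('bub'),",
    "              A_eq=d.get('Aeq'), b_eq=d.get('beq'),",
    "              bounds=list(zip(d['lb'], d['ub'])), method='highs')",
    "json.dump({'status': int(res.status),",
    "           'fun': None if res.fun is None else float(res.fun),",
    "           'x': None if res.x is None else list(map(float, res.x))},",
    "          open(sys.argv[2], 'w'))",
    sep = "\n")
  st <- system2("python", c("-c", shQuote(code), fin, fout),
                stdout = FALSE, stderr = FALSE)
  stopifnot(st == 0)
  jsonlite::fromJSON(fout)
}

# maximize x[obj] subject to S x = 0, 0 <= x <= ub, sum(x) <= cap
oracle_max_atp <- function(S, ub, cap, obj_col) {
  n <- ncol(S)
  keep <- rowSums(abs(S)) > 0
  out <- oracle_linprog(c = -as.numeric(seq_len(n) == obj_col),
                        Aub = matrix(1, 1, n), bub = cap,
                        Aeq = S[keep, , drop = FALSE],
                        beq = rep(0, sum(keep)),
                        lb = rep(0, n), ub = ub)
  stopifnot(out$status == 0)
  -out$fun
}

abundant <- function(model, B = 5e9, amounts = c(lcts = 100), a = 2)
  solve_step(model, B, uptake_bounds(amounts, B), a = a)
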