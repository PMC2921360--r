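# Residue, atomic and terminal-modification mass accounting.
#
# Two mass conventions coexist deliberately: monoisotopic masses drive MS
# fragment matching, average masses drive whole-protein kDa figures. Both
# tables carry all 20 standard residues; nonstandard codes (B, Z, X, U) are
# rejected rather than approximated.

.MONO_RESIDUE <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047679, V = 99.068414, W = 186.079313, Y = 163.063329
)

.AVG_RESIDUE <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
  C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
  H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
  M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
  T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)

.ATOM_MONO <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
.ATOM_AVG  <- c(H = 1.00794, C = 12.0107, N = 14.0067,
                O = 15.9994, S = 32.065)

.WATER_MONO <- 18.010565
.WATER_AVG  <- 18.01528
.PROTON     <- 1.00728

.AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", E = "Glu",
  Q = "Gln", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", V = "Val",
  W = "Trp", Y = "Tyr"
)

#' Residue mass table
#'
#' Returns the per-residue (i.e. dehydrated amino acid) masses used
#' throughout the package, together with the water and proton constants.
#'
#' @param mode `"monoisotopic"` or `"average"`.
#' @return A list with elements `mode`, `residue_masses` (named numeric,
#'   20 standard residues), `water_mass` and `proton_mass`, all in Da.
#' @examples
#' residue_masses("monoisotopic")$residue_masses[["G"]]
#' @export
residue_masses <- function(mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  list(
    mode = mode,
    residue_masses = if (mode == "monoisotopic") .MONO_RESIDUE else .AVG_RESIDUE,
    water_mass = if (mode == "monoisotopic") .WATER_MONO else .WATER_AVG,
    proton_mass = .PROTON
  )
}

# Validate a residue string; error names the offending character and its
# position. Used by every entry point that consumes sequences.
check_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  if (!nzchar(sequence))
    stop(what, " is empty", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(.MONO_RESIDUE))
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  chars
}

# Parse an elemental formula like "C7H5NO" into atom counts (C,H,N,O,S only).
parse_formula <- function(formula) {
  m <- gregexpr("([CHNOS])([0-9]*)", formula)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula '", formula, "' (C,H,N,O,S only)", call. = FALSE)
  parts <- regmatches(formula, gregexpr("([CHNOS])([0-9]*)", formula))[[1]]
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L
    counts[el] <- counts[el] + n
  }
  counts
}

formula_mass <- function(formula, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  counts <- parse_formula(formula)
  atoms <- if (mode == "monoisotopic") .ATOM_MONO else .ATOM_AVG
  sum(counts * atoms[names(counts)])
}

#' Define a terminal modification
#'
#' A terminal modification is a fixed mass delta applied exactly once to one
#' terminus of a peptide. The built-in registry covers the two tags of
#' internally quenched fluorogenic substrates -- the ortho-aminobenzoic acid
#' (Abz) fluorophore acylating the N-terminal amine, and the
#' ethylenediamine-2,4-dinitrophenyl (EDDnp) quencher amidating the
#' C-terminus -- plus plain C-terminal amidation.
#'
#' @param name Modification name.
#' @param site `"N_term"` or `"C_term"`.
#' @param delta_mono,delta_avg Mass deltas in Da. May be omitted when
#'   `formula` (an added composition) and `removed` (a removed composition,
#'   e.g. the hydroxyl displaced by an amide) are given instead.
#' @param formula,removed Elemental formulas (C,H,N,O,S) from which the
#'   deltas are computed when not given explicitly.
#' @return An object of class `terminal_modification`.
#' @examples
#' terminal_modification("acetyl", "N_term", formula = "C2H2O")
#' get_modification("Abz")
#' @export
terminal_modification <- function(name, site = c("N_term", "C_term"),
                                  delta_mono = NULL, delta_avg = NULL,
                                  formula = NULL, removed = NULL) {
  site <- match.arg(site)
  if (is.null(delta_mono) || is.null(delta_avg)) {
    if (is.null(formula))
      stop("either explicit deltas or a formula is required", call. = FALSE)
    delta_mono <- formula_mass(formula, "monoisotopic")
    delta_avg <- formula_mass(formula, "average")
    if (!is.null(removed)) {
      delta_mono <- delta_mono - formula_mass(removed, "monoisotopic")
      delta_avg <- delta_avg - formula_mass(removed, "average")
    }
  }
  structure(
    list(name = name, site = site,
         delta_mono = delta_mono, delta_avg = delta_avg),
    class = "terminal_modification"
  )
}

#' @export
print.terminal_modification <- function(x, ...) {
  cat(sprintf("<terminal modification> %s (%s): %+0.4f Da mono, %+0.4f Da avg\n",
              x$name, x$site, x$delta_mono, x$delta_avg))
  invisible(x)
}

.builtin_modifications <- function() {
  list(
    abz = terminal_modification("Abz", "N_term", formula = "C7H5NO"),
    eddnp = terminal_modification("EDDnp", "C_term",
                                  formula = "C8H9N4O4", removed = "OH"),
    amide = terminal_modification("amide", "C_term",
                                  formula = "NH2", removed = "OH")
  )
}

#' Look up a terminal modification by name
#'
#' @param name Name (case-insensitive); one of the built-ins (`"Abz"`,
#'   `"EDDnp"`, `"amide"`) or a name present in `registry`.
#' @param registry Optional list of `terminal_modification` objects, e.g.
#'   from [read_modifications()], searched before the built-ins.
#' @return A `terminal_modification`.
#' @export
get_modification <- function(name, registry = NULL) {
  if (inherits(name, "terminal_modification")) return(name)
  if (is.null(name)) return(NULL)
  key <- tolower(name)
  pool <- c(registry, .builtin_modifications())
  hit <- pool[tolower(vapply(pool, `[[`, "", "name")) == key]
  if (!length(hit))
    stop("unknown terminal modification '", name, "'", call. = FALSE)
  hit[[1]]
}

#' Read a terminal-modification registry from JSON
#'
#' Each entry carries `name`, `site` and either explicit `delta_mono` /
#' `delta_avg` or a `formula` (plus optional `removed` composition).
#'
#' @param path Path to a JSON array of modification records.
#' @return A named list of `terminal_modification` objects.
#' @export
read_modifications <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  mods <- lapply(recs, function(r) {
    terminal_modification(
      name = r$name, site = r$site,
      delta_mono = r$delta_mono, delta_avg = r$delta_avg,
      formula = r$formula, removed = r$removed
    )
  })
  names(mods) <- tolower(vapply(mods, `[[`, "", "name"))
  mods
}

#' Neutral mass of a (possibly tagged) peptide
#'
#' Sums residue masses plus one water, then applies at most one modification
#' per terminus.
#'
#' @param sequence Residue string (uppercase, 20 standard amino acids).
#' @param n_mod,c_mod Terminal modifications: a `terminal_modification`, a
#'   registered name, or `NULL` for a free terminus.
#' @param mode `"monoisotopic"` (default; used for fragment matching) or
#'   `"average"` (used for whole-protein masses).
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G")                        # glycine, 75.032 Da
#' peptide_mass("FLSQ", c_mod = "EDDnp")    # tagged C-terminal fragment
#' @export
peptide_mass <- function(sequence, n_mod = NULL, c_mod = NULL,
                         mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  chars <- check_sequence(sequence)
  tab <- residue_masses(mode)
  n_mod <- get_modification(n_mod)
  c_mod <- get_modification(c_mod)
  if (!is.null(n_mod) && n_mod$site != "N_term")
    stop("modification '", n_mod$name, "' is not an N-terminal modification",
         call. = FALSE)
  if (!is.null(c_mod) && c_mod$site != "C_term")
    stop("modification '", c_mod$name, "' is not a C-terminal modification",
         call. = FALSE)
  mass <- sum(tab$residue_masses[chars]) + tab$water_mass
  for (mod in list(n_mod, c_mod)) {
    if (is.null(mod)) next
    mass <- mass + if (mode == "monoisotopic") mod$delta_mono else mod$delta_avg
  }
  mass
}

#' Convert between neutral mass and m/z
#'
#' Singly protonated ions are the default convention throughout the package;
#' higher charge states are opt-in.
#'
#' @param neutral_mass Neutral mass in Da.
#' @param charge Positive integer charge.
#' @return `to_mz()`: m/z; `from_mz()`: the neutral mass in Da.
#' @examples
#' to_mz(374.217, 1)
#' from_mz(to_mz(374.217, 2), 2)
#' @export
to_mz <- function(neutral_mass, charge = 1L) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer", call. = FALSE)
  (neutral_mass + charge * .PROTON) / charge
}

#' @rdname to_mz
#' @param mz Observed m/z.
#' @export
from_mz <- function(mz, charge = 1L) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer", call. = FALSE)
  mz * charge - charge * .PROTON
}

# pKa sets for isoelectric-point estimation. "emboss" is the default;
# "expasy" follows the Bjellqvist-style constants. The computed pI depends
# materially on this choice, so results are always reported with the set name.
.PKA_SETS <- list(
  emboss = list(
    positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
    negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  ),
  expasy = list(
    positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
    negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  )
)

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over side chains and the two termini.
#'
#' @param sequence Residue string.
#' @param ph pH value (may be a vector).
#' @param pka_set `"emboss"` or `"expasy"`.
#' @return Net charge in elementary charges, same length as `ph`.
#' @export
net_charge <- function(sequence, ph, pka_set = "emboss") {
  chars <- check_sequence(sequence)
  pk <- .PKA_SETS[[match.arg(pka_set, names(.PKA_SETS))]]
  counts <- table(factor(chars, levels = names(.MONO_RESIDUE)))
  vapply(ph, function(p) {
    pos <- 1 / (1 + 10^(p - pk$positive["Nterm"]))
    neg <- -1 / (1 + 10^(pk$negative["Cterm"] - p))
    for (aa in setdiff(names(pk$positive), "Nterm"))
      pos <- pos + counts[[aa]] / (1 + 10^(p - pk$positive[[aa]]))
    for (aa in setdiff(names(pk$negative), "Cterm"))
      neg <- neg - counts[[aa]] / (1 + 10^(pk$negative[[aa]] - p))
    pos + neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] crosses zero, to `tol` elementary
#' charges.
#'
#' @inheritParams net_charge
#' @param tol Convergence tolerance on the net charge.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka_set = "emboss", tol = 1e-6) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka_set)
    if (abs(q) < tol || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Whole-protein parameters: length, average mass, pI
#'
#' Average-mass convention for the kDa figure (reported rounded to one
#' decimal, as is conventional for predicted protein masses); isoelectric
#' point by bisection under a named pKa set. An optional N-terminal
#' truncation (`mature_from`) reports the mature polypeptide after signal-
#' peptide removal.
#'
#' @param sequence Full (pre)protein residue string.
#' @param mature_from 1-based residue index at which the mature chain
#'   starts, or `NULL` for no truncation.
#' @param pka_set pKa set name for the pI ([net_charge()]).
#' @return A list with `length`, `mass_da`, `mass_kda` (1 decimal), `pi`
#'   and `pka_set`.
#' @examples
#' protein_params(strrep("G", 10))  # 588.5 Da -> 0.6 kDa
#' @export
protein_params <- function(sequence, mature_from = NULL, pka_set = "emboss") {
  chars <- check_sequence(sequence)
  if (!is.null(mature_from)) {
    if (mature_from < 1 || mature_from > length(chars))
      stop("mature_from out of range (1..", length(chars), ")", call. = FALSE)
    sequence <- substr(sequence, mature_from, nchar(sequence))
  }
  mass <- peptide_mass(sequence, mode = "average")
  list(
    length = nchar(sequence),
    mass_da = mass,
    mass_kda = round(mass / 1000, 1),
    pi = round(isoelectric_point(sequence, pka_set), 2),
    pka_set = pka_set
  )
}
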