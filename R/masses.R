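#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble
NULL

# Atomic masses: monoisotopic from the most abundant isotope, average from
# IUPAC standard atomic weights. Only the elements occurring in peptides and
# the supported modifications are listed.
.atomic_masses <- data.frame(
  element = c("H", "C", "N", "O", "S"),
  mono = c(1.0078250319, 12.0, 14.0030740052, 15.9949146221, 31.97207069),
  avg  = c(1.008, 12.011, 14.007, 15.999, 32.06)
)

#' Mass of an elemental formula
#'
#' Sums standard atomic masses over a condensed elemental formula such as
#' `"C8H13NO"` or `"C2H4"`. This is the single source of mass values in the
#' package: residue and modification masses are derived from their
#' compositions through this function, never hard-coded.
#'
#' @param formula Character vector of formulas (e.g. `"C6H12N2O"`). An element
#'   symbol without a count means one atom.
#' @param kind `"mono"` (monoisotopic) or `"avg"` (average).
#' @return Numeric vector of masses in Da.
#' @examples
#' formula_mass("H2O")            # 18.0106
#' formula_mass("C2H4", "avg")
#' @export
formula_mass <- function(formula, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(0)
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (sum(nchar(toks)) != nchar(f)) {
      abort(paste0("cannot parse elemental formula: '", f, "'"))
    }
    total <- 0
    for (tok in toks) {
      el <- gsub("[0-9]", "", tok)
      n <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", tok)))
      if (is.na(n)) n <- 1L
      i <- match(el, .atomic_masses$element)
      if (is.na(i)) abort(paste0("unknown element '", el, "' in formula '", f, "'"))
      total <- total + n * .atomic_masses[[kind]][i]
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

# Post-condensation (residue) compositions. S5 is
# (S)-2-(4'-pentenyl)alanine, the alpha-methyl, alpha-pentenyl residue used
# at both ends of an i,i+4 hydrocarbon staple.
.residue_compositions <- c(
  A = "C3H5NO",    C = "C3H5NOS",  D = "C4H5NO3",  E = "C5H7NO3",
  F = "C9H9NO",    G = "C2H3NO",   H = "C6H7N3O",  I = "C6H11NO",
  K = "C6H12N2O",  L = "C6H11NO",  M = "C5H9NOS",  N = "C4H6N2O2",
  P = "C5H7NO",    Q = "C5H8N2O2", R = "C6H12N4O", S = "C3H5NO2",
  T = "C4H7NO2",   V = "C5H9NO",   W = "C11H10N2O", Y = "C9H9NO2",
  S5 = "C8H13NO"
)

#' Residue specification table
#'
#' The 20 standard amino-acid residues plus the stapling residue `S5`
#' ((S)-2-(4'-pentenyl)alanine), with post-condensation elemental
#' compositions and monoisotopic/average residue masses computed from
#' [formula_mass()].
#'
#' @return A tibble with columns `token`, `composition`, `mono_mass`,
#'   `avg_mass`.
#' @export
residue_table <- function() {
  tibble(
    token = names(.residue_compositions),
    composition = unname(.residue_compositions),
    mono_mass = formula_mass(unname(.residue_compositions), "mono"),
    avg_mass = formula_mass(unname(.residue_compositions), "avg")
  )
}

# Terminal modifications as (gain, loss) elemental changes on the free
# terminus:
#   acetyl      N-terminal amine acylation: + C2H2O
#   amide       C-terminal acid -> primary amide: + NH2 - OH (net -0.984 Da)
#   biotinyl_Acp N-(+)-biotinyl-6-aminocaproic acid coupled as an amide:
#               + C16H27N3O4S - H2O
#   FITC        fluorescein isothiocyanate + amine -> thiourea, no atom loss:
#               + C21H11NO5S
.terminal_mods <- data.frame(
  name = c("free", "acetyl", "amide", "biotinyl_Acp", "FITC"),
  position = c("NC", "N", "C", "N", "N"),
  gain = c("", "C2H2O", "NH2", "C16H27N3O4S", "C21H11NO5S"),
  loss = c("", "", "OH", "H2O", "")
)

#' Terminal modification table
#'
#' Supported N- and C-terminal chemistries with their mass deltas, computed
#' from the elemental change of the coupling reaction. `acetyl`,
#' `biotinyl_Acp` and `FITC` apply at the N-terminus only, `amide` at the
#' C-terminus only; `free` applies anywhere and has zero delta.
#'
#' @return A tibble with columns `name`, `position` (allowed terminus),
#'   `delta_mono`, `delta_avg` (Da).
#' @export
terminal_mods <- function() {
  tibble(
    name = .terminal_mods$name,
    position = .terminal_mods$position,
    delta_mono = formula_mass(.terminal_mods$gain, "mono") -
      formula_mass(.terminal_mods$loss, "mono"),
    delta_avg = formula_mass(.terminal_mods$gain, "avg") -
      formula_mass(.terminal_mods$loss, "avg")
  )
}

.mod_delta <- function(name, terminus, kind) {
  tab <- terminal_mods()
  i <- match(name, tab$name)
  if (is.na(i)) abort(paste0("unknown terminal modification '", name, "'"))
  allowed <- tab$position[i]
  if (allowed != "NC" && allowed != terminus) {
    abort(paste0("terminal modification '", name, "' applies only at the ",
                 allowed, "-terminus"))
  }
  if (kind == "mono") tab$delta_mono[i] else tab$delta_avg[i]
}

# Bridge closure by ring-closing metathesis releases ethylene from the two
# terminal alkenes of the S5 side chains.
.staple_bridge_delta <- function(kind) -formula_mass("C2H4", kind)
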