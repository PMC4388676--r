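#' Create a peptide construct
#'
#' A peptide construct is an ordered run of residues numbered by their
#' position in the parent protein, with terminal chemistry and an optional
#' i,i+4 hydrocarbon staple between two `S5` residues.
#'
#' @param name Identifier, e.g. `"Cul3_49_68LA"`.
#' @param tokens Character vector of residue tokens (one-letter codes or
#'   `"S5"`).
#' @param start First residue's position in the parent protein. Positions are
#'   consecutive from there.
#' @param n_mod,c_mod Terminal modification names (see [terminal_mods()]).
#' @param staple `NULL`, or an integer pair `c(i, j)` of parent positions
#'   with `j == i + 4`; both positions must carry `S5`.
#' @param staple_closed Logical; `TRUE` once ring-closing metathesis has
#'   closed the bridge (subtracts one ethylene from the mass).
#' @return An object of class `peptide_construct`.
#' @examples
#' wt <- peptide_construct("Cul3_49_68",
#'   strsplit("NSGLSFEELYRNAYTMVLHK", "")[[1]],
#'   start = 49, n_mod = "acetyl", c_mod = "amide")
#' peptide_mass(wt)
#' @export
peptide_construct <- function(name, tokens, start, n_mod = "free",
                              c_mod = "free", staple = NULL,
                              staple_closed = TRUE) {
  stopifnot(is.character(tokens), length(tokens) >= 1)
  tab <- residue_table()
  bad <- setdiff(tokens, tab$token)
  if (length(bad)) {
    abort(paste0("unknown residue token(s): ", paste(unique(bad), collapse = ", ")))
  }
  positions <- seq.int(start, length.out = length(tokens))
  residues <- tibble(position = positions, token = tokens)
  # validate mods against their allowed terminus
  .mod_delta(n_mod, "N", "mono")
  .mod_delta(c_mod, "C", "mono")
  if (!is.null(staple)) {
    staple <- as.integer(staple)
    if (length(staple) != 2 || staple[2] - staple[1] != 4) {
      abort("staple must link positions i and i+4 (one helical turn)")
    }
    if (!all(staple %in% positions)) {
      abort("staple positions must lie within the peptide")
    }
    at <- residues$token[match(staple, residues$position)]
    if (!all(at == "S5")) {
      abort("both staple positions must carry the S5 residue")
    }
  }
  structure(
    list(name = name, residues = residues, n_mod = n_mod, c_mod = c_mod,
         staple = staple, staple_closed = if (is.null(staple)) FALSE else staple_closed),
    class = "peptide_construct"
  )
}

#' @export
print.peptide_construct <- function(x, ...) {
  seq_str <- paste(x$residues$token, collapse = "")
  cat("<peptide_construct> ", x$name, "\n", sep = "")
  cat("  span ", min(x$residues$position), "-", max(x$residues$position),
      ": ", seq_str, "\n", sep = "")
  cat("  N-terminus: ", x$n_mod, "; C-terminus: ", x$c_mod, "\n", sep = "")
  if (!is.null(x$staple)) {
    cat("  staple: ", x$staple[1], "-", x$staple[2],
        if (x$staple_closed) " (closed)" else " (open)", "\n", sep = "")
  }
  invisible(x)
}

#' Derive a peptide variant by substitution and optional stapling
#'
#' Builds a new construct from a parent by point substitutions (for example
#' placing `S5` at the two staple positions, or an alanine scan of interface
#' hot spots). The parent is unchanged.
#'
#' @param parent A [peptide_construct()].
#' @param substitutions Named list or vector mapping parent position to a new
#'   residue token, e.g. `c("57" = "S5", "61" = "S5")`.
#' @param staple_pair Optional `c(i, i + 4)` staple; both positions must be
#'   substituted to `S5`.
#' @param name Name of the variant; defaults to the parent name with
#'   `"_variant"` appended.
#' @return A new `peptide_construct`.
#' @export
build_variant <- function(parent, substitutions = list(), staple_pair = NULL,
                          name = paste0(parent$name, "_variant")) {
  stopifnot(inherits(parent, "peptide_construct"))
  tokens <- parent$residues$token
  positions <- parent$residues$position
  subs <- unlist(substitutions)
  if (length(subs)) {
    at <- as.integer(names(subs))
    missing_pos <- setdiff(at, positions)
    if (length(missing_pos)) {
      abort(paste0("substitution at position(s) not in parent: ",
                   paste(missing_pos, collapse = ", ")))
    }
    tokens[match(at, positions)] <- unname(subs)
  }
  if (!is.null(staple_pair)) {
    staple_pair <- as.integer(staple_pair)
    if (length(staple_pair) != 2 || staple_pair[2] - staple_pair[1] != 4) {
      abort("staple_pair must span one helical turn: j = i + 4")
    }
    if (!all(as.character(staple_pair) %in% names(subs)) ||
        !all(subs[as.character(staple_pair)] == "S5")) {
      abort("staple positions must be substituted to S5")
    }
  }
  peptide_construct(name, tokens, start = positions[1],
                    n_mod = parent$n_mod, c_mod = parent$c_mod,
                    staple = staple_pair)
}

#' Built-in Cul3 helix-2 peptide panel
#'
#' The wild-type Cullin3 helix-2 peptide (residues 49-68,
#' `NSGLSFEELYRNAYTMVLHK`, acetylated/amidated to mimic its charge state in
#' the parent protein) and the four characterized variants: the two central
#' staples EN (56-60) and LA (57-61), the N-terminal staple SL (53-57), and
#' the AA double-alanine control replacing the interface tyrosines 58 and 62.
#'
#' @return Named list of [peptide_construct()] objects
#'   (`wt`, `EN`, `LA`, `SL`, `AA`).
#' @export
cul3_peptides <- function() {
  wt <- peptide_construct(
    "Cul3_49_68", strsplit("NSGLSFEELYRNAYTMVLHK", "")[[1]],
    start = 49, n_mod = "acetyl", c_mod = "amide"
  )
  list(
    wt = wt,
    EN = build_variant(wt, c("56" = "S5", "60" = "S5"), c(56, 60), "Cul3_49_68EN"),
    LA = build_variant(wt, c("57" = "S5", "61" = "S5"), c(57, 61), "Cul3_49_68LA"),
    SL = build_variant(wt, c("53" = "S5", "57" = "S5"), c(53, 57), "Cul3_49_68SL"),
    AA = build_variant(wt, c("58" = "A", "62" = "A"), name = "Cul3_49_68AA")
  )
}

#' Monoisotopic or average mass of a peptide or fragment
#'
#' Mass = sum of residue masses + water + terminal deltas, minus one
#' ethylene if the construct carries a closed hydrocarbon staple.
#'
#' @param p A [peptide_construct()] or a `proteolytic_fragment` row produced
#'   by [enumerate_fragments()].
#' @param kind `"mono"` or `"avg"`.
#' @return Mass in Da.
#' @export
peptide_mass <- function(p, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  stopifnot(inherits(p, "peptide_construct"))
  tab <- residue_table()
  i <- match(p$residues$token, tab$token)
  if (anyNA(i)) {
    abort(paste0("unknown residue token: ",
                 paste(unique(p$residues$token[is.na(i)]), collapse = ", ")))
  }
  col <- if (kind == "mono") tab$mono_mass else tab$avg_mass
  m <- sum(col[i]) + formula_mass("H2O", kind) +
    .mod_delta(p$n_mod, "N", kind) + .mod_delta(p$c_mod, "C", kind)
  if (!is.null(p$staple) && isTRUE(p$staple_closed)) {
    m <- m + .staple_bridge_delta(kind)
  }
  m
}
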