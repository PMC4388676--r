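#' Construct a structure model from an atom table
#'
#' A structure model is a tibble of atoms (one row each) with class
#' `structure_model`. Coordinates are in Angstrom; residue numbering is taken
#' verbatim from the input (peptide residues keep their parent-protein
#' numbering).
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`, `chain`,
#'   `res_index`, `res_name`, `x`, `y`, `z`.
#' @return A `structure_model` tibble.
#' @export
structure_model <- function(atoms) {
  req <- c("serial", "name", "element", "chain", "res_index", "res_name",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)[, union(req, names(atoms))]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("all coordinates must be finite")
  }
  key <- paste(atoms$chain, atoms$res_index, atoms$name, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- strsplit(key[which(dup)[1]], "|", fixed = TRUE)[[1]]
    abort(paste0("duplicate atom: chain ", d[1], ", residue ", d[2],
                 ", atom ", d[3]))
  }
  class(atoms) <- c("structure_model", class(atoms))
  atoms
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nrow(x), " atoms, ",
      length(unique(x$chain)), " chain(s)\n", sep = "")
  NextMethod()
}

# Element from a PDB atom name: strip digits and primes, take the leading
# letter; two-letter elements do not occur in the supported subset.
.infer_element <- function(name) {
  toupper(substr(gsub("[0-9']", "", trimws(name)), 1, 1))
}

#' Bondi-style van der Waals radii
#'
#' The element radius table used for solvent accessibility. Hydrogens are
#' listed but excluded by default by [sasa()] (united-atom convention).
#'
#' @return A tibble with columns `element`, `radius` (Angstrom).
#' @export
vdw_radii <- function() {
  tibble(element = c("H", "C", "N", "O", "S", "P"),
         radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80))
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records (first MODEL only; see [read_trajectory()] for
#' multi-model files) via bio3d, then validates coordinates and atom
#' uniqueness. A missing element column is inferred from the atom name with a
#' warning.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @return A [structure_model()].
#' @export
read_pdb <- function(source) {
  file <- .as_pdb_file(source)
  .scan_pdb_lines(readLines(file, warn = FALSE))
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                  error = function(e) abort(paste0("PDB parse failed: ", conditionMessage(e))))
  a <- pdb$atom
  elem <- trimws(as.character(a$elesy))
  if (any(!nzchar(elem) | is.na(elem))) {
    warn("element column missing for some atoms; inferred from atom names")
    bad <- !nzchar(elem) | is.na(elem)
    elem[bad] <- .infer_element(a$elety[bad])
  }
  chain <- as.character(a$chain)
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  structure_model(tibble(
    serial = as.integer(a$eleno), name = trimws(a$elety), element = elem,
    chain = chain, res_index = as.integer(a$resno),
    res_name = trimws(a$resid), x = a$x, y = a$y, z = a$z
  ))
}

.as_pdb_file <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    return(source)
  }
  file <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(source, "\n")), file)
  file
}

.scan_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords)) {
      abort(paste0("malformed coordinate fields at line ", i))
    }
  }
  invisible(TRUE)
}

#' Write a structure model as PDB text
#'
#' @param s A [structure_model()].
#' @param file Optional path; if `NULL` the PDB text is returned as a
#'   character vector of lines.
#' @return The file path (invisibly) or the lines.
#' @export
write_pdb <- function(s, file = NULL) {
  stopifnot(inherits(s, "structure_model"))
  out <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    file = out,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    resno = s$res_index, resid = s$res_name, eleno = s$serial,
    elety = s$name, chain = s$chain, elesy = s$element
  )
  if (is.null(file)) readLines(out, warn = FALSE) else invisible(out)
}

#' Extract coordinates of a selection as a matrix
#'
#' @param s A [structure_model()].
#' @param atom_names Atom names to keep (default `"CA"`).
#' @param chain Optional chain filter.
#' @return An n x 3 matrix ordered by chain then residue index.
#' @export
coords_matrix <- function(s, atom_names = "CA", chain = NULL) {
  d <- s
  if (!is.null(chain)) d <- d[d$chain %in% chain, ]
  if (!is.null(atom_names)) d <- d[d$name %in% atom_names, ]
  d <- d[order(d$chain, d$res_index), ]
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- paste(d$chain, d$res_index, d$name, sep = "_")
  m
}
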