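#' Enumerate proteolytic fragments under partial digestion
#'
#' Cleavage sites mean "cut after this residue". Partial digestion is
#' assumed: every contiguous span delimited by the peptide ends and any
#' subset of the cuts is emitted, so overlapping fragments coexist (e.g. the
#' 49-58 and 49-59 fragments of the wild-type peptide when both Tyr58 and
#' Arg59 sites are used). A fragment starting at the parent's first residue
#' inherits the parent's N-terminal modification, otherwise its N-terminus is
#' free; symmetrically at the C-terminus. For a parent with a closed staple,
#' spans containing exactly one of the two stapled positions are excluded
#' (the hydrocarbon bridge covalently ties them together).
#'
#' @param p A [peptide_construct()].
#' @param cleavage_sites Integer vector of interior parent positions.
#' @return A tibble with one row per fragment: `parent`, `start`, `end`,
#'   `sequence`, `n_mod`, `c_mod`, `mono_mass`, `avg_mass`, and a
#'   `construct` list-column holding the fragment as a `peptide_construct`.
#' @export
enumerate_fragments <- function(p, cleavage_sites = integer()) {
  stopifnot(inherits(p, "peptide_construct"))
  pos <- p$residues$position
  first <- pos[1]
  last <- pos[length(pos)]
  cuts <- sort(unique(as.integer(cleavage_sites)))
  if (length(cuts) && (any(cuts < first) || any(cuts >= last))) {
    abort("cleavage sites must be interior positions (first <= site < last)")
  }
  starts <- c(first, cuts + 1L)
  ends <- c(cuts, last)
  spans <- expand.grid(start = starts, end = ends)
  spans <- spans[spans$start <= spans$end, , drop = FALSE]
  if (!is.null(p$staple) && isTRUE(p$staple_closed)) {
    i <- p$staple[1]; j <- p$staple[2]
    has_i <- spans$start <= i & i <= spans$end
    has_j <- spans$start <= j & j <= spans$end
    spans <- spans[has_i == has_j, , drop = FALSE]
  }
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  frags <- purrr::pmap(spans, function(start, end) {
    sel <- pos >= start & pos <= end
    n_mod <- if (start == first) p$n_mod else "free"
    c_mod <- if (end == last) p$c_mod else "free"
    keep_staple <- !is.null(p$staple) && p$staple[1] >= start && p$staple[2] <= end
    peptide_construct(
      paste0(p$name, "_", start, "_", end),
      p$residues$token[sel], start = start, n_mod = n_mod, c_mod = c_mod,
      staple = if (keep_staple) p$staple else NULL,
      staple_closed = if (keep_staple) p$staple_closed else FALSE
    )
  })
  tibble(
    parent = p$name,
    start = spans$start,
    end = spans$end,
    sequence = purrr::map_chr(frags, ~ paste(.x$residues$token, collapse = "")),
    n_mod = purrr::map_chr(frags, "n_mod"),
    c_mod = purrr::map_chr(frags, "c_mod"),
    mono_mass = purrr::map_dbl(frags, peptide_mass, kind = "mono"),
    avg_mass = purrr::map_dbl(frags, peptide_mass, kind = "avg"),
    construct = frags
  )
}

#' Assign observed LC-MS masses to proteolytic fragments
#'
#' Each observed mass is matched to the fragment minimizing the absolute mass
#' difference, provided it falls within `tol`; otherwise it is reported
#' unassigned. Ties are broken toward the longer span, then the lower start
#' position.
#'
#' @param observed Numeric vector of observed masses (Da).
#' @param fragments Fragment table from [enumerate_fragments()].
#' @param tol Matching tolerance in Da (default 1, ion-trap ESI accuracy).
#' @param kind Compare against `"mono"` (default) or `"avg"` fragment masses.
#' @return A tibble with `observed`, `start`, `end`, `sequence`, `n_mod`,
#'   `c_mod`, `fragment_mass`, `delta` (observed - fragment), and `assigned`.
#'   Unassigned rows carry `NA` fragment fields.
#' @export
assign_masses <- function(observed, fragments, tol = 1.0,
                          kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  stopifnot(tol > 0)
  mass_col <- if (kind == "mono") "mono_mass" else "avg_mass"
  empty <- tibble(
    observed = numeric(), start = integer(), end = integer(),
    sequence = character(), n_mod = character(), c_mod = character(),
    fragment_mass = numeric(), delta = numeric(), assigned = logical()
  )
  if (!length(observed)) return(empty)
  purrr::map_dfr(observed, function(m) {
    if (!nrow(fragments)) {
      return(tibble(observed = m, start = NA_integer_, end = NA_integer_,
                    sequence = NA_character_, n_mod = NA_character_,
                    c_mod = NA_character_, fragment_mass = NA_real_,
                    delta = NA_real_, assigned = FALSE))
    }
    d <- abs(m - fragments[[mass_col]])
    ord <- order(d, -(fragments$end - fragments$start), fragments$start)
    best <- ord[1]
    if (d[best] <= tol) {
      tibble(observed = m, start = as.integer(fragments$start[best]),
             end = as.integer(fragments$end[best]),
             sequence = fragments$sequence[best],
             n_mod = fragments$n_mod[best], c_mod = fragments$c_mod[best],
             fragment_mass = fragments[[mass_col]][best],
             delta = m - fragments[[mass_col]][best], assigned = TRUE)
    } else {
      tibble(observed = m, start = NA_integer_, end = NA_integer_,
             sequence = NA_character_, n_mod = NA_character_,
             c_mod = NA_character_, fragment_mass = NA_real_,
             delta = NA_real_, assigned = FALSE)
    }
  })
}
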