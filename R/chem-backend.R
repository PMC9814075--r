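# OpenBabel-backed chemistry primitives. All SMILES interpretation in the
# package funnels through these helpers so that canonicalization, property
# estimation and substructure matching agree with one perception model.

ob_no2d <- data.frame(names = character(), args = character())

#' Canonical SMILES via OpenBabel
#'
#' Returns the canonical SMILES string for each input, or `NA` for strings
#' OpenBabel cannot parse. Explicit hydrogens are folded into implicit counts
#' and aromaticity is perceived (kekulized rings come back aromatic).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector, same length, `NA` where unparseable.
#' @export
ob_canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s, options = ob_no2d)),
      error = function(e) ""
    )
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Molecular properties from OpenBabel descriptors (MW g/mol, atom-contribution
# logP, H-bond donors/acceptors).
ob_properties <- function(smiles) {
  props <- purrr::map(smiles, function(s) {
    m <- ChemmineOB::forEachMol("SMILES", s, identity)
    p <- ChemmineOB::prop_OB(m)
    tibble::tibble(mw = p$MW, clogp = p$logP, hbd = p$HBD, hba = p$HBA1)
  })
  dplyr::bind_rows(props)
}

# Count matches of one SMARTS pattern against one SMILES.
ob_smarts_count <- function(smiles, smarts) {
  m <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  as.numeric(ChemmineOB::smartsSearch_OB(m, smarts))
}

#' Heavy-atom molecular graph of a SMILES string
#'
#' Parses a molecule into a heavy-atom graph: element per atom and a bond
#' table with orders `-` (single, incl. amide), `=` (double), `#` (triple),
#' `*` (aromatic). The graph is obtained through an OpenBabel MOL2 round trip
#' (MOL2 retains aromatic bond flags) parsed with [bio3d::read.mol2()].
#'
#' @param smiles single SMILES string.
#' @return list with `elements` (character), `bonds` (tibble: from, to,
#'   order), `n_atoms`.
#' @export
mol_graph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL2", smiles, options = ob_no2d)),
    error = function(e) ""
  )
  if (!nzchar(txt)) abort(paste0("cannot parse SMILES: ", smiles))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- scan(text = lines[3], quiet = TRUE)
  if (counts[2] == 0) {
    # bond-less molecule (bio3d's reader requires a bond block)
    atom_start <- which(lines == "@<TRIPOS>ATOM") + 1L
    elety <- vapply(lines[seq(atom_start, atom_start + counts[1] - 1L)],
                    function(l) strsplit(trimws(l), "\\s+")[[1]][6],
                    character(1), USE.NAMES = FALSE)
    elements <- sub("\\..*$", "", elety)
    heavy <- elements != "H"
    return(list(elements = elements[heavy],
                bonds = tibble::tibble(from = integer(), to = integer(),
                                       order = character()),
                n_atoms = sum(heavy)))
  }
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  m <- bio3d::read.mol2(tf)
  elements <- sub("\\..*$", "", m$atom$elety)
  heavy <- elements != "H"
  idx <- cumsum(heavy)            # old index -> new index for heavy atoms
  bonds <- m$bond
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- tibble::tibble(from = integer(), to = integer(), order = character())
  } else {
    keep <- heavy[bonds$origin] & heavy[bonds$target]
    bonds <- tibble::tibble(
      from = idx[bonds$origin[keep]],
      to = idx[bonds$target[keep]],
      order = dplyr::case_match(
        as.character(bonds$type[keep]),
        "1" ~ "-", "2" ~ "=", "3" ~ "#", "ar" ~ "*", "am" ~ "-",
        .default = "-"
      )
    )
  }
  list(elements = elements[heavy], bonds = bonds, n_atoms = sum(heavy))
}

# igraph object from a mol_graph, with topological (unweighted) edges.
mol_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_atoms, directed = FALSE)
  if (nrow(g$bonds) > 0L) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$from, g$bonds$to))
  }
  ig
}

# Net formal charge read off bracket atoms of a SMILES string.
smiles_net_charge <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  if (length(brackets) == 0L) return(0L)
  sum(vapply(brackets, function(b) {
    m <- regmatches(b, regexec("([+-])([0-9]*)\\]$", b))[[1]]
    if (length(m) == 0L) {
      # count bare +/- runs, e.g. [N+], [O-], [Ca++]
      plus <- lengths(regmatches(b, gregexpr("\\+", b)))
      minus <- lengths(regmatches(b, gregexpr("-", b)))
      return(as.integer(plus - minus))
    }
    sign <- if (m[2] == "+") 1L else -1L
    mag <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    sign * mag
  }, integer(1)))
}
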