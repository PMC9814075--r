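#' Standardize a molecule library
#'
#' Applies the screening-pipeline standardization to each structure, in a
#' fixed order: counter-ion / solvent stripping (largest organic fragment),
#' neutralization of charged atoms, aromatization, stereochemistry depletion
#' and removal of explicit hydrogens, ending in a canonical SMILES. The last
#' three steps are realized through canonical re-perception by OpenBabel
#' after text-level stereo stripping.
#'
#' @param library a data frame with columns `id` and `smiles`; any further
#'   columns (e.g. a `pka` column destined for the descriptor passthrough)
#'   are carried through unchanged.
#' @return a tibble with columns `id`, `smiles` (input), `smiles_std`
#'   (canonical standardized SMILES, `NA` if unparseable), `transforms`
#'   (list-column of applied transform names), `mw`, `clogp`, `parse_error`,
#'   plus any extra input columns.
#' @examples
#' standardize_library(tibble::tibble(id = "tea", smiles = "CCN(CC)CC.Cl"))
#' @export
standardize_library <- function(library) {
  check_library_frame(library)
  if (nrow(library) == 0L) {
    return(tibble::tibble(id = character(), smiles = character(),
                          smiles_std = character(), transforms = list(),
                          mw = numeric(), clogp = numeric(),
                          parse_error = character()))
  }
  rows <- purrr::map2(library$id, library$smiles, standardize_one)
  out <- dplyr::bind_rows(rows)
  extra <- setdiff(names(library), names(out))
  if (length(extra) > 0L) {
    out <- dplyr::left_join(out, library[, c("id", extra)], by = "id")
  }
  out
}

check_library_frame <- function(library, smiles_col = "smiles") {
  if (!is.data.frame(library) || !all(c("id", smiles_col) %in% names(library))) {
    abort(paste0("`library` must be a data frame with columns 'id' and '", smiles_col, "'"))
  }
  dup <- unique(library$id[duplicated(library$id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicated id(s) in library: ", paste(dup, collapse = ", ")))
  }
  invisible(library)
}

# One molecule through the fixed transform order. Returns a one-row tibble;
# parse failures are reported in-band so library runs never abort.
standardize_one <- function(id, smiles) {
  fail <- function(msg) {
    tibble::tibble(
      id = id, smiles = smiles, smiles_std = NA_character_,
      transforms = list(character()), mw = NA_real_, clogp = NA_real_,
      parse_error = msg
    )
  }
  if (is.na(smiles) || !nzchar(smiles)) return(fail("empty SMILES"))
  if (is.na(ob_canonical_smiles(smiles))) {
    return(fail(paste0("unparseable SMILES for id '", id, "'")))
  }
  transforms <- character()

  # 1. salt/solvent removal: keep the largest organic fragment
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1L) {
    kept <- largest_organic_fragment(frags)
    if (is.na(kept)) return(fail(paste0("no organic fragment left for id '", id, "'")))
    smiles <- kept
    transforms <- c(transforms, "salt_solvent_removal")
  }

  # 2. neutralization of charged bracket atoms
  neut <- neutralize_smiles(smiles)
  if (neut != smiles) transforms <- c(transforms, "neutralization")
  smiles <- neut

  # 3-5. aromatization, stereo depletion, explicit-H removal via canonical
  # re-perception; stereo marks are stripped at text level first since the
  # canonical writer would preserve them.
  had_stereo <- grepl("[@/\\\\]", smiles)
  destereo <- strip_stereo(smiles)
  can <- ob_canonical_smiles(destereo)
  if (is.na(can)) return(fail(paste0("standardization produced unparseable SMILES for id '", id, "'")))
  if (had_stereo) transforms <- c(transforms, "stereo_depletion")
  if (grepl("\\[H\\]", smiles)) transforms <- c(transforms, "explicit_h_removal")
  if (!grepl("[a-z]", smiles) && grepl("(?<![A-Z])[cnosp]", can, perl = TRUE)) {
    transforms <- c(transforms, "aromatization")
  }

  props <- ob_properties(can)
  tibble::tibble(
    id = id, smiles = smiles, smiles_std = can, transforms = list(transforms),
    mw = props$mw, clogp = props$clogp, parse_error = NA_character_
  )
}

# Largest fragment containing carbon, measured in heavy atoms; NA if no
# fragment is organic (pure salt).
largest_organic_fragment <- function(frags) {
  info <- purrr::map(frags, function(f) {
    g <- tryCatch(mol_graph(f), error = function(e) NULL)
    if (is.null(g)) list(organic = FALSE, size = 0L)
    else list(organic = "C" %in% g$elements, size = g$n_atoms)
  })
  organic <- purrr::map_lgl(info, "organic")
  if (!any(organic)) return(NA_character_)
  sizes <- purrr::map_int(info, "size")
  sizes[!organic] <- -1L
  frags[which.max(sizes)]
}

# Text-level neutralization of bracket atoms: deprotonated O/S/N acids gain a
# proton, protonated amines lose one. Multiply charged or quaternary centers
# are left as-is (they cannot be neutralized by (de)protonation).
neutralize_smiles <- function(smiles) {
  subs <- c(
    "\\[O-\\]"  = "O",  "\\[S-\\]"  = "S",  "\\[N-\\]"  = "N",
    "\\[NH-\\]" = "N",
    "\\[NH\\+\\]"  = "N", "\\[NH2\\+\\]" = "N", "\\[NH3\\+\\]" = "N",
    "\\[NH4\\+\\]" = "N",
    "\\[nH\\+\\]"  = "[nH]",
    "\\[OH\\+\\]"  = "O", "\\[OH2\\+\\]" = "O",
    "\\[SH\\+\\]"  = "S"
  )
  for (pat in names(subs)) smiles <- gsub(pat, subs[[pat]], smiles)
  smiles
}

# Remove stereo descriptors: tetrahedral @ marks and cis/trans bond slashes.
strip_stereo <- function(smiles) {
  s <- gsub("@{1,2}", "", smiles)
  s <- gsub("[/\\\\]", "-", s)
  # unbracket atoms that needed brackets only for stereo, e.g. [CH] -> C
  gsub("\\[(C|N|O|S|P)H\\]", "\\1H0___", s) |>
    (\(x) gsub("(C|N|O|S|P)H0___", "\\1", x))()
}
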