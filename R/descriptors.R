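#' Fragment descriptor scheme
#'
#' Defines one substructure-count descriptor space over heavy-atom molecular
#' graphs: `sequence` (all shortest topological paths between atom pairs,
#' labeled by atoms and bonds along the path), `atom_pair` (element pair plus
#' topological distance) or `triplet` (three atoms with their three pairwise
#' topological distances).
#'
#' @param family one of `"sequence"`, `"atom_pair"`, `"triplet"`.
#' @param min_length,max_length path length bounds in atoms for sequences
#'   (`min_length >= 2`); for atom pairs `max_length` bounds the topological
#'   distance; for triplets it bounds each pairwise distance.
#' @param coloration `"atoms_bonds"` (bond orders in labels) or
#'   `"atoms_only"`; pairs and triplets are atoms-only by construction.
#' @return a `fragment_scheme` list.
#' @export
fragment_scheme <- function(family = c("sequence", "atom_pair", "triplet"),
                            min_length = 2L, max_length = 4L,
                            coloration = c("atoms_bonds", "atoms_only")) {
  family <- match.arg(family)
  coloration <- match.arg(coloration)
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  if (min_length < 2L) abort("`min_length` must be >= 2")
  if (max_length < min_length) abort("`max_length` must be >= `min_length`")
  if (max_length > 8L) abort("`max_length` must be <= 8")
  structure(list(family = family, min_length = min_length,
                 max_length = max_length, coloration = coloration),
            class = "fragment_scheme")
}

bond_symbol_matrix <- function(g) {
  sym <- matrix(NA_character_, g$n_atoms, g$n_atoms)
  if (nrow(g$bonds) > 0L) {
    sym[cbind(g$bonds$from, g$bonds$to)] <- g$bonds$order
    sym[cbind(g$bonds$to, g$bonds$from)] <- g$bonds$order
  }
  sym
}

#' Enumerate fragment counts for one molecule
#'
#' @param smiles a standardized (single-fragment) SMILES string.
#' @param scheme a [fragment_scheme()].
#' @return named integer vector of fragment counts; fragments are heavy-atom
#'   only, each unordered occurrence counted once.
#' @examples
#' enumerate_fragments("CCO", fragment_scheme("sequence", 2, 2))
#' @export
enumerate_fragments <- function(smiles, scheme) {
  stopifnot(inherits(scheme, "fragment_scheme"))
  g <- mol_graph(smiles)
  ig <- mol_igraph(g)
  if (g$n_atoms > 1L && igraph::components(ig)$no > 1L) {
    abort(paste0("disconnected molecule: ", smiles))
  }
  switch(scheme$family,
    sequence = count_sequences(g, ig, scheme),
    atom_pair = count_atom_pairs(g, ig, scheme),
    triplet = count_triplets(g, ig, scheme)
  )
}

# Sequences: every distinct shortest path between every unordered atom pair
# whose atom count falls within [min_length, max_length]. A path label reads
# element (bond element)*; the lexicographically smaller reading direction
# names the fragment.
count_sequences <- function(g, ig, scheme) {
  if (g$n_atoms < 2L) return(integer())
  d <- igraph::distances(ig)
  bsym <- bond_symbol_matrix(g)
  counts <- new.env(parent = emptyenv())
  bump <- function(lab) {
    assign(lab, (if (exists(lab, counts)) get(lab, counts) else 0L) + 1L,
           envir = counts)
  }
  for (i in seq_len(g$n_atoms - 1L)) {
    targets <- which(d[i, ] + 1 >= scheme$min_length &
                     d[i, ] + 1 <= scheme$max_length)
    targets <- targets[targets > i]
    if (length(targets) == 0L) next
    asp <- igraph::all_shortest_paths(ig, from = i, to = targets)$vpaths
    for (p in asp) {
      v <- as.integer(p)
      bump(sequence_label(v, g$elements, bsym, scheme$coloration))
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) integer() else out[order(names(out))]
}

sequence_label <- function(v, elements, bsym, coloration) {
  lab_dir <- function(v) {
    if (coloration == "atoms_only") return(paste(elements[v], collapse = "."))
    parts <- elements[v[1]]
    for (k in seq_along(v)[-1]) {
      parts <- c(parts, bsym[v[k - 1L], v[k]], elements[v[k]])
    }
    paste(parts, collapse = "")
  }
  a <- lab_dir(v); b <- lab_dir(rev(v))
  if (a <= b) a else b
}

# Atom pairs: (elementA, elementB, topological distance), A <= B, one count
# per unordered atom pair with 1 <= distance <= max_length.
count_atom_pairs <- function(g, ig, scheme) {
  if (g$n_atoms < 2L) return(integer())
  d <- igraph::distances(ig)
  labs <- character()
  for (i in seq_len(g$n_atoms - 1L)) {
    for (j in seq.int(i + 1L, g$n_atoms)) {
      if (d[i, j] >= 1 && d[i, j] <= scheme$max_length) {
        ab <- sort(c(g$elements[i], g$elements[j]))
        labs <- c(labs, paste(ab[1], ab[2], d[i, j], sep = "."))
      }
    }
  }
  if (length(labs) == 0L) return(integer())
  tab <- table(labs)
  setNames(as.integer(tab), names(tab))
}

# Triplets: every 3-atom combination labeled by the three elements and the
# three pairwise distances; the label is the lexicographic minimum over the
# six atom orderings (distances written d12.d13.d23).
count_triplets <- function(g, ig, scheme) {
  if (g$n_atoms < 3L) return(integer())
  d <- igraph::distances(ig)
  combs <- utils::combn(g$n_atoms, 3L)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  labs <- apply(combs, 2L, function(v) {
    if (max(d[v, v]) > scheme$max_length) return(NA_character_)
    cand <- vapply(perms, function(p) {
      w <- v[p]
      paste(g$elements[w[1]], g$elements[w[2]], g$elements[w[3]],
            d[w[1], w[2]], d[w[1], w[3]], d[w[2], w[3]], sep = ".")
    }, character(1))
    min(cand)
  })
  labs <- labs[!is.na(labs)]
  if (length(labs) == 0L) return(integer())
  tab <- table(labs)
  setNames(as.integer(tab), names(tab))
}

#' Build a descriptor matrix over a library
#'
#' Columns are the union of fragment labels over the library (absent
#' fragment = 0) or the provider's property names. Constant columns are
#' pruned at training time since they carry no signal.
#'
#' @param standardized data frame with columns `id`, `smiles_std`.
#' @param scheme a [fragment_scheme()] or a property provider created with
#'   [property_provider()].
#' @param prune drop all-constant columns? Set `FALSE` when featurizing
#'   prediction candidates against an existing model.
#' @return a `descriptor_matrix`: a tibble with `id` plus numeric feature
#'   columns, with attributes `space_name` and `scheme`.
#' @export
build_matrix <- function(standardized, scheme, prune = TRUE) {
  stopifnot(is.data.frame(standardized),
            all(c("id", "smiles_std") %in% names(standardized)))
  if (nrow(standardized) == 0L) abort("empty library")
  if (inherits(scheme, "property_provider")) {
    vals <- scheme$evaluate(standardized)
    stopifnot(identical(sort(names(vals)), sort(scheme$property_names)))
    out <- dplyr::bind_cols(tibble::tibble(id = standardized$id),
                            tibble::as_tibble(vals))
    space_name <- scheme$name
  } else {
    stopifnot(inherits(scheme, "fragment_scheme"))
    maps <- purrr::map(standardized$smiles_std, enumerate_fragments,
                       scheme = scheme)
    feats <- sort(unique(unlist(purrr::map(maps, names))))
    mat <- matrix(0L, nrow(standardized), length(feats),
                  dimnames = list(NULL, feats))
    for (i in seq_along(maps)) mat[i, names(maps[[i]])] <- maps[[i]]
    out <- dplyr::bind_cols(tibble::tibble(id = standardized$id),
                            tibble::as_tibble(mat))
    space_name <- paste0(scheme$family, "_", scheme$min_length, "_",
                         scheme$max_length, "_", scheme$coloration)
  }
  if (prune) {
    feat <- setdiff(names(out), "id")
    const <- feat[vapply(out[feat], function(x) length(unique(x)) == 1L,
                         logical(1))]
    if (length(const) > 0L) {
      inform(paste0("pruned ", length(const), " constant column(s) from ",
                    space_name))
      out <- out[setdiff(names(out), const)]
    }
  }
  structure(out, space_name = space_name, scheme = scheme,
            class = c("descriptor_matrix", class(out)))
}

#' Concatenate descriptor spaces
#'
#' @param matrices list of [build_matrix()] outputs sharing identical
#'   compound ids in identical order.
#' @return one `descriptor_matrix` with space-name-prefixed feature columns.
#' @export
concat_spaces <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ids <- matrices[[1]]$id
  for (m in matrices[-1]) {
    if (!identical(m$id, ids)) abort("compound ids differ between spaces")
  }
  if (length(matrices) == 1L) return(matrices[[1]])
  blocks <- purrr::map(matrices, function(m) {
    sp <- attr(m, "space_name") %||% "space"
    block <- m[setdiff(names(m), "id")]
    names(block) <- paste0(sp, ".", names(block))
    block
  })
  out <- dplyr::bind_cols(tibble::tibble(id = ids), blocks)
  if (anyDuplicated(names(out))) abort("duplicate feature names after concatenation")
  structure(out, space_name = "merged", scheme = NULL,
            class = c("descriptor_matrix", class(out)))
}

#' Physicochemical property provider
#'
#' A deterministic evaluator mapping standardized molecules to a fixed set
#' of named real-valued properties. The default provider computes molecular
#' weight, an atom-contribution logP estimate, H-bond donor and acceptor
#' counts, ring count and heavy-atom count from the structure, and passes
#' through a user-supplied pKa column when present (pKa is the dominant
#' predictor for the absorption endpoints and usually comes from an external
#' model or a measurement table).
#'
#' @param name provider name (becomes the descriptor space name).
#' @param property_names character vector of the properties produced.
#' @param evaluate function(standardized data frame) -> data frame of the
#'   declared properties.
#' @return a `property_provider`.
#' @export
property_provider <- function(name, property_names, evaluate) {
  structure(list(name = name, property_names = property_names,
                 evaluate = evaluate),
            class = "property_provider")
}

#' @rdname property_provider
#' @param pka_column name of a column of the standardized library holding
#'   user-supplied pKa values to pass through as a descriptor (pKa is the
#'   dominant predictor of the absorption endpoints and usually comes from
#'   an external model or a measurement table), or NULL to omit it.
#' @export
default_property_provider <- function(pka_column = NULL) {
  props <- c("mw", "clogp", "hbd", "hba", "ring_count", "heavy_atoms")
  if (!is.null(pka_column)) props <- c(props, "pka")
  property_provider(
    name = "physchem",
    property_names = props,
    evaluate = function(standardized) {
      base <- ob_properties(standardized$smiles_std)
      graphs <- purrr::map(standardized$smiles_std, mol_graph)
      base$ring_count <- purrr::map_dbl(graphs, function(g)
        nrow(g$bonds) - g$n_atoms + 1)  # cyclomatic number, connected graph
      base$heavy_atoms <- purrr::map_dbl(graphs, "n_atoms")
      if (!is.null(pka_column)) {
        if (!pka_column %in% names(standardized) ||
            anyNA(standardized[[pka_column]])) {
          abort(paste0("pKa passthrough needs a complete '", pka_column,
                       "' column in the library"))
        }
        base$pka <- standardized[[pka_column]]
      }
      base
    }
  )
}
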