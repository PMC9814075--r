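# Shared fixtures, memoized so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# 150-compound synthetic library with mechanistic truth (the standard
# end-to-end study condition).
fixture_gen150 <- function() memo("gen150", function() {
  generate_library(n_compounds = 150L, seed = 7L)
})

fixture_std150 <- function() memo("std150", function() {
  gen <- fixture_gen150()
  standardize_library(dplyr::mutate(gen$library, pka = gen$truth$pka))
})

fixture_descriptor_config <- function() {
  descriptor_config(
    schemes = list(seq24 = fragment_scheme("sequence", 2, 4),
                   pairs4 = fragment_scheme("atom_pair", 2, 4)),
    provider = default_property_provider(pka_column = "pka")
  )
}

fixture_spaces150 <- function() memo("spaces150", function() {
  suppressMessages(featurize(fixture_std150(), fixture_descriptor_config(),
                             prune = TRUE))
})

# Small learnable regression fixture: y is a noisy linear function of two
# descriptors, so tree and kernel models can recover it.
fixture_learnable <- function(n = 60L, seed = 42L, noise = 0.05) {
  set.seed(seed)
  X <- tibble::tibble(id = sprintf("c%03d", seq_len(n)),
                      f1 = runif(n), f2 = runif(n), f3 = runif(n))
  list(X = X, y = 2 * X$f1 - X$f2 + rnorm(n, 0, noise))
}

tiny_rf_grid <- function() {
  tibble::tibble(trees = 100, features = "all", depth = Inf, bootstrap = TRUE)
}

# Independent brute-force shortest-path fragment enumeration (DFS over all
# simple paths, keep those matching the BFS shortest distance), used as the
# oracle for the sequence descriptor family.
oracle_sequence_counts <- function(smiles, min_len, max_len) {
  g <- mol_graph(smiles)
  n <- g$n_atoms
  adj <- matrix(FALSE, n, n)
  bond <- matrix(NA_character_, n, n)
  if (nrow(g$bonds) > 0) {
    adj[cbind(g$bonds$from, g$bonds$to)] <- TRUE
    adj[cbind(g$bonds$to, g$bonds$from)] <- TRUE
    bond[cbind(g$bonds$from, g$bonds$to)] <- g$bonds$order
    bond[cbind(g$bonds$to, g$bonds$from)] <- g$bonds$order
  }
  # BFS distances
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer()
      for (v in frontier) for (w in which(adj[v, ])) {
        if (dist[s, w] > dist[s, v] + 1) { dist[s, w] <- dist[s, v] + 1; nxt <- c(nxt, w) }
      }
      frontier <- unique(nxt)
    }
  }
  counts <- list()
  label <- function(path) {
    lab <- function(v) {
      parts <- g$elements[v[1]]
      for (k in seq_along(v)[-1]) parts <- c(parts, bond[v[k-1], v[k]], g$elements[v[k]])
      paste(parts, collapse = "")
    }
    min(lab(path), lab(rev(path)))
  }
  dfs <- function(path, target) {
    v <- path[length(path)]
    if (v == target) {
      if (length(path) - 1 == dist[path[1], target]) {
        lab <- label(path)
        counts[[lab]] <<- (counts[[lab]] %||% 0L) + 1L
      }
      return(invisible())
    }
    if (length(path) - 1 >= dist[path[1], target]) return(invisible())
    for (w in which(adj[v, ])) if (!w %in% path) dfs(c(path, w), target)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    len <- dist[i, j] + 1
    if (is.finite(len) && len >= min_len && len <= max_len) dfs(i, j)
  }
  out <- unlist(counts)
  if (is.null(out)) integer() else out[order(names(out))]
}
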