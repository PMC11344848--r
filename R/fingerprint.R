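# MinHashed atom-pair fingerprint. A molecule is represented by its set of
# shingles "envA|d|envB": for every unordered pair of connected heavy atoms
# and every radius 1..max_radius, the canonical circular-environment strings
# of the two atoms joined by their topological (bond-count) distance. The
# shingle set is summarized by a seeded MinHash signature whose component-wise
# agreement estimates Jaccard similarity.

#' Fingerprint parameters
#'
#' @param max_radius Bond-count radius of the circular atom environments
#'   (default 2, the published atom-pair default).
#' @param signature_length Number of MinHash permutations (default 1024).
#' @param seed Integer seed salting the hash family; identical
#'   (molecule, params) always give identical signatures.
#' @param include_stereo Keep stereo descriptors in the molecular graph
#'   before shingling (default `FALSE`: stereo is stripped so environment
#'   canonicalization is stable).
#' @return An `fp_params` object.
#' @examples
#' fp_params(signature_length = 2048, seed = 7)
#' @export
fp_params <- function(max_radius = 2L, signature_length = 1024L, seed = 42L,
                      include_stereo = FALSE) {
  max_radius <- as.integer(max_radius)
  signature_length <- as.integer(signature_length)
  seed <- as.integer(seed)
  if (is.na(max_radius) || max_radius < 1L) abort("`max_radius` must be >= 1")
  if (is.na(signature_length) || signature_length < 16L) {
    abort("`signature_length` must be >= 16")
  }
  if (is.na(seed)) abort("`seed` must be an integer")
  structure(
    list(max_radius = max_radius, signature_length = signature_length,
         seed = seed, include_stereo = isTRUE(include_stereo)),
    class = "fp_params"
  )
}

#' @export
print.fp_params <- function(x, ...) {
  cat(sprintf("<fp_params> radius %d, %d permutations, seed %d, stereo %s\n",
              x$max_radius, x$signature_length, x$seed,
              if (x$include_stereo) "kept" else "stripped"))
  invisible(x)
}

params_equal <- function(a, b) {
  identical(a[c("max_radius", "signature_length", "seed", "include_stereo")],
            b[c("max_radius", "signature_length", "seed", "include_stereo")])
}

#' All-pairs topological distances of a molecular graph
#'
#' Shortest-path bond counts between heavy atoms; `Inf` marks atom pairs in
#' different connected components (shingling skips them).
#'
#' @param graph A `molecule_graph`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
topological_distances <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  n <- nrow(graph$atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(graph$bonds)) {
    g <- igraph::add_edges(g, rbind(graph$bonds$from, graph$bonds$to))
  }
  igraph::distances(g)
}

# Atom label used at the root of environment strings: element (lowercased if
# aromatic), charge sign if any, and implicit hydrogen count.
atom_labels <- function(graph) {
  a <- graph$atoms
  el <- ifelse(a$aromatic, tolower(a$element), a$element)
  chg <- ifelse(a$charge == 0L, "",
                ifelse(a$charge > 0L, paste0("+", a$charge), as.character(a$charge)))
  paste0(el, chg, "H", a$n_h)
}

#' Canonical circular atom environment
#'
#' Deterministic canonical serialization of the neighborhood within `radius`
#' bonds of an atom: a depth-limited tree unfolding in which sibling branches
#' are ordered lexicographically, so the string is independent of atom input
#' order and equal for symmetry-equivalent atoms. Aromatic ring bonds use
#' `:`; single/double/triple use `-`, `=`, `#`. The string is prefixed with
#' the radius (`r2:...`), so environments taken at different radii are
#' distinct tokens even when a small molecule saturates early.
#'
#' @param graph A `molecule_graph`.
#' @param atom 1-based atom index.
#' @param radius Number of bonds to unfold (0 gives the bare atom label).
#' @return Canonical environment string.
#' @export
atom_environment <- function(graph, atom, radius) {
  stopifnot(inherits(graph, "molecule_graph"))
  n <- nrow(graph$atoms)
  if (atom < 1L || atom > n) abort("`atom` out of range")
  if (radius < 0L) abort("`radius` must be >= 0")
  labels <- atom_labels(graph)
  adj <- adjacency_list(graph)
  paste0("r", radius, ":", env_string(atom, radius, 0L, labels, adj))
}

adjacency_list <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  b <- graph$bonds
  sym <- ifelse(b$aromatic, ":", c("-", "=", "#", ":")[pmin(b$order, 4L)])
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$from[k]]] <- rbind(adj[[b$from[k]]], c(b$to[k], sym[k]))
      adj[[b$to[k]]] <- rbind(adj[[b$to[k]]], c(b$from[k], sym[k]))
    }
  }
  adj
}

env_string <- function(atom, radius, parent, labels, adj) {
  root <- labels[atom]
  if (radius == 0L) return(root)
  nb <- adj[[atom]]
  if (is.null(nb)) return(root)
  keep <- as.integer(nb[, 1]) != parent
  if (!any(keep)) return(root)
  branches <- character(sum(keep))
  j <- 1L
  for (k in which(keep)) {
    child <- as.integer(nb[k, 1])
    branches[j] <- paste0(nb[k, 2], env_string(child, radius - 1L, atom, labels, adj))
    j <- j + 1L
  }
  paste0(root, "(", paste(sort(branches), collapse = ","), ")")
}

#' Shingle set of a molecule
#'
#' For every unordered pair of distinct connected heavy atoms (i, j) and
#' every radius k in 1..`max_radius`, emits the shingle
#' `min(env, env') | d(i,j) | max(env, env')` and deduplicates.
#'
#' @param graph A `molecule_graph` with at least 2 heavy atoms (a single-atom
#'   molecule yields an empty set with a warning).
#' @param params An [fp_params()] object.
#' @return Character vector (a set: sorted, unique).
#' @export
shingle_set <- function(graph, params = fp_params()) {
  stopifnot(inherits(graph, "molecule_graph"), inherits(params, "fp_params"))
  if (!params$include_stereo) graph <- strip_graph_stereo(graph)
  n <- nrow(graph$atoms)
  if (n < 2L) {
    warn("molecule has fewer than 2 heavy atoms; shingle set is empty")
    return(character(0))
  }
  d <- topological_distances(graph)
  labels <- atom_labels(graph)
  adj <- adjacency_list(graph)

  idx <- which(upper.tri(d) & is.finite(d), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warn("no connected atom pairs; shingle set is empty")
    return(character(0))
  }
  out <- character(0)
  for (k in seq_len(params$max_radius)) {
    envs <- vapply(seq_len(n), function(a) {
      paste0("r", k, ":", env_string(a, k, 0L, labels, adj))
    }, character(1))
    ea <- envs[idx[, 1]]
    eb <- envs[idx[, 2]]
    lo <- ifelse(ea <= eb, ea, eb)
    hi <- ifelse(ea <= eb, eb, ea)
    out <- c(out, paste0(lo, "|", d[idx], "|", hi))
  }
  sort(unique(out))
}

strip_graph_stereo <- function(graph) {
  # stereo only enters through the SMILES; reparse a stereo-stripped
  # canonical form (graph topology is unchanged, kekulization is re-derived)
  if (!grepl("[@/\\\\]", graph$smiles)) return(graph)
  parse_smiles(canonical_smiles(graph$smiles, strip_stereo = TRUE))
}

#' MinHash signature of a shingle set
#'
#' Component i is the minimum, over shingles, of a documented
#' platform-independent 64-bit string hash salted by (seed, i); see the
#' package vignette for the exact hash contract. Signatures from the same
#' (molecule, params) are byte-identical across runs and machines.
#'
#' @param shingles Nonempty character vector from [shingle_set()].
#' @param params An [fp_params()] object.
#' @return A `minhash_signature`: list with `components` (numeric vector of
#'   `signature_length` hash minima) and `params`.
#' @export
minhash <- function(shingles, params = fp_params()) {
  stopifnot(inherits(params, "fp_params"))
  if (length(shingles) == 0L) {
    abort("cannot MinHash an empty shingle set: no signature is defined")
  }
  comp <- minhash_components(shingles, params$signature_length,
                             as.double(params$seed))
  structure(list(components = comp, params = params),
            class = "minhash_signature")
}

#' @export
print.minhash_signature <- function(x, ...) {
  cat(sprintf("<minhash_signature> %d components (radius %d, seed %d)\n",
              length(x$components), x$params$max_radius, x$params$seed))
  invisible(x)
}

#' Estimate Jaccard similarity from two MinHash signatures
#'
#' The fraction of equal components; an unbiased estimate of the Jaccard
#' similarity of the underlying shingle sets.
#'
#' @param a,b `minhash_signature` objects built with identical parameters.
#' @return Similarity in \[0, 1\]; symmetric in its arguments.
#' @export
estimate_jaccard <- function(a, b) {
  stopifnot(inherits(a, "minhash_signature"), inherits(b, "minhash_signature"))
  if (!params_equal(a$params, b$params)) {
    abort("signatures built with different parameters are not comparable")
  }
  mean(a$components == b$components)
}

#' Exact Jaccard similarity of two shingle sets
#'
#' Brute-force |intersection| / |union|; the oracle against which the MinHash
#' estimator is validated.
#'
#' @param a,b Character vectors (sets) from [shingle_set()].
#' @return Similarity in \[0, 1\].
#' @export
exact_jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    abort("Jaccard similarity of two empty sets is undefined")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Serialize / restore a MinHash signature
#'
#' @param sig A `minhash_signature`.
#' @param path File path for the JSON record `{params, components}`.
#' @return `read_signature()` returns the restored `minhash_signature`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "minhash_signature"))
  # components are 53-bit integers; serialize as decimal strings so no
  # precision is lost to double formatting
  jsonlite::write_json(
    list(params = unclass(sig$params),
         components = sprintf("%.0f", sig$components)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- fp_params(x$params$max_radius, x$params$signature_length,
                 x$params$seed, x$params$include_stereo)
  structure(list(components = as.numeric(x$components), params = p),
            class = "minhash_signature")
}
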