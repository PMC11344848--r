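# The three panel-comparison methods: whole-sequence fingerprint Jaccard,
# per-position fingerprint Jaccard, and TF-IDF cosine similarity of the
# residue text, plus cross-family averaging with self-comparisons excluded.

#' Coerce input to a peptide panel
#'
#' A panel is a tibble with columns `id`, `sequence` and (optionally)
#' `family`. Character vectors are accepted, with names (or `seq_1`,
#' `seq_2`, ...) becoming ids.
#'
#' @param x Data frame with `id` and `sequence` columns, or a character
#'   vector of sequences.
#' @return A validated panel tibble (`id`, `sequence`, `family`).
#' @export
as_panel <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids) || any(!nzchar(ids))) {
      ids <- paste0("seq_", seq_along(x))
    }
    x <- tibble(id = ids, sequence = unname(x), family = NA_character_)
  }
  if (!is.data.frame(x) || !all(c("id", "sequence") %in% names(x))) {
    abort("a panel needs `id` and `sequence` columns (or a character vector)")
  }
  x <- as_tibble(x)
  if (!"family" %in% names(x)) x$family <- NA_character_
  if (nrow(x) == 0L) return(x[c("id", "sequence", "family")])
  if (anyDuplicated(x$id)) {
    abort(sprintf("duplicate panel ids: %s",
                  paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  }
  x$sequence <- vapply(x$sequence, check_sequence, character(1))
  x[c("id", "sequence", "family")]
}

sequence_shingles <- function(sequence, params) {
  # stereo is stripped before the first parse so the molecule is only
  # canonicalized once; shingle_set would otherwise reparse
  mol <- parse_smiles(peptide_smiles(sequence),
                      strip_stereo = !params$include_stereo)
  shingle_set(mol, params)
}

# Free-amino-acid signatures and shingle sets are cached: only 20 molecules
# exist per parameter set and positional similarity hits them constantly.
residue_fp <- function(code, params) {
  key <- paste(code, params$max_radius, params$signature_length, params$seed,
               params$include_stereo, sep = "/")
  hit <- the$residue_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (is.null(the$residue_cache)) the$residue_cache <- list()
  mol <- parse_smiles(residue_smiles(code, "free")$smiles,
                      strip_stereo = !params$include_stereo)
  sh <- shingle_set(mol, params)
  out <- list(shingles = sh, signature = minhash(sh, params))
  the$residue_cache[[key]] <- out
  out
}

#' Whole-sequence chemical similarity of two peptides
#'
#' Assembles both peptides into molecules, computes MinHashed atom-pair
#' fingerprints and returns the estimated Jaccard similarity
#' (1 - Jaccard distance): 1 for identical, 0 for highly dissimilar.
#'
#' @param a,b One-letter residue strings.
#' @param params An [fp_params()] object.
#' @param exact Use the brute-force exact Jaccard of the shingle sets
#'   instead of the MinHash estimate.
#' @return Similarity in \[0, 1\]; symmetric.
#' @examples
#' \donttest{
#' full_similarity("CGGSGGC", "CGSGGSGC")
#' }
#' @export
full_similarity <- function(a, b, params = fp_params(), exact = FALSE) {
  sa <- sequence_shingles(a, params)
  sb <- sequence_shingles(b, params)
  if (exact) return(exact_jaccard(sa, sb))
  estimate_jaccard(minhash(sa, params), minhash(sb, params))
}

#' Per-position chemical similarity profile
#'
#' Aligns two equal-length peptides position by position; at each position
#' the free amino-acid molecules of the two residues are fingerprinted and
#' their Jaccard similarity estimated. Identical residues short-circuit to
#' exactly 1.
#'
#' @param a,b Equal-length one-letter residue strings.
#' @param params An [fp_params()] object.
#' @param exact Use exact Jaccard on the residue shingle sets.
#' @return A tibble (`position`, `residue_a`, `residue_b`, `similarity`)
#'   with one row per position.
#' @export
positional_similarity <- function(a, b, params = fp_params(), exact = FALSE) {
  a <- check_sequence(a, "a")
  b <- check_sequence(b, "b")
  if (nchar(a) != nchar(b)) {
    abort(sprintf(
      "positional similarity needs equal lengths: got %d (a) vs %d (b)",
      nchar(a), nchar(b)
    ))
  }
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  sim <- vapply(seq_along(ra), function(p) {
    if (ra[p] == rb[p]) return(1)
    fa <- residue_fp(ra[p], params)
    fb <- residue_fp(rb[p], params)
    if (exact) exact_jaccard(fa$shingles, fb$shingles)
    else estimate_jaccard(fa$signature, fb$signature)
  }, numeric(1))
  tibble(position = seq_along(ra), residue_a = ra, residue_b = rb,
         similarity = sim)
}

#' TF-IDF cosine similarity of the residue text
#'
#' Treats each peptide sequence as a document of single-letter tokens.
#' Term counts are weighted by smoothed inverse document frequency
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1` over the supplied panel as
#' corpus, Euclidean-normalized, and compared by dot product.
#'
#' @param panel A panel (see [as_panel()]) with at least one sequence.
#' @return A `similarity_matrix` (method `"tfidf_cosine"`).
#' @examples
#' tfidf_cosine(c(a = "AAG", b = "AGG", c = "CCC"))
#' @export
tfidf_cosine <- function(panel) {
  panel <- as_panel(panel)
  if (nrow(panel) == 0L) abort("cannot compute TF-IDF over an empty panel")
  counts <- tfidf_counts(panel$sequence)
  v <- tfidf_vectors(counts)
  m <- v %*% t(v)
  diag(m) <- 1
  m[m < 0] <- 0
  m[m > 1] <- 1
  dimnames(m) <- list(panel$id, panel$id)
  new_similarity_matrix(m, "tfidf_cosine", params = NULL)
}

tfidf_counts <- function(sequences) {
  t(vapply(sequences, function(s) {
    tab <- table(factor(strsplit(s, "")[[1]], levels = AA_CODES))
    as.integer(tab)
  }, integer(length(AA_CODES))))
}

tfidf_vectors <- function(counts) {
  n_docs <- nrow(counts)
  df <- colSums(counts > 0L)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  w <- sweep(counts, 2, idf, `*`)
  norms <- sqrt(rowSums(w^2))
  sweep(w, 1, norms, `/`)
}

new_similarity_matrix <- function(m, method, params) {
  structure(m, class = c("similarity_matrix", class(m)),
            method = method, params = params)
}

#' Pairwise similarity matrix over a panel
#'
#' @param panel A panel of at least 2 peptides with unique ids; for
#'   `positional_mean`, all sequences must share one length.
#' @param method `"full_map4"` (whole-sequence fingerprint Jaccard),
#'   `"positional_mean"` (arithmetic mean of the per-position profile, a
#'   convenience summary), or `"tfidf_cosine"`.
#' @param params An [fp_params()] object (ignored by `tfidf_cosine`).
#' @param exact Use exact Jaccard instead of the MinHash estimate.
#' @return A `similarity_matrix`: symmetric numeric matrix with peptide ids
#'   as dimnames, carrying `method` and `params` attributes.
#' @export
pairwise_matrix <- function(panel,
                            method = c("full_map4", "positional_mean", "tfidf_cosine"),
                            params = fp_params(), exact = FALSE) {
  method <- match.arg(method)
  panel <- as_panel(panel)
  if (nrow(panel) < 2L) abort("a pairwise matrix needs at least 2 peptides")
  if (method == "tfidf_cosine") return(tfidf_cosine(panel))

  n <- nrow(panel)
  m <- diag(1, n)
  dimnames(m) <- list(panel$id, panel$id)

  if (method == "full_map4") {
    shingles <- lapply(panel$sequence, sequence_shingles, params = params)
    sigs <- if (!exact) lapply(shingles, minhash, params = params)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        s <- if (exact) exact_jaccard(shingles[[i]], shingles[[j]])
        else estimate_jaccard(sigs[[i]], sigs[[j]])
        m[i, j] <- m[j, i] <- s
      }
    }
  } else {
    lens <- nchar(panel$sequence)
    if (length(unique(lens)) != 1L) {
      abort(sprintf(
        "positional_mean needs equal-length sequences; lengths seen: %s",
        paste(sort(unique(lens)), collapse = ", ")
      ))
    }
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        prof <- positional_similarity(panel$sequence[i], panel$sequence[j],
                                      params = params, exact = exact)
        m[i, j] <- m[j, i] <- mean(prof$similarity)
      }
    }
  }
  new_similarity_matrix(m, method, params)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, method %s\n",
              nrow(x), ncol(x), attr(x, "method")))
  print(round(unclass(x)[, , drop = FALSE], 3))
  invisible(x)
}

#' @rdname pairwise_matrix
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return `tidy()` returns a long tibble (`id_a`, `id_b`, `similarity`,
#'   `method`) over unordered pairs (upper triangle, no diagonal).
#' @export
tidy.similarity_matrix <- function(x, ...) {
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    id_a = rownames(x)[idx[, 1]],
    id_b = colnames(x)[idx[, 2]],
    similarity = x[idx],
    method = attr(x, "method")
  )
}

#' @rdname pairwise_matrix
#' @export
glance.similarity_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  tibble(method = attr(x, "method"), n_peptides = nrow(x),
         mean_similarity = mean(off), min_similarity = min(off),
         max_similarity = max(off))
}

#' @rdname pairwise_matrix
#' @param object A `similarity_matrix`.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(id_a = rownames(object), id_b = colnames(object))
  df$similarity <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$id_b, .data$id_a,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity",
                  title = paste("Pairwise similarity:", attr(object, "method"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Cross-family average similarities, excluding self-comparisons
#'
#' For each peptide of group A, the mean similarity against all of group B
#' (cross) and against the rest of group A (within, `NA` for a singleton
#' group — undefined, not zero); and symmetrically for group B. The matrix
#' diagonal never contributes.
#'
#' @param mat A `similarity_matrix`.
#' @param group_a,group_b Disjoint character vectors of peptide ids present
#'   in `mat`.
#' @return A `panel_comparison` tibble: `id`, `group`, `cross_mean`,
#'   `within_mean`.
#' @export
cross_family_averages <- function(mat, group_a, group_b) {
  stopifnot(inherits(mat, "similarity_matrix"))
  ids <- rownames(mat)
  missing <- setdiff(c(group_a, group_b), ids)
  if (length(missing)) {
    abort(sprintf("ids not in matrix: %s", paste(missing, collapse = ", ")))
  }
  if (length(intersect(group_a, group_b))) {
    abort("groups must be disjoint")
  }
  one_group <- function(own, other, label) {
    purrr::map_dfr(own, function(id) {
      within_ids <- setdiff(own, id)
      tibble(
        id = id,
        group = label,
        cross_mean = mean(mat[id, other]),
        within_mean = if (length(within_ids)) mean(mat[id, within_ids]) else NA_real_
      )
    })
  }
  out <- dplyr::bind_rows(one_group(group_a, group_b, "A"),
                          one_group(group_b, group_a, "B"))
  structure(out, class = c("panel_comparison", class(out)),
            method = attr(mat, "method"))
}

#' @rdname cross_family_averages
#' @param x A `panel_comparison`.
#' @param ... Unused.
#' @export
glance.panel_comparison <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$group),
    n = dplyr::n(),
    mean_cross = mean(.data$cross_mean),
    mean_within = mean(.data$within_mean, na.rm = TRUE),
    .groups = "drop"
  )
}

#' @rdname cross_family_averages
#' @param object A `panel_comparison`.
#' @export
autoplot.panel_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("cross_mean", "within_mean"),
                            names_to = "scope", values_to = "similarity")
  ggplot2::ggplot(df, ggplot2::aes(.data$id, .data$similarity,
                                   fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "mean similarity (self excluded)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
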