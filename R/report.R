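# Report assembly: run all requested comparison methods over two labelled
# panels and write a diff-able bundle (TSV matrices/profiles, JSON averages,
# JSON manifest). Outputs are a pure function of the config, so reruns with
# the same config and seed are byte-identical.

#' Build a comparison run configuration
#'
#' @param panel_a,panel_b Panels (tibbles, character vectors, or FASTA
#'   paths), e.g. a cyclic-binder family vs a linear-binder family.
#' @param label_a,label_b Group labels used in file names and reports.
#' @param methods Subset of `c("full_map4", "positional_mean",
#'   "tfidf_cosine")`; at least one.
#' @param params An [fp_params()] object (its seed drives all randomness).
#' @param exact Use exact Jaccard (brute-force shingle-set oracle) instead
#'   of the MinHash estimate; intended for panels of at most ~50 peptides.
#' @param out_dir Output directory (created if missing).
#' @return A `run_config` list.
#' @export
run_config <- function(panel_a, panel_b, label_a = "A", label_b = "B",
                       methods = c("full_map4", "positional_mean", "tfidf_cosine"),
                       params = fp_params(), exact = FALSE,
                       out_dir = tempfile("pepsim_run_")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) == 0L) abort("at least one method is required")
  resolve <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x)
    else as_panel(x)
  }
  structure(
    list(panel_a = resolve(panel_a), panel_b = resolve(panel_b),
         label_a = label_a, label_b = label_b, methods = methods,
         params = params, exact = isTRUE(exact), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the panel comparison and write the report bundle
#'
#' Per requested method: the pairwise similarity matrix (TSV, id header row
#' and column), a per-peptide average report excluding self-comparisons
#' (JSON), and - for the positional method - a per-position profile TSV for
#' every cross-family pair. A `manifest.json` records parameters, seed,
#' methods, emitted files and package version. Sequences of unequal length
#' block the positional method only (logged as a skip); the other methods
#' proceed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages (messages never alter outputs).
#' @return Invisibly, a list with the in-memory results (`matrices`,
#'   `comparisons`, `positional`) and the manifest.
#' @export
run_comparison <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  both <- dplyr::bind_rows(
    dplyr::mutate(config$panel_a, family = config$label_a),
    dplyr::mutate(config$panel_b, family = config$label_b)
  )
  both <- as_panel(both)
  ids_a <- both$id[both$family == config$label_a]
  ids_b <- both$id[both$family == config$label_b]

  equal_len <- length(unique(nchar(both$sequence))) == 1L
  methods <- config$methods
  skipped <- character(0)
  if ("positional_mean" %in% methods && !equal_len) {
    say("skipping positional method: sequences have unequal lengths")
    skipped <- "positional_mean"
    methods <- setdiff(methods, "positional_mean")
  }

  matrices <- list()
  comparisons <- list()
  files <- character(0)
  for (m in methods) {
    say("computing %s similarity matrix (%d peptides)", m, nrow(both))
    mat <- pairwise_matrix(both, method = m, params = config$params,
                           exact = config$exact)
    matrices[[m]] <- mat
    f <- file.path(config$out_dir, paste0("similarity_", m, ".tsv"))
    write_matrix_tsv(mat, f)
    files <- c(files, f)

    cmp <- cross_family_averages(mat, ids_a, ids_b)
    cmp$group <- ifelse(cmp$group == "A", config$label_a, config$label_b)
    comparisons[[m]] <- cmp
    f <- file.path(config$out_dir, paste0("comparison_", m, ".json"))
    jsonlite::write_json(as_tibble(cmp), f, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    files <- c(files, f)
  }

  positional <- NULL
  if ("positional_mean" %in% methods) {
    prof <- purrr::map_dfr(ids_a, function(ia) {
      purrr::map_dfr(ids_b, function(ib) {
        p <- positional_similarity(both$sequence[both$id == ia],
                                   both$sequence[both$id == ib],
                                   params = config$params,
                                   exact = config$exact)
        dplyr::mutate(p, id_a = ia, id_b = ib, .before = 1)
      })
    })
    positional <- prof
    f <- file.path(config$out_dir, "positional_profiles.tsv")
    write.table(prof, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- list(
    package = "pepsim",
    version = as.character(utils::packageVersion("pepsim")),
    seed = config$params$seed,
    params = unclass(config$params),
    exact = config$exact,
    methods = methods,
    skipped_methods = skipped,
    labels = c(config$label_a, config$label_b),
    n_peptides = c(length(ids_a), length(ids_b)),
    files = basename(files)
  )
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("wrote %d files to %s", length(files) + 1L, config$out_dir)

  invisible(list(matrices = matrices, comparisons = comparisons,
                 positional = positional, manifest = manifest))
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), unclass(mat), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [run_comparison()]
#'
#' @param path TSV path.
#' @param method Method tag to attach.
#' @return A `similarity_matrix`.
#' @export
read_matrix_tsv <- function(path, method = "full_map4") {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  new_similarity_matrix(m, method, params = NULL)
}
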