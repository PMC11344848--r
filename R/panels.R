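# Seeded synthetic peptide-panel generator emulating CX10C phage-display
# selection outputs: a cyclic-binder family with the CPXNXXXPXXXC consensus,
# a linear-binder family with an embedded HPQ/HPM motif, and uniform-random
# CX10C controls. FASTA I/O for real panels.

#' Generate a synthetic peptide panel
#'
#' All families use the CX10C library scaffold (12-mers, cysteines fixed at
#' positions 1 and 12). `"str_like"` additionally fixes P2, N4 and P8 so
#' every member satisfies [matches_consensus()]; `"hpq_like"` writes HPQ or
#' HPM (fair seeded coin) at an internal offset; `"random"` draws all ten
#' internal positions uniformly. Identical spec + seed gives identical
#' panels.
#'
#' @param family `"str_like"`, `"hpq_like"` or `"random"`.
#' @param n Panel size (>= 1).
#' @param seed Integer seed; the generator leaves the global RNG untouched.
#' @param length Residue count; the CX10C scaffold requires 12.
#' @param alphabet Residue set drawn from at wildcard positions (default all
#'   20 natural amino acids; "X = any natural amino acid").
#' @param exclude_cys Drop cysteine from `alphabet` (real selections may
#'   disfavor extra thiols).
#' @param motif_offset For `"hpq_like"`: `"uniform"` places the tripeptide
#'   motif at a seeded uniform offset in 2..9; an integer in 2..9 fixes it.
#' @return A panel tibble (`id`, `sequence`, `family`) with ids like
#'   `str_like_001`.
#' @examples
#' generate_panel("str_like", n = 9, seed = 7)
#' @export
generate_panel <- function(family = c("str_like", "hpq_like", "random"),
                           n, seed, length = 12L, alphabet = AA_CODES,
                           exclude_cys = FALSE, motif_offset = "uniform") {
  family <- match.arg(family)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be >= 1")
  if (as.integer(length) != 12L) {
    abort("the CX10C scaffold is a 12-mer; `length` must be 12")
  }
  alphabet <- toupper(alphabet)
  bad <- setdiff(alphabet, AA_CODES)
  if (base::length(bad)) {
    abort(sprintf("invalid alphabet letters: %s", paste(bad, collapse = ", ")))
  }
  if (exclude_cys) alphabet <- setdiff(alphabet, "C")
  if (base::length(alphabet) == 0L) abort("`alphabet` is empty")

  seqs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) {
      res <- character(12L)
      res[c(1L, 12L)] <- "C"
      internal <- 2:11
      if (family == "str_like") {
        res[c(2L, 4L, 8L)] <- c("P", "N", "P")
        internal <- setdiff(internal, c(2L, 4L, 8L))
      }
      res[internal] <- sample(alphabet, base::length(internal), replace = TRUE)
      if (family == "hpq_like") {
        motif <- if (sample(c(TRUE, FALSE), 1L)) "HPQ" else "HPM"
        off <- if (identical(motif_offset, "uniform")) {
          sample(2:9, 1L)
        } else {
          off <- as.integer(motif_offset)
          if (is.na(off) || off < 2L || off > 9L) {
            abort("`motif_offset` must be \"uniform\" or an integer in 2..9")
          }
          off
        }
        res[off:(off + 2L)] <- strsplit(motif, "")[[1]]
      }
      paste(res, collapse = "")
    }, character(1))
  })
  tibble(
    id = sprintf("%s_%03d", family, seq_len(n)),
    sequence = seqs,
    family = family
  )
}

#' @rdname generate_panel
#' @param ... Passed on to [generate_panel()].
#' @export
generate_str_like <- function(n, seed, ...) {
  generate_panel("str_like", n = n, seed = seed, ...)
}

#' @rdname generate_panel
#' @export
generate_hpq_like <- function(n, seed, ...) {
  generate_panel("hpq_like", n = n, seed = seed, ...)
}

#' @rdname generate_panel
#' @export
generate_random_panel <- function(n, seed, ...) {
  generate_panel("random", n = n, seed = seed, ...)
}

#' Bundled fixture peptides
#'
#' The model peptides printed in the source study: P1-P6 (P1 appears in two
#' discrepant variants in the original report - `P1_table` CTTRRPYLVCWL from
#' the table, `P1_text` CTTEEPYLVCWL from the body text - both are kept and
#' flagged in the `note` column), the vasopressin scaffold CYFQNCPRG and its
#' two single-cysteine controls.
#'
#' @return A panel tibble with columns `id`, `sequence`, `family`, `note`.
#' @export
fixture_panel <- function() {
  tibble(
    id = c("P1_table", "P1_text", "P2", "P3", "P4", "P5", "P6",
           "vasopressin", "pep1", "pep2"),
    sequence = c("CTTRRPYLVCWL", "CTTEEPYLVCWL", "CGGSGGC", "CGSGGSGC",
                 "CQPHPGQTC", "CPEGYILDDGFCTDIDE", "CYKLAEGDKYYIC",
                 "CYFQNCPRG", "CYFQNSPRG", "SYFQNCPRG"),
    family = "fixture",
    note = c("P1 as tabulated", "P1 as given in body text (discrepant)",
             rep(NA_character_, 6),
             "N-terminal-cysteine-only control",
             "internal-cysteine-only control")
  )
}

#' Read / write peptide panels as FASTA
#'
#' Single-line sequence records; the description line is
#' `id family=<family>` when a family tag is present. Round-trips are
#' lossless. Records with letters outside the 20-residue alphabet are
#' rejected with the offending record named.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a panel tibble (empty, with a warning, for
#'   an empty file).
#' @export
read_fasta <- function(path) {
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readAAStringSet(path),
      error = function(e) abort(sprintf("malformed FASTA '%s': %s",
                                        path, conditionMessage(e)))
    ),
    # the reader silently drops invalid letters; treat that as malformed
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (base::length(set) == 0L) {
    warn(sprintf("empty FASTA file: %s", path))
    return(tibble(id = character(), sequence = character(),
                  family = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  fam <- ifelse(grepl("family=", headers),
                sub("^.*family=(\\S+).*$", "\\1", headers), NA_character_)
  seqs <- as.character(set)
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[i], "")[[1]], AA_CODES)
    if (base::length(bad)) {
      abort(sprintf(
        "record '%s' (entry %d) contains non-amino-acid letters: %s",
        ids[i], i, paste(unique(bad), collapse = ", ")
      ))
    }
  }
  as_panel(tibble(id = ids, sequence = seqs, family = fam))
}

#' @rdname read_fasta
#' @param panel A panel tibble.
#' @export
write_fasta <- function(panel, path) {
  panel <- as_panel(panel)
  header <- ifelse(is.na(panel$family), panel$id,
                   paste0(panel$id, " family=", panel$family))
  lines <- as.vector(rbind(paste0(">", header), panel$sequence))
  writeLines(lines, path)
  invisible(path)
}
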